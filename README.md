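# rdnadrift

Tools for studying copy-number dynamics of the ribosomal DNA (rDNA) array in
budding yeast. The rDNA is a tandem repeat of ~9.1-kb units (~150 copies) on
chromosome XII; the Fob1 protein stalls replication forks at each unit's
replication fork barrier (RFB), triggering double-strand breaks whose repair
by unequal sister-chromatid recombination both changes copy number and
recovers it toward a setpoint. Long-term evolution experiments probe what
happens when that machinery is removed (*fob1Δ*): copy number drifts
downward, while wild type fluctuates around its setpoint.

`rdnadrift` re-implements the computational side of such experiments as a
tested, reusable R pipeline, driven entirely by its own synthetic-data
generators:

* **Synthetic data** — an annotated rDNA repeat unit (35S, 5S, rARS, E-pro,
  RFB), tandem arrays with planted SNVs and internal deletions, nanopore-style
  long reads, collapsed-unit short-read pileups, pulsed-field gel (PFGE) lane
  profiles with a *Hansenula wingei* marker ladder, flow-cytometry DNA-content
  histograms, and replicate copy-number trajectories.
* **Gel quantification** — ladder calibration (piecewise-linear in
  log10 size vs distance), band detection with prominence and FWHM,
  copy-number estimation `copies = (size − backbone) / unit`, copy shift
  relative to generation 0, and band-proportion densitometry for competition
  and ERC gels.
* **Long-read SV calling** — the bin-split procedure: QC (length > 8000 nt,
  mean Phred > 18), splitting reads into 300-nt bins, mapping each bin to the
  circular repeat unit (k-mer seed + Hamming verify; SAM/PAF import for
  external mappings), and calling a structural variant whenever consecutive
  bins' reference distance deviates from expectation by more than 100 nt
  (deletions if positive, insertions if negative).
* **Short-read variant tallying** — naive per-position base counts over the
  collapsed unit (a variant in k of n copies appears at frequency ≈ k/n),
  variant-frequency spectra, and a bootstrap comparison of two spectra.
* **Culture analysis** — generation accounting for serial-dilution and
  colony passaging (`log2` of the growth factor), per-replicate drift slopes
  of copy-number trajectories, and ploidy classification from DNA-content
  histograms.

## Worked example

```r
library(rdnadrift)
library(dplyr)

# How many generations does a passage scheme represent?
generations_per_transfer(1000)   # 9.965784 -> ~10 generations per transfer
colony_generations(1.165e7)      # 23.47393 -> a 1-2 mm colony is ~23.5 doublings

# A 4-copy array with one 500-bp internal deletion, error-free long reads,
# and the bin-split SV caller:
unit  <- make_reference_unit(seed = 1)
arr   <- build_array(unit, 4,
                     deletions = tibble(copy = 2, start = 2000, end = 2500),
                     arms = c(1000, 1000), seed = 2)
reads <- simulate_long_reads(arr, 50,
                             length_law = list(meanlog = log(10500), sdlog = 0.1,
                                               min = 8500, max = 16000),
                             error_rate = 0,
                             q_law = list(mean = 30, sd = 1, base_sd = 1),
                             seed = 3)
s <- summarize_sample(reads, unit)
s
#> <sv_sample_summary> 50 reads -> 50 pass QC -> 50 analyzed; 19 with SVs
#>   (fraction 0.380); 19 deletion calls >= 50 nt
tidy(s) |> count(type, size)
#> 19 deletion calls, every one of size exactly 500

# PFGE: simulate a clonal 150-copy lane, refit the marker ladder, estimate
# copies from the chromosome XII band:
gel <- simulate_gel_lanes(list(clonal = 150), noise_sd = 0, seed = 4)
mp  <- find_peaks(gel_lane(gel, "marker"), min_prominence = 0.2)
cal <- fit_ladder(tibble(distance_mm = mp$distance_mm,
                         size_kb = sort(default_hwingei_ladder()$size_kb,
                                        decreasing = TRUE)))
pk  <- find_peaks(gel_lane(gel, "clonal"))
estimate_copy_number(pk[which.max(pk$area), ], cal)$copies
#> [1] 149.9999

# Copy-number trajectories: 24 fob1-null replicates over 900 generations
traj <- simulate_trajectory(sim_params(), "fob1d",
                            n_replicates = 24, n_generations = 900, seed = 5)
glance(estimate_drift(traj))
#> 24 replicates, 24 negative slopes, mean_slope -0.0999 copies/generation
```

The estimated 150.0 copies comes back from the simulated gel because the
clonal band's apex maps through the refitted ladder to chromosome XII size
2415 kb = 1050 kb backbone + 150 × 9.1 kb. The drift summary reproduces the
defining contrast of the system: every fork-barrier-deficient replicate
loses copies, while wild-type runs (mode `"WT"`) center on zero shift.

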