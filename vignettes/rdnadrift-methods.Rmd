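---
title: "Models and methods behind rdnadrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rdnadrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rdnadrift` analyses the copy-number dynamics of the yeast rDNA — a tandem
array of ~9.1-kb repeat units on chromosome XII — across long-term culture
experiments. This vignette explains the models the package implements, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate.

## The system in brief

Each rDNA unit carries the 35S and 5S rRNA genes, a replication origin
(rARS), a bidirectional non-coding promoter (E-pro) and a replication fork
barrier (RFB). Fob1 bound at the RFB stalls replication forks; the
resulting double-strand breaks are repaired by unequal sister-chromatid
recombination, which changes copy number and — through a Sir2/UAF counting
mechanism acting on *total* copy number — recovers it toward a setpoint.
Removing Fob1 suppresses this variation and its recovery; residual,
Fob1-independent recombination is deletion-biased, so copy number drifts
downward. The package's analyses quantify exactly the observables used to
establish this picture: chromosome XII band positions on pulsed-field gels,
bin-split structural-variant calls from nanopore reads, naive per-position
variant frequencies from short reads, DNA-content histograms, and
generation accounting for the passage schemes.

## Synthetic-data generators

The generators are first-class, tested code: every downstream analysis is
validated against data whose ground truth is known by construction.

**Reference unit and tandem array.** The unit is a uniform-random ACGT
sequence with a schematic element map. A random sequence is used, rather
than the real S288C repeat, because no analysis here depends on sequence
content — mapping, deviation geometry, pileup fractions and gel physics are
all content-agnostic; a real unit can be supplied via `read_unit_fasta()`.
The default unit length (9,100 bp) and setpoint (150 copies) are standard
yeast values; both are configuration, as is the 1,050-kb non-rDNA
chromosome XII "backbone" used to convert band size to copies. Arrays are
built copy by copy with planted SNVs and internal deletions, and the
realized length is exact: `|arms| + n·L_unit − Σ deletions`.

**Long reads.** Lengths follow a log-normal law truncated to
[1,000, 50,000] nt (default median 9,000 nt, log-sd 0.4), chosen so the
length filter genuinely splits the population; per-read mean quality is
Normal(20, 3) Phred with within-read spread 3, so the quality filter does
too. Errors are uniform substitutions; indel errors are not modelled (the
deviation rule tolerates up to 100 nt of accumulated indel drift by
construction, so substitution-only reads exercise every code path except
sub-tolerance indel noise). Reads record their true origin interval and the
planted deletions they span. Qualities are written as Sanger-encoded FASTQ
(offset 33).

**Short-read pileups.** Rather than simulating individual short reads, the
generator draws each unit position's base counts from the exact multinomial
implied by the analysis geometry: all copies collapse onto one unit, so a
variant carried by k of n copies contributes allele fraction k/n, mixed
with a uniform substitution error. Counts sum to the requested coverage at
every position by construction — the conservation invariant the tally
validates.

**Gel lanes.** A migration law linear in log10(size)
(`distance = 330 − 90·log10(size_kb)`, sampled at the seven largest
*H. wingei* marker chromosomes) maps each cell's chromosome XII size to a
band centre; a lane is the Gaussian mixture over the population's cells
(band sd 1 mm) plus truncated-Gaussian baseline noise. A clonal population
gives a tight band; a broad copy-number distribution gives a smear — the
gel's visual signature of copy-number heterogeneity. Because the law is
log-linear, refitting the simulated marker lane recovers the truth
calibration exactly, which is what makes the round-trip tests sharp. No
PFGE mobility physics beyond this empirical monotone map is modelled.

**Trajectories.** A biased, copy-count-scaled random walk: each generation
each chromosome recombines with probability `recomb_rate × copies`
(default 0.001 per copy), and on an event takes a Gaussian step (sd 3
copies). Wild type steps have mean `recovery_gain × (setpoint_total −
total)` (gain 0.05), i.e. symmetric variation plus recovery of the *total*
copy number toward the setpoint; the fork-barrier-deficient mode has mean
−1 copy and no recovery. Copies are floored at `min_viable` (2). This is
the simplest generative structure consistent with the observed phenomena:
downward monotone drift without the barrier, directionless fluctuation
with it, and — because event rate scales with copy count while recovery
watches the total — a diploid's larger homolog fluctuating more than its
smaller one. The parameters are configuration; no mechanistic fidelity is
claimed, and no attempt is made to calibrate absolute shift magnitudes to
any particular experiment.

**DNA-content histograms.** Two Gaussian peaks at `ploidy·u` and
`2·ploidy·u` (unit fluorescence u = 100 a.u., CV 0.05, 60% of cells
post-replication), binned on a fixed, ploidy-independent grid so that
haploid and diploid histograms are directly comparable.

## Analysis methods and numerical choices

**Ladder calibration** interpolates log10(size) piecewise-linearly against
migration distance — the standard treatment for chromosomal ladders; the
functional form is otherwise unconstrained by any published procedure.
Evaluation at a knot returns its size exactly; outside the knot range the
terminal segment is extrapolated linearly with a warning. Monotonicity
(size strictly decreasing with distance) is enforced at fit time.

**Peak detection** subtracts a rolling-minimum lower envelope (window 601
samples = 30 mm at the default 0.05-mm grid; the original densitometry
software's baseline procedure is undocumented, so a standard lower-envelope
estimate is used), smooths with a quadratic Savitzky-Golay filter (window
11), and keeps local maxima whose prominence exceeds a fraction of the
profile maximum (default 5%). Apexes are refined by parabolic
interpolation, so a noiseless Gaussian band is located far below one
sample step; peak areas are integrated between the prominence-defining
valleys, which is robust to noise upticks on the flanks. A smeared band is
summarized by its apex (matching peak-density readouts) rather than its
centroid; `method = "endpoints"`-style alternatives exist where relevant.

**Copy-number estimation** is the deliberately transparent arithmetic
`copies = (size − backbone_kb) / unit_kb`; an estimated size below the
backbone raises an error, since it signals mis-calibration rather than a
meaningful negative copy number. `copy_shift()` matches the chromosome XII
peak of a later lane to the generation-0 anchor (nearest peak; ties by
larger area) and differences the two estimates under one shared
calibration.

**Band proportions** integrate baseline-subtracted signal over
user-supplied disjoint windows and normalize. Extinction (a competitor's
band disappearing) reports 0; an all-zero lane flags undefined proportions
instead of dividing by zero. ERC quantification is this same operation with
ERC vs genomic windows — no special code path.

**Bin-split SV calling.** QC keeps reads with length strictly > 8,000 nt
and arithmetic-mean Phred strictly > 18 (the thresholds are quoted as
strict inequalities, and the boundary tests pin that reading; mean quality
is averaged in Phred space, as basecaller summaries are, with an
error-probability-domain option). Reads are cut into 300-nt bins, the
sub-bin tail discarded. Each bin is mapped by exact k-mer seeding (k = 15)
into a hashed index of the unit extended circularly by one bin length, then
verified by Hamming distance (≤ 60 of 300 by default); best candidate wins,
ties to the lowest unit position, then to the forward strand. The seeded
mapper is checked test-side against an exhaustive Hamming scan of every
offset on both strands. For consecutive mapped bins the expected reference
distance is `(bin gap) × 300` — unmapped bins scale the expectation rather
than break the chain, preserving sensitivity when one noisy bin fails to
map — and the observed distance is the modulo-unit displacement lifted by
whole units toward the expectation, which makes ordinary junction crossings
in a tandem array deviation-free by construction. Deviations strictly
greater than 100 nt are called: positive = deletion, negative =
insertion/duplication. Discordant-strand pairs are flagged inversion-like
and excluded from the deviation rule. Headline summaries count deletions of
at least 50 nt and exclude insertion-type calls, which are hard to separate
from sequencing error at nanopore error rates. Note the structural gap this
inherits: the deviation rule cannot fire below its 100-nt tolerance, so
deletions of 51–100 nt are undetectable under the literal procedure; the
package follows the literal rule rather than silently tightening it.
The "distance between mapped reads" rule is read as *consecutive-bin*
distances (which localizes each event) rather than first-to-last distance.

**Variant tallying** counts bases per collapsed-unit position into
{A, C, G, T, deletion} — insertions are not a column state, matching a
naive caller's column model — with an optional base-quality floor (off by
default). Frequencies are `(coverage − ref_count)/coverage`, with
below-coverage positions reported as missing rather than zero.
`compare_spectra()` summarizes paired per-position differences with a
seeded position-resampling bootstrap; the original comparison was purely
descriptive ("comparable"), so the bootstrap interval is this package's
own, documented choice of summary, not a reproduced procedure.

**Generation accounting** equates generations with doublings:
`log2(dilution)` per liquid transfer (1,000-fold ⇒ 9.97 ≈ 10; 90 transfers
⇒ ~897, the "~900 generations" order of magnitude) and
`log2(cells per colony)` for colony passaging (1.165 × 10⁷ cells ⇒ 23.5).
This assumes every viable cell divides until saturation with no death; the
known tension between a 2^23.5-cell colony and the ~20 generations usually
quoted per colony passage is documented, not reconciled — both numbers are
exposed and neither is forced to agree. **Drift** is summarized by
per-replicate OLS slopes of copies on generation (using all time points;
an end-minus-start option exists), with signs tallied against a ±ε zero
band (default 0.01 copies/generation). **Ploidy** is classified by the
ratio of dominant DNA-content modes, where "dominant" is the peak with the
largest integrated cell mass — not the tallest bin, since at fixed CV a
lower peak is narrower and therefore taller per bin — with calls "doubled"
at 2 ± 0.2 and "unchanged" at 1 ± 0.2.

## Problem sizes used in tests

The test suite and acceptance script run the pipeline end to end at sizes
chosen to make the statistics sharp while keeping the suite quick: 50-read
sets on 4-copy full-size arrays for the mapper-oracle and deletion-recovery
checks; 50 seeded gels for the noisy round trip (tolerance ±2 copies;
noiseless ±0.5); coverage 2,000 for the 15-of-150 SNV recovery (3 binomial
SDs); 50 seeded pairs of equal-load samples for the null bootstrap
(coverage 300 on a 2-kb unit); 24 replicates × 900 generations for the
drift-direction checks; and 10⁴ cells at CV 0.05 for the ploidy ratio.

## What passing tests do and do not show

The generators encode the *statistical structure* the analyses assume —
planted truth, exact arithmetic, binomial sampling, Gaussian bands,
log-linear migration — not the messiness of real data. Passing tests
demonstrate that the procedures are implemented correctly and recover
planted truth at the stated tolerances. They do not demonstrate robustness
to basecaller-specific error structure (homopolymer bias, indel-rich
errors), gel artifacts (lane warping, comb effects, saturation), PCR
amplification bias in the sequenced rDNA, or cell-cycle structure beyond
two Gaussian DNA-content peaks. Real-data entry points (FASTQ, SAM/PAF,
lane-profile TSV) are provided precisely so the same tested code paths can
be pointed at real inputs.

## Known limitations

* The internal bin mapper is a seed-and-verify Hamming mapper for
  fixed-length bins; it does not do gapped alignment, soft-clipping or
  mapping-quality modelling. External mappings can be supplied as SAM/PAF.
* The trajectory model is phenomenological; its parameters shape direction
  and variance structure, not absolute rates.
* Deletions of 51–100 nt are invisible to the deviation rule, as discussed.
* Doublings-as-generations ignores death and incomplete regrowth.
* The unit length and backbone length used for copy-number conversion are
  configuration with documented defaults (9.1 kb, 1,050 kb); absolute copy
  numbers scale accordingly if a user changes them.
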