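test_that("reference unit construction is deterministic and validated", {
  unit <- make_reference_unit(L_unit = 9100, seed = 1)
  expect_s3_class(unit, "reference_unit")
  expect_equal(nchar(unit$sequence), 9100)
  expect_setequal(unit$elements$element, c("35S", "5S", "rARS", "E-pro", "RFB"))
  expect_true(all(unit$elements$start >= 0 & unit$elements$end <= 9100))

  expect_identical(make_reference_unit(seed = 1)$sequence,
                   make_reference_unit(seed = 1)$sequence)
  expect_false(identical(make_reference_unit(seed = 1)$sequence,
                         make_reference_unit(seed = 2)$sequence))

  expect_error(
    make_reference_unit(9100, elements = tibble::tibble(
      element = "35S", start = 9000, end = 9200)),
    "within")
  expect_error(
    make_reference_unit(9100, elements = tibble::tibble(
      element = c("35S", "5S"), start = c(0, 50), end = c(100, 120))),
    "disjoint")
})

test_that("array length arithmetic is exact and edits are validated", {
  unit <- make_reference_unit(L_unit = 9100, seed = 1)
  arr <- build_array(unit, 150, arms = c(1000, 1000), seed = 2)
  expect_equal(nchar(arr$sequence), 2000 + 150 * 9100)

  arr2 <- build_array(unit, 3,
                      deletions = tibble::tibble(copy = 2, start = 100, end = 600),
                      arms = c(1000, 1000), seed = 2)
  expect_equal(nchar(arr2$sequence), 2000 + 3 * 9100 - 500)
  expect_equal(arr2$sv_table$size, 500)
  expect_equal(arr2$sv_table$global_pos, 1000 + 9100 + 100)

  expect_error(
    build_array(unit, 3, snvs = tibble::tibble(copy = 5, pos = 10, alt = "A")),
    "edit")
  expect_error(
    build_array(unit, 3, deletions = tibble::tibble(copy = 1, start = 9000,
                                                    end = 9200)),
    "edit|Deletion")
})

test_that("arrays round-trip through FASTA", {
  unit <- small_unit()
  arr <- build_array(unit, 4, arms = c(200, 200), seed = 3)
  path <- withr::local_tempfile(fileext = ".fa")
  write_array_fasta(arr, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_identical(as.character(back[[1]]), arr$sequence)
})

test_that("error-free reads are exact substrings of the truth array", {
  unit <- small_unit()
  arr <- build_array(unit, 8, arms = c(500, 500), seed = 4)
  rd <- simulate_long_reads(
    arr, 30, length_law = list(meanlog = log(3000), sdlog = 0.3,
                               min = 1500, max = 8000),
    error_rate = 0, seed = 5)
  for (i in seq_len(nrow(rd))) {
    fwd <- if (rd$strand[i] == "+") rd$sequence[i] else {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rd$sequence[i])))
    }
    expect_identical(
      fwd, substr(arr$sequence, rd$origin_start[i] + 1, rd$origin_end[i]))
  }
})

test_that("FASTQ output is byte-identical under a fixed seed and round-trips", {
  unit <- small_unit()
  arr <- build_array(unit, 4, arms = c(300, 300), seed = 4)
  law <- list(meanlog = log(2500), sdlog = 0.3, min = 1200, max = 6000)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_reads_fastq(simulate_long_reads(arr, 10, law, 0.02, seed = 7), f1)
  write_reads_fastq(simulate_long_reads(arr, 10, law, 0.02, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_reads_fastq(f1)
  orig <- simulate_long_reads(arr, 10, law, 0.02, seed = 7)
  expect_identical(back$sequence, orig$sequence)
  expect_identical(back$quals, orig$quals)
})

test_that("simulated substitution errors match the requested rate", {
  unit <- small_unit()
  arr <- build_array(unit, 10, arms = c(500, 500), seed = 4)
  rd <- simulate_long_reads(
    arr, 200, length_law = list(meanlog = log(3000), sdlog = 0.2,
                                min = 2000, max = 6000),
    error_rate = 0.05, rc_prob = 0, seed = 8)
  n_mm <- 0L; n_bases <- 0L
  for (i in seq_len(nrow(rd))) {
    truth <- substr(arr$sequence, rd$origin_start[i] + 1, rd$origin_end[i])
    n_mm <- n_mm + sum(utf8ToInt(rd$sequence[i]) != utf8ToInt(truth))
    n_bases <- n_bases + rd$length[i]
  }
  p_hat <- n_mm / n_bases
  tol <- 3 * sqrt(0.05 * 0.95 / n_bases)
  expect_lt(abs(p_hat - 0.05), tol)
})

test_that("pileup counts conserve coverage and recover planted allele fractions", {
  unit <- make_reference_unit(seed = 1)
  clean <- build_array(unit, 10, seed = 2)
  pu0 <- simulate_pileup(clean, coverage = 50, error_rate = 0, seed = 3)
  expect_true(all(pu0$A + pu0$C + pu0$G + pu0$T + pu0$del == pu0$coverage))
  ref_count <- as.matrix(pu0[, c("A", "C", "G", "T")])[
    cbind(seq_len(nrow(pu0)), match(pu0$ref, c("A", "C", "G", "T")))]
  expect_true(all(ref_count == pu0$coverage))  # no SNVs, no errors

  arr <- build_array(unit, 150,
                     snvs = tibble::tibble(copy = 1:15, pos = 4000,
                                           alt = "A"), seed = 2)
  stopifnot(substr(unit$sequence, 4001, 4001) != "A")
  pu <- simulate_pileup(arr, coverage = 1000, error_rate = 0, seed = 4)
  f <- pu$A[pu$pos == 4000] / 1000
  expect_lt(abs(f - 0.10), 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("gel lanes encode copy number and population heterogeneity", {
  truth_cal <- default_gel_calibration()
  gel <- simulate_gel_lanes(list(clonal = 150), noise_sd = 0, seed = 1)
  # marker apexes reproduce the ladder
  mp <- find_peaks(gel_lane(gel, "marker"), min_prominence = 0.2)
  expect_equal(nrow(mp), 7)
  expect_equal(mp$distance_mm,
               sort(distance_for_size(truth_cal,
                                      default_hwingei_ladder()$size_kb)),
               tolerance = 1e-3)
  # clonal apex maps back to the planted copy number by construction
  pk <- find_peaks(gel_lane(gel, "clonal"))
  size <- predict(truth_cal, pk$distance_mm[which.max(pk$area)])
  expect_equal((size - 1050) / 9.1, 150, tolerance = 0.01)

  # a broad copy distribution gives a wider band than a clonal one
  withr::with_seed(9, {
    smear <- sample(100:200, 400, replace = TRUE)
  })
  g2 <- simulate_gel_lanes(list(u = smear, c = 150), noise_sd = 0, seed = 2)
  pu <- find_peaks(gel_lane(g2, "u"))
  pc <- find_peaks(gel_lane(g2, "c"))
  expect_gt(pu$fwhm_mm[which.max(pu$area)], pc$fwhm_mm[which.max(pc$area)])
})

test_that("trajectories respect the copy floor and a zero rate freezes them", {
  p0 <- sim_params(recomb_rate = 1e-12)
  tr <- simulate_trajectory(p0, "WT", n_replicates = 2, n_generations = 100,
                            seed = 1)
  expect_true(all(tr$copies == 150))

  p <- sim_params(deletion_bias = 30, step_sd = 10)
  tr2 <- simulate_trajectory(p, "fob1d", n_replicates = 4,
                             n_generations = 400, seed = 2)
  expect_true(all(tr2$copies >= p$min_viable))
})

test_that("trajectory generations are recorded from 0 and reproducible", {
  p <- sim_params()
  tr <- simulate_trajectory(p, "fob1d", n_replicates = 2, n_generations = 95,
                            record_every = 10, seed = 3)
  gens <- sort(unique(tr$generation))
  expect_equal(gens[1], 0)
  expect_true(all(diff(gens) > 0))
  expect_equal(max(gens), 95)
  expect_identical(tr, simulate_trajectory(p, "fob1d", n_replicates = 2,
                                           n_generations = 95,
                                           record_every = 10, seed = 3))
})

test_that("DNA-content histograms conserve cells and are reproducible", {
  h <- simulate_facs(1, n_cells = 5000, seed = 4)
  expect_equal(sum(h$count), 5000)
  expect_true(all(diff(h$fluorescence) > 0))
  expect_identical(h, simulate_facs(1, n_cells = 5000, seed = 4))
})
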