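test_that("read QC applies strict length and mean-quality thresholds", {
  mk <- function(len, q) tibble::tibble(
    read_id = "r", sequence = strrep("A", len),
    quals = list(rep(q, max(len, 1))), length = len,
    mean_q = mean(rep(q, max(len, 1))))
  p <- sim_params()
  expect_false(qc_filter(mk(8000, 30), p)$qc_pass)   # length not strictly >
  expect_false(qc_filter(mk(8001, 18), p)$qc_pass)   # mean Q not strictly >
  expect_true(qc_filter(dplyr::mutate(mk(8001, 18), mean_q = 18.01), p)$qc_pass)
  expect_true(qc_filter(mk(12000, 25), p)$qc_pass)
  empty <- tibble::tibble(read_id = "e", sequence = "", quals = list(integer()),
                          length = 0L, mean_q = NaN)
  out <- qc_filter(empty, p)
  expect_false(out$qc_pass)
  expect_equal(out$qc_reason, "empty")
})

test_that("bin splitting drops the tail and reconstructs the prefix", {
  s <- small_unit(L = 8999, seed = 2)$sequence
  bins <- split_bins(s, 300)
  expect_length(bins, 29)
  expect_true(all(nchar(bins) == 300))
  expect_identical(paste(bins, collapse = ""), substr(s, 1, 29 * 300))

  s2 <- substr(s, 1, 9000)  # length 8999; extend by one for exact multiple
  bins2 <- split_bins(paste0(s, "A"), 300)
  expect_length(bins2, 30)
})

test_that("bin mapping wraps the circular unit and matches the exhaustive oracle", {
  unit <- make_reference_unit(seed = 21)
  idx <- unit_index(unit)

  # wrap past the origin
  wrap_bin <- paste0(substr(unit$sequence, 8951, 9100),
                     substr(unit$sequence, 1, 150))
  hit <- map_bin(wrap_bin, idx)
  expect_true(hit$mapped)
  expect_equal(hit$unit_pos, 8950)
  expect_equal(hit$mismatches, 0)

  # planted mismatches are counted and agree with the oracle
  b <- substr(unit$sequence, 3001, 3300)
  b2 <- b
  for (i in c(50, 200)) {
    old <- substr(b2, i, i)
    substr(b2, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  hit2 <- map_bin(b2, idx, max_mismatch = 5)
  expect_true(hit2$mapped)
  expect_equal(hit2$mismatches, 2)
  expect_equal(hit2$unit_pos, 3000)
  expect_identical(as.data.frame(hit2),
                   as.data.frame(oracle_map_bin(b2, unit, max_mismatch = 5)))

  # a random 300-mer maps nowhere, confirmed by the oracle
  withr::with_seed(5, {
    rand <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  })
  miss <- map_bin(rand, idx)
  expect_false(miss$mapped)
  expect_false(oracle_map_bin(rand, unit)$mapped)

  # reverse-strand bins report the forward position of their complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(unit$sequence, 5001, 5300))))
  hit3 <- map_bin(rc, idx)
  expect_equal(hit3$strand, "-")
  expect_equal(hit3$unit_pos, 5000)
})

test_that("seeded mapping equals the exhaustive scan over a synthetic read set", {
  unit <- small_unit(L = 3000, seed = 22)
  arr <- build_array(unit, 6,
                     deletions = tibble::tibble(copy = 3, start = 500,
                                                end = 900),
                     arms = c(400, 400), seed = 23)
  rd <- simulate_long_reads(
    arr, 10, length_law = list(meanlog = log(4000), sdlog = 0.2,
                               min = 2500, max = 8000),
    error_rate = 0.03, seed = 24)
  idx <- unit_index(unit)
  for (i in seq_len(nrow(rd))) {
    for (b in split_bins(rd$sequence[i], 300)) {
      expect_identical(as.data.frame(map_bin(b, idx)),
                       as.data.frame(oracle_map_bin(b, unit)))
    }
  }
})

test_that("the deviation rule is strict at the 100-nt boundary", {
  aln <- function(pos2) tibble::tibble(
    bin = c(0L, 1L), read_offset = c(0L, 300L),
    unit_pos = c(1000L, pos2), strand = "+",
    mismatches = 0L, mapped = TRUE)
  p <- sim_params()
  expect_equal(nrow(call_read_sv(aln(1300L), p, L_unit = 9100)), 0)  # exact
  expect_equal(nrow(call_read_sv(aln(1400L), p, L_unit = 9100)), 0)  # dev 100
  calls <- call_read_sv(aln(1401L), p, L_unit = 9100)                # dev 101
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "deletion")
  expect_equal(calls$size, 101)
})

test_that("junction crossings, gaps, strands and degenerate chains behave", {
  p <- sim_params()
  # crossing the unit junction in a tandem array is deviation-free
  junc <- tibble::tibble(bin = c(0L, 1L), read_offset = c(0L, 300L),
                         unit_pos = c(9000L, 200L), strand = "+",
                         mismatches = 0L, mapped = TRUE)
  expect_equal(nrow(call_read_sv(junc, p, L_unit = 9100)), 0)

  # an unmapped bin scales the expected distance instead of dropping the pair
  gap <- tibble::tibble(bin = c(0L, 2L), read_offset = c(0L, 600L),
                        unit_pos = c(1000L, 2300L), strand = "+",
                        mismatches = 0L, mapped = TRUE)
  calls <- call_read_sv(gap, p, L_unit = 9100)
  expect_equal(calls$size, 700)
  expect_equal(calls$type, "deletion")

  # reverse-strand pairs step backwards through unit coordinates
  rev <- tibble::tibble(bin = c(0L, 1L), read_offset = c(0L, 300L),
                        unit_pos = c(2000L, 1700L), strand = "-",
                        mismatches = 0L, mapped = TRUE)
  expect_equal(nrow(call_read_sv(rev, p, L_unit = 9100)), 0)

  # mixed strands are flagged, not called
  mixed <- tibble::tibble(bin = c(0L, 1L), read_offset = c(0L, 300L),
                          unit_pos = c(1000L, 1300L), strand = c("+", "-"),
                          mismatches = 0L, mapped = TRUE)
  out <- call_read_sv(mixed, p, L_unit = 9100)
  expect_equal(out$type, "inversion-like")

  # fewer than two mapped bins is uninformative
  single <- tibble::tibble(bin = 0L, read_offset = 0L, unit_pos = 1000L,
                           strand = "+", mismatches = 0L, mapped = TRUE)
  res <- call_read_sv(single, p, L_unit = 9100)
  expect_equal(nrow(res), 0)
  expect_true(isTRUE(attr(res, "uninformative")))
})

test_that("planted deletions are recovered exactly; clean arrays yield no calls", {
  unit <- make_reference_unit(seed = 31)
  p <- sim_params()
  law <- list(meanlog = log(11000), sdlog = 0.15, min = 8500, max = 20000)
  qhigh <- list(mean = 30, sd = 1, base_sd = 1)

  clean <- build_array(unit, 5, arms = c(1000, 1000), seed = 32)
  rd0 <- simulate_long_reads(clean, 12, law, error_rate = 0, q_law = qhigh,
                             seed = 33)
  s0 <- summarize_sample(rd0, unit, p)
  expect_equal(s0$summary$sv_read_fraction, 0)
  expect_equal(nrow(s0$calls), 0)

  del <- build_array(unit, 5,
                     deletions = tibble::tibble(copy = 3, start = 2000,
                                                end = 2500),
                     arms = c(1000, 1000), seed = 32)
  rd1 <- simulate_long_reads(del, 15, law, error_rate = 0, q_law = qhigh,
                             seed = 34)
  s1 <- summarize_sample(rd1, unit, p)
  margin <- 2 * p$bin_len
  spanning <- vapply(seq_len(nrow(rd1)), function(i) {
    sv <- rd1$svs[[i]]
    nrow(sv) > 0 && all(sv$global_pos - rd1$origin_start[i] >= margin) &&
      all(rd1$origin_end[i] - sv$global_pos >= margin)
  }, logical(1))
  qc <- qc_filter(rd1, p)$qc_pass
  for (id in rd1$read_id[spanning & qc]) {
    cl <- s1$calls[s1$calls$read_id == id, ]
    expect_equal(nrow(cl), 1)
    expect_equal(cl$type, "deletion")
    expect_equal(cl$size, 500)
  }
  expect_gt(sum(spanning & qc), 0)

  # filter-chain counts weakly decreasing
  s <- s1$summary
  expect_true(s$n_reads >= s$n_pass_qc && s$n_pass_qc >= s$n_analyzed &&
                s$n_analyzed >= s$n_sv_reads)
})

test_that("SAM and PAF import reproduce the internal mapper's calls", {
  unit <- small_unit(L = 3000, seed = 41)
  arr <- build_array(unit, 6,
                     deletions = tibble::tibble(copy = 2, start = 800,
                                                end = 1200),
                     arms = c(400, 400), seed = 42)
  rd <- simulate_long_reads(
    arr, 10, length_law = list(meanlog = log(4000), sdlog = 0.15,
                               min = 3000, max = 7000),
    error_rate = 0, q_law = list(mean = 30, sd = 1, base_sd = 1), seed = 43)
  idx <- unit_index(unit)
  aln <- purrr::map_dfr(seq_len(nrow(rd)), function(i) {
    dplyr::mutate(map_read_bins(rd$sequence[i], idx),
                  read_id = rd$read_id[i], .before = 1)
  })
  p <- sim_params(min_read_len = 1000, min_mean_q = 10)
  internal <- summarize_sample(rd, unit, p)

  sam <- withr::local_tempfile(fileext = ".sam")
  write_bin_sam(aln, unit, sam)
  from_sam <- summarize_sample(rd, unit, p,
                               alignments = read_bin_sam(sam, unit))
  expect_identical(as.data.frame(internal$calls), as.data.frame(from_sam$calls))

  paf <- withr::local_tempfile(fileext = ".paf")
  write_bin_paf(aln, unit, paf)
  from_paf <- summarize_sample(rd, unit, p,
                               alignments = read_bin_paf(paf, unit))
  expect_identical(as.data.frame(internal$calls), as.data.frame(from_paf$calls))
})
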