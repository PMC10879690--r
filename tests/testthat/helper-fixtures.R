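# Shared fixtures: a small repeat unit keeps most tests fast; the
# full-size 9.1-kb unit is built only where geometry matters.

small_unit <- function(L = 2000, seed = 11) {
  make_reference_unit(
    L_unit = L,
    elements = tibble::tibble(
      element = c("35S", "5S", "rARS", "E-pro", "RFB"),
      start = round(c(0.1, 0.6, 0.7, 0.8, 0.9) * L),
      end = round(c(0.55, 0.63, 0.75, 0.83, 0.93) * L)),
    seed = seed)
}

# Independent exhaustive oracle for bin mapping: Hamming distance at every
# unit offset on both strands via Biostrings, with the same tie rules as
# the seeded mapper (fewest mismatches; lowest position; '+' over '-').
oracle_map_bin <- function(bin, unit, bin_len = nchar(bin), max_mismatch = 60) {
  ext <- Biostrings::DNAString(
    paste0(unit$sequence, substr(unit$sequence, 1, bin_len)))
  L <- unit$L_unit
  best <- list(pos = NA_integer_, strand = NA_character_, mm = Inf)
  for (strand in c("+", "-")) {
    b <- if (strand == "+") bin else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(bin)))
    }
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(b), ext,
                                      starting.at = seq_len(L),
                                      with.indels = FALSE)
    i <- which.min(mm)
    if (mm[i] <= max_mismatch && mm[i] < best$mm) {
      best <- list(pos = i - 1L, strand = strand, mm = mm[i])
    }
  }
  mapped <- is.finite(best$mm)
  tibble::tibble(
    unit_pos = if (mapped) as.integer(best$pos) else NA_integer_,
    strand = if (mapped) best$strand else NA_character_,
    mismatches = if (mapped) as.integer(best$mm) else NA_integer_,
    mapped = mapped)
}

# A marker calibration refit from a noiseless simulated marker lane.
fitted_marker_calibration <- function(gel) {
  mp <- find_peaks(gel_lane(gel, "marker"), min_prominence = 0.2)
  stopifnot(nrow(mp) == 7)
  fit_ladder(tibble::tibble(
    distance_mm = mp$distance_mm,
    size_kb = sort(default_hwingei_ladder()$size_kb, decreasing = TRUE)))
}
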