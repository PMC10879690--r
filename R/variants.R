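#' Per-position base tallies over the collapsed repeat unit
#'
#' Naive variant tallying: every aligned base is counted into its unit
#' position's {A, C, G, T, deletion} column with no genotyping model.
#' Accepts either a pileup table produced by [simulate_pileup()] (validated
#' and passed through) or a SAM file of reads mapped to the unit, which is
#' piled up with Rsamtools. Because all array copies collapse onto one unit
#' coordinate system, a variant carried by k of n copies appears at
#' frequency ~ k/n.
#'
#' @param x Pileup tibble (`pos`, `ref`, `A`, `C`, `G`, `T`, `del`,
#'   `coverage`) or a path to a SAM file.
#' @param unit The [reference_unit][make_reference_unit] (required for the
#'   SAM path; used to fill reference bases and complete empty positions).
#' @param min_base_quality Optional Phred floor for counted bases (SAM path
#'   only; default 0, i.e. disabled).
#' @return Pileup tibble with one row per unit position.
#' @export
tally <- function(x, unit = NULL, min_base_quality = 0) {
  if (is_tibble(x) || is.data.frame(x)) {
    x <- as_tibble(x)
    need <- c("pos", "ref", "A", "C", "G", "T", "del", "coverage")
    stopifnot(all(need %in% names(x)))
    counted <- x$A + x$C + x$G + x$T + x$del
    if (!all(counted == x$coverage)) {
      abort("Pileup counts must sum to coverage at every position.")
    }
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1)
  if (is.null(unit)) abort("`unit` is required when tallying a SAM file.")
  bam <- Rsamtools::asBam(x, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  pp <- Rsamtools::PileupParam(
    max_depth = 1e6L, min_base_quality = as.integer(min_base_quality),
    min_mapq = 0L, min_nucleotide_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = TRUE,
    include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  ref <- strsplit(unit$sequence, "")[[1]]
  wide <- tidyr::pivot_wider(
    tibble(pos = p$pos - 1L, nucleotide = as.character(p$nucleotide),
           count = p$count),
    names_from = "nucleotide", values_from = "count", values_fill = 0L,
    values_fn = sum)
  full <- tibble(pos = 0:(unit$L_unit - 1L), ref = ref)
  full <- dplyr::left_join(full, wide, by = "pos")
  for (b in c(DNA_BASES, "-")) {
    if (!b %in% names(full)) full[[b]] <- 0L
  }
  out <- dplyr::transmute(full,
    pos = .data$pos, ref = .data$ref,
    A = dplyr::coalesce(.data$A, 0L), C = dplyr::coalesce(.data$C, 0L),
    G = dplyr::coalesce(.data$G, 0L), T = dplyr::coalesce(.data$T, 0L),
    del = dplyr::coalesce(.data$`-`, 0L))
  dplyr::mutate(out, coverage = .data$A + .data$C + .data$G + .data$T + .data$del)
}

#' Non-reference variant frequencies per unit position
#'
#' For every position with coverage at least `min_coverage`, the frequency
#' of reads disagreeing with the reference base,
#' `(coverage - ref_count) / coverage`. Positions below the coverage floor
#' are reported as missing (`NA`), not zero.
#'
#' @param columns Pileup tibble from [tally()].
#' @param min_coverage Minimum coverage to report a frequency.
#' @return Tibble `pos`, `ref`, `coverage`, `freq`.
#' @export
frequencies <- function(columns, min_coverage = 1) {
  columns <- tally(columns)  # re-validates
  cnt <- as.matrix(columns[, c(DNA_BASES, "del")])
  ref_count <- cnt[cbind(seq_len(nrow(columns)), match(columns$ref, DNA_BASES))]
  freq <- ifelse(columns$coverage >= min_coverage & columns$coverage > 0,
                 (columns$coverage - ref_count) / columns$coverage, NA_real_)
  tibble(pos = columns$pos, ref = columns$ref,
         coverage = columns$coverage, freq = freq)
}

#' Compare two variant-frequency spectra
#'
#' Pairs positions covered in both spectra and summarises the per-position
#' frequency differences (`b - a`): the mean difference, a seeded bootstrap
#' percentile interval obtained by resampling positions, and the positions
#' whose absolute difference exceeds a reporting floor. The paper-style
#' question — is one sample accumulating more variants than the other? —
#' reduces to whether the interval covers zero.
#'
#' @param a,b Spectra from [frequencies()] over the same unit coordinates.
#' @param n_boot Bootstrap resamples.
#' @param conf Interval coverage (default 0.95).
#' @param floor Reporting floor for per-position differences.
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `mean_diff`, `ci_lo`, `ci_hi`, `n_positions`,
#'   `n_exceed_floor`, `covers_zero`; attribute `"sites"` holds the
#'   positions exceeding the floor.
#' @export
compare_spectra <- function(a, b, n_boot = 1000, conf = 0.95, floor = 0.05,
                            seed = NULL) {
  j <- dplyr::inner_join(
    dplyr::select(as_tibble(a), "pos", freq_a = "freq"),
    dplyr::select(as_tibble(b), "pos", freq_b = "freq"),
    by = "pos")
  j <- dplyr::filter(j, !is.na(.data$freq_a), !is.na(.data$freq_b))
  if (!nrow(j)) abort("No jointly covered positions.")
  d <- j$freq_b - j$freq_a
  local_seed(seed)
  boot <- vapply(seq_len(n_boot),
                 function(i) mean(d[sample.int(length(d), replace = TRUE)]),
                 numeric(1))
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  sites <- j[abs(d) > floor, ]
  out <- tibble(mean_diff = mean(d), ci_lo = qs[1], ci_hi = qs[2],
                n_positions = nrow(j), n_exceed_floor = nrow(sites),
                covers_zero = qs[1] <= 0 && 0 <= qs[2])
  attr(out, "sites") <- sites
  out
}

#' Write a variant spectrum as TSV
#'
#' @param spectrum Tibble from [frequencies()].
#' @param path TSV path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  readr::write_tsv(spectrum, path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(ref = readr::col_character()))
}
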