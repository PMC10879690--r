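#' Simulate a flow-cytometry DNA-content histogram
#'
#' An asynchronous culture shows two DNA-content peaks, pre-replication
#' (1C of the given ploidy) and post-replication (2C), at `ploidy * u` and
#' `2 * ploidy * u` for a fixed unit fluorescence `u`. Peak spread is a
#' Gaussian with coefficient of variation `peak_cv`. Counts are binned on a
#' fixed fluorescence grid; every cell lands in a bin, so counts sum to
#' `n_cells`.
#'
#' @param ploidy 1 or 2.
#' @param n_cells Number of cells.
#' @param peak_cv Coefficient of variation of each peak.
#' @param unit_fluor Fluorescence of one haploid genome equivalent (a.u.).
#' @param g2_fraction Fraction of cells post-replication (the 2C peak
#'   dominates in these cultures).
#' @param bin_width Histogram bin width (a.u.).
#' @param seed Integer seed.
#' @return Tibble `fluorescence` (bin centres, increasing), `count`.
#' @export
simulate_facs <- function(ploidy, n_cells = 10000, peak_cv = 0.05,
                          unit_fluor = 100, g2_fraction = 0.6,
                          bin_width = 4, seed = NULL) {
  stopifnot(ploidy %in% c(1, 2))
  assert_scalar_pos(peak_cv, "peak_cv")
  assert_scalar_pos(n_cells, "n_cells")
  local_seed(seed)
  g2 <- runif(n_cells) < g2_fraction
  mu <- ploidy * unit_fluor * ifelse(g2, 2, 1)
  x <- rnorm(n_cells, mu, peak_cv * mu)
  top <- max(4.5 * unit_fluor * 2, max(x))  # fixed support, ploidy-independent
  x <- pmin(pmax(x, 0), top)
  edges <- seq(0, top + bin_width, by = bin_width)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  tibble(fluorescence = head(edges, -1) + bin_width / 2, count = counts)
}

#' Write / read DNA-content histograms as TSV
#'
#' @param hist Histogram tibble (`fluorescence`, `count`).
#' @param path TSV path.
#' @export
write_facs_tsv <- function(hist, path) {
  readr::write_tsv(hist, path)
  invisible(path)
}

#' @rdname write_facs_tsv
#' @export
read_facs_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
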