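#' Generations per serial-dilution transfer
#'
#' Regrowth to saturation after an f-fold dilution takes `log2(f)` cell
#' doublings; a 1,000-fold transfer is therefore ~10 generations.
#'
#' @param dilution_factor Fold dilution per transfer (> 1).
#' @param round_generations Round to the nearest integer?
#' @return Doublings per transfer.
#' @examples
#' generations_per_transfer(1000)                  # 9.97
#' generations_per_transfer(1000, round_generations = TRUE)  # 10
#' @export
generations_per_transfer <- function(dilution_factor, round_generations = FALSE) {
  if (any(dilution_factor <= 1)) {
    abort("`dilution_factor` must be > 1 (no growth implied otherwise).")
  }
  g <- log2(dilution_factor)
  if (round_generations) round(g) else g
}

#' Generations represented by a single colony
#'
#' A colony of n cells founded by one cell represents `log2(n)` doublings.
#'
#' @param cells_per_colony Cell count of the colony (>= 1).
#' @return Doublings.
#' @examples
#' colony_generations(1.165e7)  # 23.5
#' @export
colony_generations <- function(cells_per_colony) {
  if (any(cells_per_colony < 1)) abort("`cells_per_colony` must be >= 1.")
  log2(cells_per_colony)
}

#' Per-replicate drift of copy-number trajectories
#'
#' Fits an ordinary least-squares slope of copies on generation for each
#' replicate (summing homologs when present) and tallies slope signs using
#' a zero band of +/- `epsilon` copies/generation. Wild-type cultures show
#' no consistent direction; fork-barrier-deficient cultures drift negative.
#'
#' @param traj Trajectory tibble with columns `replicate`, `generation`,
#'   `copies` (and optionally `homolog`).
#' @param epsilon Half-width of the zero band (copies per generation).
#' @param method `"ols"` (slope over all time points) or `"endpoints"`
#'   (end minus start, divided by elapsed generations).
#' @return A `drift_summary`: list with `slopes` (tibble `replicate`,
#'   `slope`, `sign`), `tally`, `epsilon`, `method`. Has [tidy()] and
#'   [glance()] methods.
#' @export
estimate_drift <- function(traj, epsilon = 0.01, method = c("ols", "endpoints")) {
  method <- match.arg(method)
  traj <- as_tibble(traj)
  stopifnot(all(c("replicate", "generation", "copies") %in% names(traj)))
  tot <- dplyr::summarise(dplyr::group_by(traj, .data$replicate, .data$generation),
                          copies = sum(.data$copies), .groups = "drop")
  if (min(table(tot$replicate)) < 3) {
    abort("Need >= 3 time points per replicate.")
  }
  slopes <- dplyr::summarise(
    dplyr::group_by(tot, .data$replicate),
    slope = if (method == "ols") {
      unname(coef(lm(copies ~ generation))[2])
    } else {
      (copies[which.max(generation)] - copies[which.min(generation)]) /
        (max(generation) - min(generation))
    },
    .groups = "drop"
  )
  slopes$sign <- dplyr::case_when(
    slopes$slope < -epsilon ~ "negative",
    slopes$slope > epsilon ~ "positive",
    TRUE ~ "zero"
  )
  tally <- c(negative = sum(slopes$sign == "negative"),
             zero = sum(slopes$sign == "zero"),
             positive = sum(slopes$sign == "positive"))
  structure(list(slopes = slopes, tally = tally, epsilon = epsilon,
                 method = method),
            class = "drift_summary")
}

#' @export
print.drift_summary <- function(x, ...) {
  cat(sprintf("<drift_summary> %d replicates (%s): %d negative, %d zero, %d positive (eps = %g copies/gen)\n",
              nrow(x$slopes), x$method, x$tally["negative"], x$tally["zero"],
              x$tally["positive"], x$epsilon))
  invisible(x)
}

#' @export
tidy.drift_summary <- function(x, ...) x$slopes

#' @export
glance.drift_summary <- function(x, ...) {
  tibble(n_replicates = nrow(x$slopes),
         n_negative = unname(x$tally["negative"]),
         n_zero = unname(x$tally["zero"]),
         n_positive = unname(x$tally["positive"]),
         mean_slope = mean(x$slopes$slope),
         method = x$method)
}

# Dominant mode = the peak containing the most cells (largest integrated
# area), not the tallest bin: at fixed coefficient of variation a
# lower-fluorescence peak is narrower and so taller per bin.
facs_dominant_mode <- function(hist, smooth_window = 5) {
  stopifnot(all(c("fluorescence", "count") %in% names(hist)))
  if (any(diff(hist$fluorescence) <= 0)) abort("Bins must be strictly increasing.")
  if (sum(hist$count) <= 0) abort("Histogram has no counts.")
  pk <- find_peaks(
    tibble(distance_mm = hist$fluorescence, intensity = hist$count),
    min_prominence = 0.2, baseline_window = NULL,
    smooth_window = smooth_window)
  if (!nrow(pk)) abort("No detectable peak in the histogram.")
  pk$distance_mm[which.max(pk$area)]
}

#' Classify ploidy change from DNA-content histograms
#'
#' Compares the dominant-mode fluorescence of a sample against a reference
#' culture: a ratio near 2 indicates DNA content has doubled
#' (diploidization), near 1 unchanged, anything else ambiguous.
#'
#' @param sample,reference Histogram tibbles (`fluorescence`, `count`).
#' @param delta Half-width of the acceptance windows around 1 and 2.
#' @return One-row tibble: `ratio`, `mode_sample`, `mode_reference`, `call`.
#' @export
classify_ploidy <- function(sample, reference, delta = 0.2) {
  ms <- facs_dominant_mode(sample)
  mr <- facs_dominant_mode(reference)
  ratio <- ms / mr
  call <- if (abs(ratio - 2) <= delta) "doubled"
          else if (abs(ratio - 1) <= delta) "unchanged"
          else "ambiguous"
  tibble(ratio = ratio, mode_sample = ms, mode_reference = mr, call = call)
}
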