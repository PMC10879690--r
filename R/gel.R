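#' Fit a migration calibration from ladder marker bands
#'
#' Pulsed-field gels are calibrated by interpolating log10(size) linearly
#' against migration distance between marker bands, the standard treatment
#' for chromosomal ladders (here Hansenula wingei chromosomes). Evaluating
#' at a knot returns its size exactly; outside the knot range the terminal
#' segment is extrapolated linearly with a warning.
#'
#' @param markers Tibble with columns `distance_mm`, `size_kb` (one row per
#'   marker band). Size must strictly decrease with distance.
#' @return A `migration_calibration` object.
#' @examples
#' cal <- fit_ladder(tibble::tibble(distance_mm = c(10, 20),
#'                                  size_kb = c(1000, 100)))
#' predict(cal, 15)  # ~316.23 kb
#' @export
fit_ladder <- function(markers) {
  markers <- as_tibble(markers)
  stopifnot(all(c("distance_mm", "size_kb") %in% names(markers)))
  if (nrow(markers) < 2) abort("Need at least 2 marker bands.")
  if (anyDuplicated(markers$distance_mm)) abort("Marker distances must be distinct.")
  markers <- dplyr::arrange(markers, .data$distance_mm)
  if (any(diff(markers$size_kb) >= 0)) {
    abort("Calibration error: size must strictly decrease with distance.")
  }
  structure(
    list(knots = markers, method = "piecewise-linear log10(size) vs distance"),
    class = "migration_calibration"
  )
}

#' @export
print.migration_calibration <- function(x, ...) {
  cat(sprintf("<migration_calibration> %d knots, %s\n", nrow(x$knots), x$method))
  invisible(x)
}

#' @export
tidy.migration_calibration <- function(x, ...) x$knots

# Piecewise-linear interpolation with terminal-segment extrapolation.
interp_extrap <- function(x, y, xout, what) {
  n <- length(x)
  out <- approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    out[lo] <- y[1] + (xout[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  }
  if (any(hi)) {
    out[hi] <- y[n] + (xout[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  }
  if (any(lo | hi)) {
    warn(sprintf("%d point(s) outside the ladder range; terminal segment extrapolated (%s).",
                 sum(lo | hi), what))
  }
  out
}

#' Evaluate a migration calibration
#'
#' @param object A `migration_calibration`.
#' @param distance_mm Migration distances to convert to sizes.
#' @param ... Unused.
#' @return Sizes in kb.
#' @export
predict.migration_calibration <- function(object, distance_mm, ...) {
  k <- object$knots
  10^interp_extrap(k$distance_mm, log10(k$size_kb), distance_mm, "size lookup")
}

#' Inverse calibration: migration distance for a given size
#'
#' @param cal A `migration_calibration`.
#' @param size_kb Sizes in kb.
#' @return Distances in mm.
#' @export
distance_for_size <- function(cal, size_kb) {
  k <- cal$knots
  # distance is strictly increasing in -log10(size)
  interp_extrap(rev(log10(k$size_kb)), rev(k$distance_mm), log10(size_kb),
                "distance lookup")
}

#' Detect bands in a 1-D gel lane profile
#'
#' Estimates the baseline as a rolling-minimum lower envelope, subtracts it,
#' optionally smooths (Savitzky-Golay), and reports local maxima whose
#' prominence exceeds a fraction of the profile maximum. Apex positions are
#' refined by parabolic interpolation through the three samples around each
#' maximum, so a noiseless Gaussian band is located to well below one sample
#' step.
#'
#' @param lane Tibble with columns `distance_mm` (strictly increasing) and
#'   `intensity` (non-negative).
#' @param min_prominence Prominence threshold as a fraction of the maximum
#'   baseline-subtracted intensity.
#' @param baseline_window Rolling-minimum window (samples); `NULL` disables
#'   baseline subtraction.
#' @param smooth_window Savitzky-Golay window (odd, samples); `NULL` disables
#'   smoothing.
#' @return Tibble of peaks ordered by distance: `distance_mm`, `intensity`,
#'   `prominence`, `fwhm_mm`, `area`.
#' @export
find_peaks <- function(lane, min_prominence = 0.05,
                       baseline_window = 601, smooth_window = 11) {
  lane <- as_tibble(lane)
  stopifnot(all(c("distance_mm", "intensity") %in% names(lane)))
  d <- lane$distance_mm
  y <- lane$intensity
  n <- length(y)
  if (n == 0) abort("Empty lane profile.")
  if (any(diff(d) <= 0)) abort("`distance_mm` must be strictly increasing.")

  if (!is.null(baseline_window) && n > baseline_window) {
    base <- zoo::rollapply(y, baseline_window, min, partial = TRUE)
    y <- y - base
  }
  if (!is.null(smooth_window) && n > smooth_window) {
    y <- signal::sgolayfilt(y, p = 2, n = smooth_window)
  }
  y <- pmax(y, 0)
  ymax <- max(y)
  if (ymax <= 0) return(empty_peaks())

  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  if (!length(idx)) return(empty_peaks())

  peaks <- purrr::map(idx, function(i) {
    # prominence: descend each side until a strictly higher sample; key col
    # is the lower of the two side minima's maximum
    if (i > 1) {
      stop_at <- which(y[seq_len(i - 1)] > y[i])
      l0 <- if (length(stop_at)) max(stop_at) + 1L else 1L
      lo <- l0 + which.min(y[l0:(i - 1)]) - 1L
      left <- y[lo]
    } else {
      lo <- i; left <- y[i]
    }
    if (i < n) {
      ahead <- y[(i + 1):n]
      stop_at <- which(ahead > y[i])
      h0 <- if (length(stop_at)) i + min(stop_at) - 1L else n
      hi <- i + which.min(y[(i + 1):h0])
      right <- y[hi]
    } else {
      hi <- i; right <- y[i]
    }
    prom <- y[i] - max(left, right)
    if (prom < min_prominence * ymax) return(NULL)

    # parabolic apex refinement
    apex <- d[i]
    if (i > 1 && i < n) {
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (denom < 0) {
        delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
        apex <- d[i] + delta * (d[i + 1] - d[i - 1]) / 2
      }
    }

    # FWHM by linear interpolation at half height
    half <- y[i] / 2
    li <- i
    while (li > 1 && y[li] > half) li <- li - 1L
    left_x <- if (y[li] <= half && li < i) {
      approx(y[c(li, li + 1)], d[c(li, li + 1)], xout = half)$y
    } else d[1]
    ri <- i
    while (ri < n && y[ri] > half) ri <- ri + 1L
    right_x <- if (y[ri] <= half && ri > i) {
      approx(y[c(ri - 1, ri)], d[c(ri - 1, ri)], xout = half)$y
    } else d[n]

    # area over the peak's support: between the valleys that define its
    # prominence (robust to small noise upticks on the flanks)
    area <- trapz_xy(d[lo:hi], y[lo:hi])

    tibble(distance_mm = apex, intensity = y[i], prominence = prom,
           fwhm_mm = right_x - left_x, area = area)
  })
  out <- dplyr::bind_rows(peaks)
  if (!nrow(out)) return(empty_peaks())
  dplyr::arrange(out, .data$distance_mm)
}

empty_peaks <- function() {
  tibble(distance_mm = double(), intensity = double(), prominence = double(),
         fwhm_mm = double(), area = double())
}

trapz_xy <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Convert a band position to an rDNA copy number
#'
#' Chromosome XII size is the non-rDNA backbone plus `copies` repeat units,
#' so `copies = (size - backbone_kb) / unit_kb`. Applied to each row of a
#' peak table (or to raw distances).
#'
#' @param peaks Tibble with a `distance_mm` column (e.g. from
#'   [find_peaks()]), or a numeric vector of distances.
#' @param cal A `migration_calibration`.
#' @param unit_kb rDNA repeat-unit length in kb (default 9.1).
#' @param backbone_kb Non-rDNA chromosome XII length in kb (default 1050).
#' @param round_copies Round to the nearest integer copy?
#' @return The peak tibble with `size_kb` and `copies` columns added (or a
#'   tibble built from the distances given).
#' @examples
#' cal <- fit_ladder(tibble::tibble(distance_mm = c(10, 50),
#'                                  size_kb = c(4000, 1050)))
#' estimate_copy_number(tibble::tibble(distance_mm = 30), cal)
#' @export
estimate_copy_number <- function(peaks, cal, unit_kb = 9.1,
                                 backbone_kb = 1050, round_copies = FALSE) {
  assert_scalar_pos(unit_kb, "unit_kb")
  if (is.numeric(peaks)) peaks <- tibble(distance_mm = peaks)
  peaks <- as_tibble(peaks)
  size <- predict(cal, peaks$distance_mm)
  copies <- (size - backbone_kb) / unit_kb
  if (any(copies < 0)) {
    abort("Negative copy number: estimated size below the chromosome backbone (mis-calibration?).")
  }
  if (round_copies) copies <- round(copies)
  dplyr::mutate(peaks, size_kb = size, copies = copies)
}

#' Copy-number shift of a lane relative to a generation-0 lane
#'
#' Quantifies the shift of the chromosome XII band: both lanes are peak-
#' called with the same calibration, the generation-0 chromosome XII peak is
#' the largest-area peak (or the peak nearest `anchor_mm` if supplied), the
#' later lane's chromosome XII peak is the one nearest the generation-0
#' apex (ties broken by larger area), and the difference of the two copy
#' numbers is returned.
#'
#' @param lane_t,lane_0 Lane profiles (tibbles with `distance_mm`, `intensity`).
#' @param cal A `migration_calibration`.
#' @param unit_kb,backbone_kb Copy-number constants, as in
#'   [estimate_copy_number()].
#' @param anchor_mm Optional known chromosome XII apex in the reference lane.
#' @param ... Passed to [find_peaks()].
#' @return One-row tibble: `delta_copies`, `copies_t`, `copies_0`,
#'   `distance_t_mm`, `distance_0_mm`.
#' @export
copy_shift <- function(lane_t, lane_0, cal, unit_kb = 9.1, backbone_kb = 1050,
                       anchor_mm = NULL, ...) {
  p0 <- find_peaks(lane_0, ...)
  pt <- find_peaks(lane_t, ...)
  if (!nrow(p0) || !nrow(pt)) abort("Both lanes must contain at least one peak.")
  ref <- if (is.null(anchor_mm)) {
    p0[which.max(p0$area), ]
  } else {
    p0[which.min(abs(p0$distance_mm - anchor_mm)), ]
  }
  gap <- abs(pt$distance_mm - ref$distance_mm)
  cand <- which(gap <= min(gap) + 1e-9)
  sel <- cand[which.max(pt$area[cand])]
  c0 <- estimate_copy_number(ref, cal, unit_kb, backbone_kb)$copies
  ct <- estimate_copy_number(pt[sel, ], cal, unit_kb, backbone_kb)$copies
  tibble(delta_copies = ct - c0, copies_t = ct, copies_0 = c0,
         distance_t_mm = pt$distance_mm[sel], distance_0_mm = ref$distance_mm)
}

#' Signal proportions across band windows in one lane
#'
#' Integrates the baseline-subtracted intensity over user-supplied distance
#' windows (e.g. the chromosome XII bands of two competing strains, or ERC
#' vs genomic bands) and reports each window's fraction of the total. A band
#' that has disappeared reports 0.
#'
#' @param lane Lane profile tibble (`distance_mm`, `intensity`).
#' @param bands Tibble with columns `start_mm`, `end_mm` and optionally
#'   `band` (labels). Windows must be disjoint and within the profile.
#' @param baseline_window Rolling-minimum window, as in [find_peaks()].
#' @return Tibble: `band`, `start_mm`, `end_mm`, `area`, `fraction`. When
#'   the total signal is zero, fractions are `NA` and the result carries
#'   attribute `undefined_proportions = TRUE`.
#' @export
band_proportions <- function(lane, bands, baseline_window = 601) {
  lane <- as_tibble(lane)
  bands <- as_tibble(bands)
  stopifnot(all(c("start_mm", "end_mm") %in% names(bands)))
  if (!"band" %in% names(bands)) {
    bands$band <- sprintf("band_%d", seq_len(nrow(bands)))
  }
  b <- dplyr::arrange(bands, .data$start_mm)
  if (any(b$start_mm >= b$end_mm)) abort("Each window must satisfy start < end.")
  if (nrow(b) > 1 && any(b$end_mm[-nrow(b)] > b$start_mm[-1])) {
    abort("Window error: band windows overlap.")
  }
  rng <- range(lane$distance_mm)
  if (any(b$start_mm < rng[1]) || any(b$end_mm > rng[2])) {
    abort("Band windows must lie within the profile support.")
  }
  y <- lane$intensity
  if (!is.null(baseline_window) && length(y) > baseline_window) {
    y <- pmax(y - zoo::rollapply(y, baseline_window, min, partial = TRUE), 0)
  }
  areas <- purrr::map2_dbl(bands$start_mm, bands$end_mm, function(s, e) {
    sel <- lane$distance_mm >= s & lane$distance_mm <= e
    trapz_xy(lane$distance_mm[sel], y[sel])
  })
  total <- sum(areas)
  out <- tibble(band = bands$band, start_mm = bands$start_mm,
                end_mm = bands$end_mm, area = areas,
                fraction = if (total > 0) areas / total else NA_real_)
  if (total <= 0) attr(out, "undefined_proportions") <- TRUE
  out
}

#' Lane-profile TSV and calibration JSON input/output
#'
#' Lane profiles travel as TSV with columns `distance_mm`, `intensity`
#' (long format adds a `lane` column); calibrations as JSON holding the
#' knots and method tag.
#'
#' @param lane,cal Objects to write.
#' @param path File path.
#' @export
write_lane_tsv <- function(lane, path) {
  readr::write_tsv(lane, path)
  invisible(path)
}

#' @rdname write_lane_tsv
#' @export
read_lane_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname write_lane_tsv
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(list(method = cal$method, knots = cal$knots), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lane_tsv
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_ladder(as_tibble(x$knots))
}
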