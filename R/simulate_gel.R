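#' Hansenula wingei chromosomal marker ladder
#'
#' The seven largest H. wingei chromosomes (Bio-Rad PFGE marker), the size
#' range that brackets yeast chromosome XII.
#'
#' @return Tibble with column `size_kb`.
#' @export
default_hwingei_ladder <- function() {
  tibble(size_kb = c(3130, 2700, 2350, 1810, 1660, 1370, 1050))
}

#' Ground-truth migration mapping used by the gel simulator
#'
#' A log-linear migration law, `distance = a - b * log10(size_kb)`, sampled
#' at the marker sizes, so that a piecewise-linear refit of the simulated
#' marker lane recovers it exactly.
#'
#' @param ladder Tibble with `size_kb` (marker sizes).
#' @param a,b Intercept (mm) and slope (mm per log10 kb) of the migration law.
#' @return A `migration_calibration`.
#' @export
default_gel_calibration <- function(ladder = default_hwingei_ladder(),
                                    a = 330, b = 90) {
  sizes <- sort(ladder$size_kb, decreasing = TRUE)
  fit_ladder(tibble(distance_mm = a - b * log10(sizes), size_kb = sizes))
}

#' Simulate PFGE lane intensity profiles
#'
#' Generates a marker lane plus one lane per sample. Each sample is a
#' population of cells described by a vector of rDNA copy numbers; every
#' cell contributes a Gaussian band centred at the migration distance of
#' its chromosome XII size (`backbone_kb + copies * unit_kb`). A clonal
#' population gives a tight band; a broad copy-number distribution gives a
#' smeared band, reproducing how copy-number heterogeneity appears on a
#' pulsed-field gel. Baseline noise is truncated at zero.
#'
#' @param samples Named list of numeric vectors of per-cell copy numbers
#'   (a single value simulates a clonal lane).
#' @param calibration Ground-truth `migration_calibration` (size -> distance).
#' @param unit_kb,backbone_kb Chromosome XII size model (kb).
#' @param band_sd_mm Gaussian band width (mm).
#' @param noise_sd Baseline noise standard deviation (intensity units).
#' @param amplitude Total intensity per lane (arbitrary units).
#' @param grid Migration-distance grid (mm).
#' @param ladder Marker sizes for the marker lane.
#' @param seed Integer seed.
#' @return A long tibble with columns `lane`, `distance_mm`, `intensity`;
#'   the marker lane is named `"marker"`. Attribute `truth` stores each
#'   sample's true band distances.
#' @export
simulate_gel_lanes <- function(samples,
                               calibration = default_gel_calibration(),
                               unit_kb = 9.1, backbone_kb = 1050,
                               band_sd_mm = 1, noise_sd = 2,
                               amplitude = 100,
                               grid = seq(0, 80, by = 0.05),
                               ladder = default_hwingei_ladder(),
                               seed = NULL) {
  stopifnot(is.list(samples), length(samples) > 0)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- sprintf("sample_%d", seq_along(samples))
  }
  local_seed(seed)

  band_mix <- function(centers, weights = NULL) {
    # marker bands are loaded at full strength; sample lanes split their
    # signal across the population's cells
    weights <- weights %||% rep(1, length(centers))
    inside <- centers >= min(grid) & centers <= max(grid)
    if (any(!inside)) {
      warn(sprintf("%d band(s) outside the profile support were clipped.",
                   sum(!inside)))
    }
    y <- numeric(length(grid))
    for (i in which(inside)) {
      y <- y + weights[i] * exp(-0.5 * ((grid - centers[i]) / band_sd_mm)^2)
    }
    amplitude * y
  }
  add_noise <- function(y) {
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    pmax(y, 0)
  }

  marker_d <- distance_for_size(calibration, ladder$size_kb)
  lanes <- list(marker = add_noise(band_mix(marker_d)))
  truth <- list()
  for (nm in names(samples)) {
    copies <- samples[[nm]]
    stopifnot(is.numeric(copies), length(copies) >= 1)
    d <- distance_for_size(calibration, backbone_kb + copies * unit_kb)
    lanes[[nm]] <- add_noise(band_mix(d, rep(1 / length(d), length(d))))
    truth[[nm]] <- d
  }

  out <- purrr::imap_dfr(lanes, function(y, nm) {
    tibble(lane = nm, distance_mm = grid, intensity = y)
  })
  attr(out, "truth") <- truth
  out
}

#' Extract one lane from a long gel table
#'
#' @param gel Long tibble from [simulate_gel_lanes()] (or a lane TSV with a
#'   `lane` column).
#' @param which Lane name.
#' @return Tibble with `distance_mm`, `intensity`.
#' @export
gel_lane <- function(gel, which) {
  out <- dplyr::filter(gel, .data$lane == which)
  if (!nrow(out)) abort(sprintf("No lane named '%s'.", which))
  out <- dplyr::select(out, "distance_mm", "intensity")
  attr(out, "truth") <- NULL
  out
}
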