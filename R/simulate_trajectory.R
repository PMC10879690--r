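#' Simulate replicate rDNA copy-number trajectories
#'
#' A biased, copy-count-scaled random walk encoding the statistical
#' structure of rDNA copy-number evolution under serial passage. Each
#' generation, each chromosome undergoes a recombination event with
#' probability `recomb_rate * copies` (more repeats, more recombination,
#' which is why the larger homolog of a diploid fluctuates more). On an
#' event the copy number takes a Gaussian step:
#'
#' * wild type (`"WT"`): mean `recovery_gain * (ploidy * setpoint - total)`,
#'   i.e. symmetric variation plus Fob1-dependent recovery of the TOTAL
#'   copy number toward the setpoint (total, not per homolog);
#' * `"fob1d"`: mean `-deletion_bias` with no recovery term — variation is
#'   rarer only through its parameters, and drifts downward.
#'
#' Copies are rounded and floored at `min_viable`. No mechanistic fidelity
#' is claimed; parameters are configuration.
#'
#' @param params A [sim_params()].
#' @param mode `"WT"` or `"fob1d"`.
#' @param ploidy 1 or 2 (chromosome XII homologs per cell).
#' @param n_replicates Number of replicate lineages.
#' @param n_generations Number of generations simulated.
#' @param start_copies Starting copies per homolog (length `ploidy`);
#'   default `rep(setpoint, ploidy)`.
#' @param record_every Record copies every this many generations.
#' @param seed Integer seed.
#' @return Tibble `replicate`, `homolog`, `generation`, `copies`, with
#'   attributes `mode`, `ploidy`, `params`.
#' @export
simulate_trajectory <- function(params = sim_params(),
                                mode = c("WT", "fob1d"),
                                ploidy = 1, n_replicates = 3,
                                n_generations = 900,
                                start_copies = NULL,
                                record_every = 10, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "sim_params"), ploidy %in% c(1, 2),
            n_generations >= 1, n_replicates >= 1)
  start_copies <- start_copies %||% rep(params$setpoint, ploidy)
  stopifnot(length(start_copies) == ploidy, all(start_copies >= params$min_viable))
  local_seed(seed)

  rec_gens <- unique(c(seq(0, n_generations, by = record_every), n_generations))
  setpoint_total <- params$setpoint * ploidy
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    copies <- start_copies
    rec <- matrix(NA_real_, nrow = length(rec_gens), ncol = ploidy)
    rec[1, ] <- copies
    ri <- 2L
    for (g in seq_len(n_generations)) {
      for (h in seq_len(ploidy)) {
        if (runif(1) < min(1, params$recomb_rate * copies[h])) {
          mu <- if (mode == "WT") {
            params$recovery_gain * (setpoint_total - sum(copies))
          } else {
            -params$deletion_bias
          }
          copies[h] <- max(params$min_viable,
                           round(copies[h] + rnorm(1, mu, params$step_sd)))
        }
      }
      if (ri <= length(rec_gens) && g == rec_gens[ri]) {
        rec[ri, ] <- copies
        ri <- ri + 1L
      }
    }
    out[[r]] <- tibble(
      replicate = r,
      homolog = rep(seq_len(ploidy), each = length(rec_gens)),
      generation = rep(rec_gens, ploidy),
      copies = as.vector(rec)
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "mode") <- mode
  attr(res, "ploidy") <- ploidy
  attr(res, "params") <- params
  res
}

#' Write / read trajectories as TSV
#'
#' @param traj Trajectory tibble (`replicate`, `homolog`, `generation`,
#'   `copies`).
#' @param path TSV path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  readr::write_tsv(traj, path)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
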