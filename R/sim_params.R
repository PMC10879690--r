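#' Simulation and analysis parameter set
#'
#' One object housing every numeric threshold shared across the pipeline:
#' the long-read QC filters, the bin-split SV-caller geometry, the gel
#' copy-number constants, the passage dilution, and the copy-number
#' random-walk parameters.
#'
#' @param min_read_len Long-read QC: minimum read length, exclusive (nt).
#' @param min_mean_q Long-read QC: minimum mean Phred score, exclusive.
#' @param bin_len Bin length for split-bin mapping (nt).
#' @param dev_tol Inter-bin distance deviation tolerance, exclusive (nt).
#' @param min_del Minimum deletion size retained in headline summaries (nt).
#' @param unit_kb rDNA repeat-unit length (kb).
#' @param backbone_kb Non-rDNA chromosome XII length (kb).
#' @param dilution Serial-transfer dilution factor.
#' @param setpoint Wild-type rDNA copy-number setpoint per chromosome.
#' @param recomb_rate Per-copy, per-generation probability of a
#'   recombination event on a chromosome (event probability scales with
#'   that chromosome's copy count).
#' @param step_sd Copy-number step standard deviation per event (copies).
#' @param recovery_gain Wild-type mean step per copy of deviation of the
#'   TOTAL copy number from the setpoint (Fob1-dependent setpoint recovery).
#' @param deletion_bias fob1-null mean copy loss per event (copies); the
#'   fob1-null walk has no recovery term.
#' @param min_viable Floor on copies per chromosome.
#' @return A `sim_params` list.
#' @export
sim_params <- function(min_read_len = 8000, min_mean_q = 18, bin_len = 300,
                       dev_tol = 100, min_del = 50,
                       unit_kb = 9.1, backbone_kb = 1050,
                       dilution = 1000, setpoint = 150,
                       recomb_rate = 0.001, step_sd = 3,
                       recovery_gain = 0.05, deletion_bias = 1,
                       min_viable = 2) {
  p <- list(min_read_len = min_read_len, min_mean_q = min_mean_q,
            bin_len = bin_len, dev_tol = dev_tol, min_del = min_del,
            unit_kb = unit_kb, backbone_kb = backbone_kb,
            dilution = dilution, setpoint = setpoint,
            recomb_rate = recomb_rate, step_sd = step_sd,
            recovery_gain = recovery_gain, deletion_bias = deletion_bias,
            min_viable = min_viable)
  for (nm in c("min_read_len", "min_mean_q", "bin_len", "dev_tol", "min_del",
               "unit_kb", "backbone_kb", "dilution", "setpoint", "step_sd",
               "min_viable")) {
    assert_scalar_pos(p[[nm]], nm)
  }
  if (p$min_viable < 1 || p$setpoint < p$min_viable) {
    abort("Need setpoint >= min_viable >= 1.")
  }
  structure(p, class = "sim_params")
}

#' Write / read simulation parameters as JSON
#'
#' @param params A `sim_params`.
#' @param path JSON path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  do.call(sim_params, jsonlite::read_json(path, simplifyVector = TRUE))
}
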