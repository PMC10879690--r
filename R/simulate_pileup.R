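#' Simulate a collapsed-unit short-read pileup
#'
#' Emulates the geometry of mapping short reads from every array copy onto a
#' single repeat-unit reference: at each unit position the observed bases
#' are a multinomial draw over {A, C, G, T, deletion} whose probabilities
#' combine the per-copy planted variants (an SNV carried by k of n copies
#' contributes allele fraction k/n) with a uniform substitution error.
#' Counts at every position sum exactly to `coverage`.
#'
#' @param array A [tandem_array][build_array].
#' @param coverage Read depth at each unit position.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return Tibble with columns `pos` (0-based unit position), `ref`,
#'   `A`, `C`, `G`, `T`, `del`, `coverage`.
#' @export
simulate_pileup <- function(array, coverage, error_rate = 0, seed = NULL) {
  stopifnot(inherits(array, "tandem_array"))
  assert_scalar_pos(coverage, "coverage")
  coverage <- as.integer(coverage)
  local_seed(seed)

  L <- array$unit$L_unit
  n_c <- array$n_copies
  ref <- strsplit(array$unit$sequence, "")[[1]]

  # Per-position copy fractions for each state before sequencing error.
  frac <- matrix(0, nrow = 5, ncol = L,
                 dimnames = list(c(DNA_BASES, "del"), NULL))
  frac[cbind(match(ref, DNA_BASES), seq_len(L))] <- 1
  if (nrow(array$snvs)) {
    for (i in seq_len(nrow(array$snvs))) {
      p <- array$snvs$pos[i] + 1L
      frac[array$snvs$alt[i], p] <- frac[array$snvs$alt[i], p] + 1 / n_c
      frac[ref[p], p] <- frac[ref[p], p] - 1 / n_c
    }
  }
  if (nrow(array$deletions)) {
    for (i in seq_len(nrow(array$deletions))) {
      idx <- seq.int(array$deletions$start[i] + 1L, array$deletions$end[i])
      b <- cbind(match(ref[idx], DNA_BASES), idx)
      frac[b] <- frac[b] - 1 / n_c
      frac["del", idx] <- frac["del", idx] + 1 / n_c
    }
  }

  # Uniform substitution error on the base states (deletions unaffected).
  e <- error_rate
  base_mass <- colSums(frac[1:4, , drop = FALSE])
  probs <- frac
  probs[1:4, ] <- sweep(frac[1:4, , drop = FALSE] * (1 - e), 2,
                        base_mass * e / 3, "+") - frac[1:4, , drop = FALSE] * e / 3

  counts <- apply(probs, 2, function(p) rmultinom(1, coverage, p))
  tibble(
    pos = 0:(L - 1L),
    ref = ref,
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    del = counts[5, ],
    coverage = coverage
  )
}

#' Write / read a pileup table as TSV
#'
#' @param pileup Tibble as returned by [simulate_pileup()] or [tally()].
#' @param path TSV path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  readr::write_tsv(pileup, path)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(ref = readr::col_character()))
}
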