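DNA_BASES <- c("A", "C", "G", "T")

# Scoped RNG: functions that take `seed` restore the caller's RNG state.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Integer encoding of a DNA string (A=65,C=67,G=71,T=84) for fast Hamming.
dna_to_int <- function(x) utf8ToInt(x)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}
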