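#' Simulate nanopore-style long reads from a tandem array
#'
#' Draws read lengths from a log-normal law truncated to `[min, max]`,
#' placements uniformly along the array, and per-base qualities around a
#' per-read mean, so that a realistic fraction of reads fails the length /
#' quality filters downstream. Sequencing errors are uniform substitutions.
#' Each read records its true origin interval and the planted deletions it
#' spans, which downstream tests use as ground truth.
#'
#' @param array A [tandem_array][build_array].
#' @param n_reads Number of reads.
#' @param length_law List with `meanlog`, `sdlog`, `min`, `max` for the
#'   truncated log-normal read-length distribution (nt).
#' @param error_rate Per-base substitution probability, in `[0, 0.3]`.
#' @param q_law List with `mean`, `sd` (between-read mean Phred spread) and
#'   `base_sd` (within-read spread). Phred scores are clamped to `[0, 60]`.
#' @param rc_prob Probability a read is reverse-complemented.
#' @param seed Integer seed.
#' @return Tibble with one row per read: `read_id`, `sequence`, `quals`
#'   (integer list-column of Phred scores), `length`, `mean_q`, `strand`,
#'   `origin_start`, `origin_end` (0-based, half-open, array coordinates),
#'   and `svs` (list-column of spanned planted deletions).
#' @export
simulate_long_reads <- function(array, n_reads,
                                length_law = list(meanlog = log(9000),
                                                  sdlog = 0.4,
                                                  min = 1000, max = 50000),
                                error_rate = 0,
                                q_law = list(mean = 20, sd = 3, base_sd = 3),
                                rc_prob = 0.5,
                                seed = NULL) {
  stopifnot(inherits(array, "tandem_array"))
  if (error_rate < 0 || error_rate > 0.3) {
    abort("`error_rate` must be in [0, 0.3].")
  }
  local_seed(seed)
  A_len <- nchar(array$sequence)

  lens <- round(exp(rnorm(n_reads, length_law$meanlog, length_law$sdlog)))
  lens <- pmin(pmax(lens, length_law$min), length_law$max)
  n_trunc <- sum(lens > A_len)
  if (n_trunc > 0) {
    inform(sprintf("%d read(s) longer than the array were truncated.", n_trunc))
    lens <- pmin(lens, A_len)
  }
  starts <- floor(runif(n_reads, 0, A_len - lens + 1))  # 0-based

  mean_qs <- pmin(pmax(rnorm(n_reads, q_law$mean, q_law$sd), 2), 50)
  rc <- runif(n_reads) < rc_prob

  rows <- purrr::map(seq_len(n_reads), function(i) {
    s <- substr(array$sequence, starts[i] + 1L, starts[i] + lens[i])
    if (error_rate > 0) {
      chars <- strsplit(s, "")[[1]]
      hit <- which(runif(lens[i]) < error_rate)
      if (length(hit)) {
        chars[hit] <- vapply(chars[hit], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
        s <- paste(chars, collapse = "")
      }
    }
    if (rc[i]) s <- revcomp(s)
    q <- as.integer(pmin(pmax(round(rnorm(lens[i], mean_qs[i], q_law$base_sd)),
                              0), 60))
    sv <- array$sv_table[array$sv_table$global_pos > starts[i] &
                           array$sv_table$global_pos < starts[i] + lens[i], ]
    list(seq = s, quals = q, sv = sv)
  })

  tibble(
    read_id = sprintf("read_%05d", seq_len(n_reads)),
    sequence = purrr::map_chr(rows, "seq"),
    quals = purrr::map(rows, "quals"),
    length = lens,
    mean_q = purrr::map_dbl(rows, ~ mean(.x$quals)),
    strand = ifelse(rc, "-", "+"),
    origin_start = as.integer(starts),
    origin_end = as.integer(starts + lens),
    svs = purrr::map(rows, "sv")
  )
}

#' Write / read long reads as FASTQ (Sanger, offset 33)
#'
#' @param reads Tibble as returned by [simulate_long_reads()] (columns
#'   `read_id`, `sequence`, `quals`).
#' @param path FASTQ path.
#' @return `path` invisibly (writer); a tibble with `read_id`, `sequence`,
#'   `quals`, `length`, `mean_q` (reader).
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  q <- Biostrings::PhredQuality(
    vapply(reads$quals, function(v) intToUtf8(v + 33L), character(1)))
  xs <- Biostrings::QualityScaledDNAStringSet(x, q)
  names(xs) <- reads$read_id
  # writer warns about dropping (empty) metadata columns; nothing is lost
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(xs, path))
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  # reader warns about dropping (empty) metadata columns; nothing is lost
  xs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- purrr::map(unname(as.character(Biostrings::quality(xs))),
                      ~ utf8ToInt(.x) - 33L)
  tibble(
    read_id = names(xs),
    sequence = unname(as.character(xs)),
    quals = quals,
    length = Biostrings::width(xs),
    mean_q = purrr::map_dbl(quals, mean)
  )
}
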