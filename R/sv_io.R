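#' Export bin alignments as SAM
#'
#' Writes per-bin alignments against the (circularly extended) repeat unit
#' so that external mapping results can be exchanged. Query names follow
#' the convention `<read_id>|bin<index>`; reverse-strand bins carry FLAG
#' 16 with the position of the bin's reverse complement on the forward
#' unit; unmapped bins carry FLAG 4.
#'
#' @param alignments Tibble of bin alignments with columns `read_id`,
#'   `bin`, `unit_pos`, `strand`, `mapped` (and optionally `mismatches`).
#' @param unit The [reference_unit][make_reference_unit] mapped against.
#' @param path Output SAM path.
#' @param bin_len Bin length (reference header length is `L_unit + bin_len`).
#' @export
write_bin_sam <- function(alignments, unit, path, bin_len = 300) {
  a <- as_tibble(alignments)
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", unit$id, unit$L_unit + bin_len)
  )
  rec <- vapply(seq_len(nrow(a)), function(i) {
    qname <- sprintf("%s|bin%d", a$read_id[i], a$bin[i])
    if (isTRUE(a$mapped[i])) {
      flag <- if (a$strand[i] == "-") 16L else 0L
      nm <- if ("mismatches" %in% names(a)) {
        sprintf("\tNM:i:%d", a$mismatches[i])
      } else ""
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*%s",
              qname, flag, unit$id, a$unit_pos[i] + 1L, bin_len, nm)
    } else {
      sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", qname)
    }
  }, character(1))
  writeLines(c(lines, rec), path)
  invisible(path)
}

parse_bin_qname <- function(qname) {
  m <- regmatches(qname, regexec("^(.*)\\|bin(\\d+)$", qname))
  bad <- lengths(m) != 3
  if (any(bad)) abort("Query names must follow '<read_id>|bin<i>'.")
  tibble(read_id = vapply(m, `[`, character(1), 2),
         bin = as.integer(vapply(m, `[`, character(1), 3)))
}

#' Import pre-mapped bin alignments (SAM or PAF)
#'
#' Accepts external per-bin mappings as an alternative to the internal
#' mapper. SAM files are converted and scanned with Rsamtools; PAF is read
#' as TSV. Positions are reduced modulo the unit length, so alignments
#' reported on a circularly extended reference are handled.
#'
#' @param path SAM (or PAF) file path.
#' @param unit The [reference_unit][make_reference_unit] mapped against.
#' @return Tibble `read_id`, `bin`, `read_offset`, `unit_pos`, `strand`,
#'   `mapped`, sorted by read and bin, suitable for
#'   `summarize_sample(..., alignments = )`.
#' @export
read_bin_sam <- function(path, unit) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "strand"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  ids <- parse_bin_qname(x$qname)
  mapped <- !bitwAnd(x$flag, 4L)
  out <- dplyr::mutate(ids,
    read_offset = .data$bin * 300L,
    unit_pos = ifelse(mapped, (x$pos - 1L) %% unit$L_unit, NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(x$flag, 16L) > 0, "-", "+"),
                    NA_character_),
    mapped = mapped)
  dplyr::arrange(out, .data$read_id, .data$bin)
}

#' @rdname read_bin_sam
#' @export
read_bin_paf <- function(path, unit) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  ids <- parse_bin_qname(x$X1)
  out <- dplyr::mutate(ids,
    read_offset = .data$bin * 300L,
    unit_pos = as.integer(x$X8) %% unit$L_unit,
    strand = x$X5,
    mapped = TRUE)
  dplyr::arrange(out, .data$read_id, .data$bin)
}

#' Write a PAF file for bin alignments (mapped bins only)
#'
#' @inheritParams write_bin_sam
#' @export
write_bin_paf <- function(alignments, unit, path, bin_len = 300) {
  a <- dplyr::filter(as_tibble(alignments), .data$mapped)
  nmatch <- if ("mismatches" %in% names(a)) bin_len - a$mismatches
            else rep(bin_len, nrow(a))
  lines <- sprintf("%s|bin%d\t%d\t0\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60",
                   a$read_id, a$bin, bin_len, bin_len, a$strand, unit$id,
                   unit$L_unit + bin_len, a$unit_pos, a$unit_pos + bin_len,
                   nmatch, bin_len)
  writeLines(lines, path)
  invisible(path)
}

#' Write SV calls as TSV and a sample summary as JSON
#'
#' @param x Calls tibble (from [summarize_sample()]`$calls`) or an
#'   `sv_sample_summary`.
#' @param path Output path.
#' @export
write_sv_calls_tsv <- function(x, path) {
  if (inherits(x, "sv_sample_summary")) x <- x$calls
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_sv_calls_tsv
#' @export
write_sv_summary_json <- function(x, path) {
  stopifnot(inherits(x, "sv_sample_summary"))
  jsonlite::write_json(as.list(x$summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
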