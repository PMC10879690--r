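#' Build a tandem rDNA array with planted variants
#'
#' Concatenates `n_copies` copies of the repeat unit between two
#' non-repetitive flanking arms, applying per-copy edits: single-nucleotide
#' variants and internal deletions. The result is the ground-truth genome
#' (the rDNA portion of chromosome XII) used by the read, pileup and gel
#' simulators.
#'
#' @param unit A [reference_unit][make_reference_unit].
#' @param n_copies Number of unit copies (>= 1).
#' @param snvs Tibble with columns `copy` (1-based copy index), `pos`
#'   (0-based unit position), `alt` (alternative base). May be `NULL`.
#' @param deletions Tibble with columns `copy`, `start`, `end` (half-open,
#'   0-based unit coordinates). May be `NULL`.
#' @param arms Either a character vector of two DNA strings (left, right
#'   flank) or a numeric vector of two lengths for random flanks.
#' @param seed Integer seed (used only when random flanks are drawn).
#' @return A `tandem_array`: list with `unit`, `n_copies`, `sequence`,
#'   `snvs`, `deletions`, `copy_table` (per-copy global start/length) and
#'   `sv_table` (planted deletions in global array coordinates).
#' @examples
#' unit <- make_reference_unit(L_unit = 2000, seed = 1)
#' arr <- build_array(unit, n_copies = 3, arms = c(100, 100), seed = 2)
#' nchar(arr$sequence)  # 200 + 3 * 2000
#' @export
build_array <- function(unit, n_copies, snvs = NULL, deletions = NULL,
                        arms = c(1000, 1000), seed = NULL) {
  stopifnot(inherits(unit, "reference_unit"))
  if (!is.numeric(n_copies) || n_copies < 1) abort("`n_copies` must be >= 1.")
  n_copies <- as.integer(n_copies)
  L <- unit$L_unit
  local_seed(seed)
  if (is.numeric(arms)) {
    stopifnot(length(arms) == 2)
    arms <- c(random_dna(arms[1]), random_dna(arms[2]))
  }
  stopifnot(is.character(arms), length(arms) == 2)

  snvs <- if (is.null(snvs)) {
    tibble(copy = integer(), pos = integer(), alt = character())
  } else as_tibble(snvs)
  deletions <- if (is.null(deletions)) {
    tibble(copy = integer(), start = integer(), end = integer())
  } else as_tibble(deletions)

  if (nrow(snvs)) {
    bad <- snvs$copy < 1 | snvs$copy > n_copies | snvs$pos < 0 | snvs$pos >= L
    if (any(bad)) abort("SNV edit outside its copy or the unit.")
    if (!all(snvs$alt %in% DNA_BASES)) abort("SNV `alt` must be A/C/G/T.")
  }
  if (nrow(deletions)) {
    bad <- deletions$copy < 1 | deletions$copy > n_copies |
      deletions$start < 0 | deletions$end > L |
      deletions$start >= deletions$end
    if (any(bad)) abort("Deletion edit outside its copy or empty.")
  }

  unit_chars <- strsplit(unit$sequence, "")[[1]]
  copy_seqs <- character(n_copies)
  for (ci in seq_len(n_copies)) {
    chars <- unit_chars
    s <- snvs[snvs$copy == ci, ]
    if (nrow(s)) chars[s$pos + 1L] <- s$alt
    d <- deletions[deletions$copy == ci, ]
    if (nrow(d)) {
      drop <- unlist(purrr::map2(d$start, d$end, ~ seq.int(.x + 1L, .y)))
      chars <- chars[-unique(drop)]
    }
    copy_seqs[ci] <- paste(chars, collapse = "")
  }

  copy_len <- nchar(copy_seqs)
  copy_start <- nchar(arms[1]) + c(0L, cumsum(copy_len)[-n_copies])
  copy_table <- tibble(copy = seq_len(n_copies),
                       global_start = copy_start, length = copy_len)

  # Planted deletions lifted to global array coordinates (position of the
  # junction in the realized sequence, and the number of bases removed).
  sv_table <- if (nrow(deletions)) {
    dels <- dplyr::arrange(deletions, .data$copy, .data$start)
    dels <- dplyr::group_by(dels, .data$copy)
    dels <- dplyr::mutate(dels,
      removed_before = dplyr::lag(cumsum(.data$end - .data$start), default = 0L))
    dels <- dplyr::ungroup(dels)
    dplyr::transmute(dels,
      copy = .data$copy,
      unit_start = .data$start, unit_end = .data$end,
      size = .data$end - .data$start,
      global_pos = copy_start[.data$copy] + .data$start - .data$removed_before)
  } else {
    tibble(copy = integer(), unit_start = integer(), unit_end = integer(),
           size = integer(), global_pos = integer())
  }

  structure(
    list(
      unit = unit, n_copies = n_copies,
      left_arm = arms[1], right_arm = arms[2],
      sequence = paste0(arms[1], paste(copy_seqs, collapse = ""), arms[2]),
      snvs = snvs, deletions = deletions,
      copy_table = copy_table, sv_table = sv_table
    ),
    class = "tandem_array"
  )
}

#' @export
print.tandem_array <- function(x, ...) {
  cat(sprintf(
    "<tandem_array> %d x %d bp unit (+%d/%d bp arms) = %d bp; %d SNVs, %d deletions\n",
    x$n_copies, x$unit$L_unit, nchar(x$left_arm), nchar(x$right_arm),
    nchar(x$sequence), nrow(x$snvs), nrow(x$deletions)))
  invisible(x)
}

#' Write a tandem array as FASTA
#'
#' @param array A `tandem_array`.
#' @param path Output path.
#' @export
write_array_fasta <- function(array, path) {
  stopifnot(inherits(array, "tandem_array"))
  x <- Biostrings::DNAStringSet(array$sequence)
  names(x) <- sprintf("tandem_array_%dx%d", array$n_copies, array$unit$L_unit)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
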