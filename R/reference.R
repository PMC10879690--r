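#' Default annotation layout for a synthetic rDNA repeat unit
#'
#' Positions of the functional elements carried by each yeast rDNA repeat:
#' the 35S and 5S rRNA genes, the replication origin (rARS), the
#' non-coding-RNA promoter (E-pro) and the replication fork barrier (RFB).
#' The intervals are schematic (half-open, 0-based) and scale with the unit
#' length; only their presence and disjointness matter to the analyses here.
#'
#' @param L_unit Unit length in bp.
#' @return A tibble with columns `element`, `start`, `end`.
#' @export
default_element_layout <- function(L_unit = 9100) {
  assert_scalar_pos(L_unit, "L_unit")
  f <- L_unit / 9100
  tibble(
    element = c("35S", "5S", "rARS", "E-pro", "RFB"),
    start   = round(c(1000, 7200, 7700, 8200, 8700) * f),
    end     = round(c(7000, 7320, 7900, 8400, 8800) * f)
  )
}

#' Construct a synthetic rDNA reference repeat unit
#'
#' Builds a single rDNA repeat unit: a random DNA sequence of length
#' `L_unit` with an annotated element map. A random sequence is used rather
#' than the real S288C repeat because none of the downstream analyses depend
#' on real sequence content; a real unit can be supplied via
#' [read_unit_fasta()].
#'
#' @param L_unit Unit length in bp (default 9100, a standard yeast value).
#' @param elements Tibble with columns `element`, `start`, `end` giving
#'   half-open 0-based intervals; must be disjoint and within `[0, L_unit)`.
#' @param seed Integer seed; the same seed reproduces the same unit.
#' @return An object of class `reference_unit`: a list with `id`,
#'   `sequence` (character), `L_unit`, and `elements` (tibble).
#' @examples
#' unit <- make_reference_unit(seed = 1)
#' unit$L_unit
#' @export
make_reference_unit <- function(L_unit = 9100,
                                elements = default_element_layout(L_unit),
                                seed = NULL) {
  assert_scalar_pos(L_unit, "L_unit")
  L_unit <- as.integer(L_unit)
  elements <- as_tibble(elements)
  stopifnot(all(c("element", "start", "end") %in% names(elements)))
  if (any(elements$start < 0) || any(elements$end > L_unit) ||
      any(elements$start >= elements$end)) {
    abort("Element intervals must be non-empty and lie within [0, L_unit).")
  }
  ord <- order(elements$start)
  if (any(elements$end[ord][-nrow(elements)] > elements$start[ord][-1])) {
    abort("Element intervals must be disjoint.")
  }
  local_seed(seed)
  structure(
    list(
      id = sprintf("rDNA_unit_%d", L_unit),
      sequence = random_dna(L_unit),
      L_unit = L_unit,
      elements = elements
    ),
    class = "reference_unit"
  )
}

#' @export
print.reference_unit <- function(x, ...) {
  cat(sprintf("<reference_unit> %s: %d bp, %d elements (%s)\n",
              x$id, x$L_unit, nrow(x$elements),
              paste(x$elements$element, collapse = ", ")))
  invisible(x)
}

#' Write / read a repeat unit as FASTA
#'
#' @param unit A `reference_unit`.
#' @param path Output FASTA path.
#' @return `path`, invisibly (writer); a `reference_unit` (reader).
#' @export
write_unit_fasta <- function(unit, path) {
  stopifnot(inherits(unit, "reference_unit"))
  x <- Biostrings::DNAStringSet(unit$sequence)
  names(x) <- unit$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @param elements Element annotation to attach (the FASTA itself carries none).
#' @rdname write_unit_fasta
#' @export
read_unit_fasta <- function(path, elements = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1) abort("Expected a single-sequence FASTA for the unit.")
  L <- Biostrings::width(x)[1]
  structure(
    list(
      id = names(x)[1],
      sequence = as.character(x[[1]]),
      L_unit = L,
      elements = elements %||% default_element_layout(L)
    ),
    class = "reference_unit"
  )
}
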