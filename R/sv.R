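#' Quality-filter long reads
#'
#' A read passes when its length is strictly greater than `min_read_len`
#' and the arithmetic mean of its per-base Phred scores is strictly greater
#' than `min_mean_q` (both thresholds exclusive; a read of exactly the
#' threshold fails). The mean is taken in Phred space, matching common
#' basecaller summaries; set `q_domain = "error"` to average in
#' error-probability space instead.
#'
#' @param reads Tibble with columns `read_id`, `sequence` and either
#'   `quals` (integer list-column) or `mean_q`.
#' @param params A [sim_params()] (uses `min_read_len`, `min_mean_q`).
#' @param q_domain `"phred"` (default) or `"error"`.
#' @return The input with `qc_pass` (logical) and `qc_reason` columns.
#' @export
qc_filter <- function(reads, params = sim_params(),
                      q_domain = c("phred", "error")) {
  q_domain <- match.arg(q_domain)
  reads <- as_tibble(reads)
  len <- if ("length" %in% names(reads)) reads$length else nchar(reads$sequence)
  mq <- if (q_domain == "phred") {
    if ("mean_q" %in% names(reads)) reads$mean_q
    else purrr::map_dbl(reads$quals, mean)
  } else {
    purrr::map_dbl(reads$quals, ~ -10 * log10(mean(10^(-.x / 10))))
  }
  reason <- dplyr::case_when(
    len == 0 ~ "empty",
    len <= params$min_read_len & mq <= params$min_mean_q ~ "short;low_quality",
    len <= params$min_read_len ~ "short",
    mq <= params$min_mean_q ~ "low_quality",
    TRUE ~ "pass"
  )
  dplyr::mutate(reads, qc_pass = reason == "pass", qc_reason = reason)
}

#' Split a read into fixed-length bins
#'
#' Returns exactly `floor(length / bin_len)` bins of `bin_len` nt; the
#' shorter-than-`bin_len` tail is discarded, so the concatenated bins equal
#' the read prefix of length `n_bins * bin_len`.
#'
#' @param sequence A single read sequence (character).
#' @param bin_len Bin length in nt (default 300).
#' @return Character vector of bin sequences.
#' @export
split_bins <- function(sequence, bin_len = 300) {
  stopifnot(length(sequence) == 1, is.character(sequence))
  n <- nchar(sequence) %/% bin_len
  if (n == 0) return(character())
  starts <- (seq_len(n) - 1L) * bin_len + 1L
  substring(sequence, starts, starts + bin_len - 1L)
}

#' Precompute a k-mer index of the repeat unit
#'
#' The unit is treated as circular by extending it with its own first
#' `bin_len` bases, so a bin starting anywhere on the unit (including
#' across the unit junction — the common case in a tandem array) verifies
#' against a contiguous window. Exact k-mers of the forward extended unit
#' are hashed to their start offsets.
#'
#' @param unit A [reference_unit][make_reference_unit].
#' @param k Seed k-mer length (default 15).
#' @param bin_len Bin length the index will serve.
#' @return A `unit_index` object.
#' @export
unit_index <- function(unit, k = 15, bin_len = 300) {
  stopifnot(inherits(unit, "reference_unit"))
  L <- unit$L_unit
  if (L < bin_len) abort("Unit shorter than the bin length.")
  ext <- paste0(unit$sequence, substr(unit$sequence, 1, bin_len))
  kmers <- substring(ext, seq_len(L), seq_len(L) + k - 1L)
  idx <- list2env(split(0:(L - 1L), kmers), hash = TRUE)  # 0-based offsets
  structure(list(unit = unit, L = L, k = k, bin_len = bin_len,
                 ext_int = dna_to_int(ext), kmer_env = idx),
            class = "unit_index")
}

#' @export
print.unit_index <- function(x, ...) {
  cat(sprintf("<unit_index> %d bp unit, k = %d, bin_len = %d\n",
              x$L, x$k, x$bin_len))
  invisible(x)
}

# Hamming mismatches of `bin_int` against the extended unit at 0-based
# offset `off` (window guaranteed inside the extension).
hamming_at <- function(index, bin_int, off) {
  sum(index$ext_int[(off + 1L):(off + length(bin_int))] != bin_int)
}

# Candidate 0-based unit offsets for one orientation of a bin.
seed_candidates <- function(index, bin, seed_stride) {
  k <- index$k
  starts <- seq(1L, nchar(bin) - k + 1L, by = seed_stride)
  cand <- integer(0)
  for (s in starts) {
    hits <- index$kmer_env[[substr(bin, s, s + k - 1L)]]
    if (!is.null(hits)) cand <- c(cand, (hits - (s - 1L)) %% index$L)
  }
  unique(cand)
}

#' Map one bin to the circular repeat unit
#'
#' Seed-and-verify: exact k-mer seeds from the bin are looked up in the
#' precomputed unit index; candidate offsets are verified by Hamming
#' distance over the (circularly wrapped) window; the candidate with the
#' fewest mismatches wins, ties going to the lowest unit position. Both
#' strands are tried; the fewer-mismatch strand wins, strand ties going to
#' forward. A reverse-strand hit reports the forward-unit position at which
#' the bin's reverse complement matches.
#'
#' @param bin A bin sequence of length `bin_len`.
#' @param index A [unit_index()].
#' @param max_mismatch Maximum Hamming distance for a mapping (default 60,
#'   i.e. 20% of a 300-nt bin).
#' @param seed_stride Spacing between seed k-mers along the bin.
#' @return One-row tibble: `unit_pos` (0-based, `NA` when unmapped),
#'   `strand`, `mismatches`, `mapped`.
#' @export
map_bin <- function(bin, index, max_mismatch = 60, seed_stride = index$k) {
  stopifnot(inherits(index, "unit_index"))
  if (nchar(bin) != index$bin_len) {
    abort(sprintf("Bin must be exactly %d nt.", index$bin_len))
  }
  best <- list(pos = NA_integer_, strand = NA_character_, mm = Inf)
  for (strand in c("+", "-")) {
    b <- if (strand == "+") bin else revcomp(bin)
    b_int <- dna_to_int(b)
    for (off in sort(seed_candidates(index, b, seed_stride))) {
      mm <- hamming_at(index, b_int, off)
      if (mm <= max_mismatch && mm < best$mm) {
        best <- list(pos = off, strand = strand, mm = mm)
      }
    }
  }
  mapped <- is.finite(best$mm)
  tibble(unit_pos = if (mapped) as.integer(best$pos) else NA_integer_,
         strand = if (mapped) best$strand else NA_character_,
         mismatches = if (mapped) as.integer(best$mm) else NA_integer_,
         mapped = mapped)
}

#' Map all bins of one read
#'
#' @param sequence Read sequence.
#' @param index A [unit_index()].
#' @param ... Passed to [map_bin()].
#' @return Tibble with one row per bin: `bin` (0-based index),
#'   `read_offset`, `unit_pos`, `strand`, `mismatches`, `mapped`.
#' @export
map_read_bins <- function(sequence, index, ...) {
  bins <- split_bins(sequence, index$bin_len)
  if (!length(bins)) {
    return(tibble(bin = integer(), read_offset = integer(),
                  unit_pos = integer(), strand = character(),
                  mismatches = integer(), mapped = logical()))
  }
  aln <- purrr::map_dfr(bins, map_bin, index = index, ...)
  dplyr::bind_cols(
    tibble(bin = seq_along(bins) - 1L,
           read_offset = (seq_along(bins) - 1L) * index$bin_len),
    aln
  )
}

#' Call structural variants from one read's bin alignments
#'
#' For each pair of consecutive *mapped* bins (i, j), the expected
#' reference distance is `(j - i) * bin_len` (so a gap of unmapped bins
#' scales the expectation rather than dropping the pair). The observed
#' distance is the modulo-`L_unit` displacement between the two unit
#' positions, lifted by whole units toward the expected value — a read
#' simply crossing unit junctions in the tandem array is therefore
#' deviation-free. A call is emitted when `|observed - expected|` is
#' strictly greater than `dev_tol`: positive deviations (reference skipped)
#' are deletions, negative ones insertions/duplications. Pairs with
#' discordant strands are flagged inversion-like and excluded from the
#' deviation rule.
#'
#' @param alignments Bin alignments of one read (as from [map_read_bins()]),
#'   ordered by bin index.
#' @param params A [sim_params()] (uses `bin_len`, `dev_tol`).
#' @param L_unit Unit length in bp.
#' @return Tibble of calls: `bin_i`, `bin_j`, `pos_i`, `pos_j`, `observed`,
#'   `expected`, `deviation`, `type`, `size`. When fewer than two bins are
#'   mapped the result is empty with attribute `uninformative = TRUE`.
#' @export
call_read_sv <- function(alignments, params = sim_params(), L_unit) {
  a <- dplyr::arrange(dplyr::filter(as_tibble(alignments), .data$mapped),
                      .data$bin)
  empty <- tibble(bin_i = integer(), bin_j = integer(),
                  pos_i = integer(), pos_j = integer(),
                  observed = double(), expected = double(),
                  deviation = double(), type = character(), size = double())
  if (nrow(a) < 2) {
    attr(empty, "uninformative") <- TRUE
    return(empty)
  }
  bl <- params$bin_len
  out <- vector("list", nrow(a) - 1L)
  for (i in seq_len(nrow(a) - 1L)) {
    x <- a[i, ]; y <- a[i + 1L, ]
    if (x$strand != y$strand) {
      out[[i]] <- tibble(bin_i = x$bin, bin_j = y$bin,
                         pos_i = x$unit_pos, pos_j = y$unit_pos,
                         observed = NA_real_, expected = (y$bin - x$bin) * bl,
                         deviation = NA_real_, type = "inversion-like",
                         size = NA_real_)
      next
    }
    expected <- (y$bin - x$bin) * bl
    disp <- if (x$strand == "+") y$unit_pos - x$unit_pos
            else x$unit_pos - y$unit_pos
    obs0 <- disp %% L_unit
    m <- max(0, round((expected - obs0) / L_unit))
    observed <- obs0 + m * L_unit
    deviation <- observed - expected
    if (abs(deviation) > params$dev_tol) {
      out[[i]] <- tibble(bin_i = x$bin, bin_j = y$bin,
                         pos_i = x$unit_pos, pos_j = y$unit_pos,
                         observed = observed, expected = expected,
                         deviation = deviation,
                         type = if (deviation > 0) "deletion"
                                else "insertion/duplication",
                         size = abs(deviation))
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) empty else res
}

#' Run the full long-read SV pipeline on a sample
#'
#' Chains QC filtering, bin splitting, circular-unit mapping and the
#' inter-bin deviation rule over all reads, and tallies the sample:
#' reads in, reads passing QC, reads analyzed (>= 2 mapped bins), reads
#' with at least one call, and the headline count of deletion calls of
#' size >= `min_del`. Insertion-type calls are tallied but excluded from
#' the headline deletion rate, since insertions are hard to distinguish
#' from sequencing error at these error rates. Note the caller only fires
#' above `dev_tol` (100 nt), so deletions of `min_del`..`dev_tol` nt are
#' undetectable under the literal rule.
#'
#' @param reads Read tibble (e.g. [simulate_long_reads()] or
#'   [read_reads_fastq()]).
#' @param unit A [reference_unit][make_reference_unit].
#' @param params A [sim_params()].
#' @param alignments Optional pre-mapped bin alignments (from
#'   [read_bin_sam()] / [read_bin_paf()]); when given, QC'd reads are not
#'   re-mapped internally.
#' @param ... Passed to [map_bin()].
#' @return An `sv_sample_summary`: list with `summary` (one-row tibble),
#'   `calls` (all calls, with `read_id`), `per_read` (per-read tallies).
#'   Has a [glance()] method.
#' @export
summarize_sample <- function(reads, unit, params = sim_params(),
                             alignments = NULL, ...) {
  reads <- qc_filter(reads, params)
  passing <- dplyr::filter(reads, .data$qc_pass)
  idx <- unit_index(unit, bin_len = params$bin_len)
  calls <- list(); n_analyzed <- 0L; per_read <- list()
  for (i in seq_len(nrow(passing))) {
    rid <- passing$read_id[i]
    aln <- if (is.null(alignments)) {
      map_read_bins(passing$sequence[i], idx, ...)
    } else {
      dplyr::filter(alignments, .data$read_id == rid)
    }
    if (sum(aln$mapped) >= 2) n_analyzed <- n_analyzed + 1L
    cl <- call_read_sv(aln, params, L_unit = unit$L_unit)
    cl <- dplyr::filter(cl, .data$type != "inversion-like")
    per_read[[i]] <- tibble(read_id = rid, n_bins = nrow(aln),
                            n_mapped = sum(aln$mapped), n_calls = nrow(cl))
    if (nrow(cl)) calls[[i]] <- dplyr::mutate(cl, read_id = rid,
                                              .before = 1)
  }
  calls <- dplyr::bind_rows(calls)
  per_read <- dplyr::bind_rows(per_read)
  n_sv_reads <- if (nrow(per_read)) sum(per_read$n_calls > 0) else 0L
  n_del <- if (nrow(calls)) {
    sum(calls$type == "deletion" & calls$size >= params$min_del)
  } else 0L
  summary <- tibble(
    n_reads = nrow(reads),
    n_pass_qc = nrow(passing),
    n_analyzed = n_analyzed,
    n_sv_reads = n_sv_reads,
    sv_read_fraction = if (n_analyzed > 0) n_sv_reads / n_analyzed else NA_real_,
    n_deletion_calls = n_del
  )
  structure(list(summary = summary, calls = calls, per_read = per_read,
                 params = params),
            class = "sv_sample_summary")
}

#' @export
print.sv_sample_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<sv_sample_summary> %d reads -> %d pass QC -> %d analyzed; %d with SVs (fraction %.3f); %d deletion calls >= %d nt\n",
    s$n_reads, s$n_pass_qc, s$n_analyzed, s$n_sv_reads,
    ifelse(is.na(s$sv_read_fraction), 0, s$sv_read_fraction),
    s$n_deletion_calls, x$params$min_del))
  invisible(x)
}

#' @export
glance.sv_sample_summary <- function(x, ...) x$summary

#' @export
tidy.sv_sample_summary <- function(x, ...) x$calls
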