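# Strand-specific coverage profiling: per-base read-count vectors, the
# windowed log transform used for plotting transcription profiles, and
# transcribed-fraction statistics.

#' Per-base strand-specific coverage
#'
#' Position i on strand s counts the alignment records with transcript
#' strand s whose aligned (CIGAR M) segments cover i. Deleted reference
#' bases (D) and soft-clipped read bases (S) do not contribute.
#'
#' @param records alignment-record data.frame from [read_sam()] (or the
#'   simulator), with `pos`, `cigar`, `transcript_strand`.
#' @param genome a [plastome()] (or its length as an integer).
#' @return list with integer vectors `plus` and `minus` of genome length.
#' @export
per_base_coverage <- function(records, genome) {
  L <- if (inherits(genome, "plastome")) genome$length else as.integer(genome)
  out <- list(plus = integer(L), minus = integer(L))
  if (!nrow(records)) return(out)
  blocks <- cigar_m_blocks(records$cigar, records$pos)
  if (any(blocks$ref_start < 0L) || any(blocks$ref_start + blocks$width > L)) {
    stopf("alignment beyond genome bounds (length %d)", L)
  }
  strand <- records$transcript_strand[blocks$record]
  for (s in c("+", "-")) {
    sel <- strand == s
    if (!any(sel)) next
    cov <- IRanges::coverage(
      IRanges::IRanges(start = blocks$ref_start[sel] + 1L, width = blocks$width[sel]),
      width = L
    )
    out[[if (s == "+") "plus" else "minus"]] <- as.integer(cov)
  }
  out
}

#' Windowed log-transformed coverage profile
#'
#' Coverage is summarized in non-overlapping windows (default 100 bp; the
#' final partial window is retained) as the mean per-base read count, then
#' transformed with log10(cov + 1) / log10(max cov + 1), where the maximum
#' is taken over the windows of this vector. Scores are therefore in
#' \[0, 1\], with 0 for untranscribed windows and 1 at the coverage peak.
#'
#' @param coverage integer vector of per-base counts (one strand).
#' @param window window size in bp (>= 1).
#' @return data.frame with `start`, `end` (0-based half-open), `raw`
#'   (mean per-base count) and `score` (transformed value).
#' @export
window_scores <- function(coverage, window = 100L) {
  stopifnot(window >= 1L)
  L <- length(coverage)
  if (L == 0L) stopf("empty coverage vector")
  starts <- seq(0L, L - 1L, by = window)
  ends <- pmin(starts + window, L)
  raw <- vapply(seq_along(starts),
                function(i) mean(coverage[(starts[i] + 1L):ends[i]]),
                numeric(1))
  max_raw <- max(raw)
  score <- if (max_raw > 0) log10(raw + 1) / log10(max_raw + 1) else rep(0, length(raw))
  data.frame(start = starts, end = ends, raw = raw, score = score)
}

#' Transcribed fraction of the genome
#'
#' Fraction of positions with at least `min_cov` covering reads on the plus
#' strand, the minus strand, and on either strand (union).
#'
#' @param coverage list with `plus` and `minus` per-base vectors (from
#'   [per_base_coverage()]).
#' @param min_cov minimum read count for a base to count as transcribed.
#' @return named numeric vector `c(plus, minus, combined)`.
#' @export
transcribed_fraction <- function(coverage, min_cov = 1L) {
  stopifnot(min_cov >= 1L)
  p <- coverage$plus >= min_cov
  m <- coverage$minus >= min_cov
  if (!length(p)) stopf("empty coverage")
  c(plus = mean(p), minus = mean(m), combined = mean(p | m))
}
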