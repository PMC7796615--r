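#' Construct a plastome object
#'
#' A plastome couples a circular nucleotide sequence with strand-aware CDS
#' annotations. Internally all coordinates are 0-based half-open on the plus
#' strand; GFF3's 1-based inclusive convention is converted only at the I/O
#' boundary. Features may wrap the origin, in which case `end` exceeds the
#' genome length ("unrolled" virtual coordinate) and `wraps_origin` is TRUE.
#'
#' @param id genome identifier.
#' @param sequence nucleotide string (A/C/G/T/N), the plus strand of the
#'   circular molecule.
#' @param features data.frame of CDS features with columns `gene_id`,
#'   `start`, `end` (0-based half-open), `strand` ("+"/"-"), `phase`
#'   (0/1/2) and optionally `wraps_origin`, `operon_id`.
#' @return an object of class `plastome` with elements `id`, `sequence`,
#'   `length`, `features`.
#' @export
plastome <- function(id, sequence, features = empty_features()) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stopf("plastome '%s': sequence contains characters outside A/C/G/T/N", id)
  }
  len <- nchar(sequence)
  features <- normalize_features(features, len)
  obj <- list(id = id, sequence = sequence, length = len, features = features)
  class(obj) <- "plastome"
  obj
}

empty_features <- function() {
  data.frame(
    gene_id = character(), start = integer(), end = integer(),
    strand = character(), phase = integer(), wraps_origin = logical(),
    operon_id = character(), stringsAsFactors = FALSE
  )
}

normalize_features <- function(features, genome_length) {
  stopifnot(is.data.frame(features))
  need <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss)) stopf("features missing column(s): %s", paste(miss, collapse = ", "))
  if (!"phase" %in% names(features)) features$phase <- 0L
  if (!"wraps_origin" %in% names(features)) {
    features$wraps_origin <- features$end > genome_length
  }
  if (!"operon_id" %in% names(features)) features$operon_id <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$phase <- as.integer(features$phase)
  if (nrow(features)) {
    if (any(!features$strand %in% c("+", "-"))) stopf("feature strand must be '+' or '-'")
    if (any(features$start < 0L)) stopf("negative feature start")
    bad <- features$start >= features$end
    if (any(bad)) stopf("feature '%s': start >= end", features$gene_id[bad][1L])
    too_far <- !features$wraps_origin & features$end > genome_length
    if (any(too_far)) {
      stopf("feature '%s' extends beyond genome length %d without wraps_origin",
            features$gene_id[too_far][1L], genome_length)
    }
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  features
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("plastome '%s': %d bp, %d features (%d on '+', %d on '-')\n",
              x$id, x$length, nrow(x$features),
              sum(x$features$strand == "+"), sum(x$features$strand == "-")))
  invisible(x)
}

#' Extract the signed circular gene order of a plastome
#'
#' Genes are listed in plus-strand coordinate order (the circular order read
#' clockwise); the sign of each entry records the coding strand.
#'
#' @param genome a [plastome()].
#' @return named integer vector of +1/-1 with gene ids as names, in
#'   circular order.
#' @export
gene_order <- function(genome) {
  f <- genome$features
  if (!nrow(f)) return(structure(integer(), names = character()))
  f <- f[order(f$start), , drop = FALSE]
  structure(ifelse(f$strand == "+", 1L, -1L), names = f$gene_id)
}

# Subsequence of the plus strand over [start, end) with circular wrap.
genome_subseq <- function(genome, start, end) {
  L <- genome$length
  if (end <= L) return(substr(genome$sequence, start + 1L, end))
  paste0(substr(genome$sequence, start + 1L, L), substr(genome$sequence, 1L, end - L))
}

# Spliced CDS nucleotide sequence in coding orientation (5'->3' on the
# coding strand), honouring wraps_origin.
cds_sequence <- function(genome, feature) {
  s <- genome_subseq(genome, feature$start, feature$end)
  if (feature$strand == "-") s <- revcomp(s)
  s
}
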