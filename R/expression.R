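# Strand-aware CDS read counting, TPM normalization and inter-species
# ortholog expression correlation.

#' Count sense and antisense reads per CDS
#'
#' A read is assigned to a CDS when at least half of its aligned length
#' overlaps the CDS; among CDSs meeting the rule it goes to the one with
#' the larger overlap (an exact tie is counted in both and flagged in the
#' `ambiguous` column). A read is sense for a CDS when its transcript
#' strand equals the CDS coding strand, antisense otherwise.
#'
#' @param records alignment-record data.frame (see [read_sam()]).
#' @param features CDS feature data.frame (see [plastome()]), or a
#'   [plastome()].
#' @param min_overlap minimum fraction of the read's aligned length that
#'   must overlap the CDS (default 0.5).
#' @return data.frame with one row per CDS: `gene_id`, `length`, `strand`,
#'   `sense_count`, `antisense_count`, `ambiguous`.
#' @export
count_cds_reads <- function(records, features, min_overlap = 0.5) {
  if (inherits(features, "plastome")) features <- features$features
  n_feat <- nrow(features)
  out <- data.frame(
    gene_id = features$gene_id,
    length = features$end - features$start,
    strand = features$strand,
    sense_count = integer(n_feat),
    antisense_count = integer(n_feat),
    ambiguous = integer(n_feat),
    stringsAsFactors = FALSE
  )
  if (!nrow(records) || !n_feat) return(out)
  blocks <- cigar_m_blocks(records$cigar, records$pos)
  aligned_len <- as.integer(tapply(blocks$width, blocks$record, sum))
  rec_ids <- as.integer(names(tapply(blocks$width, blocks$record, sum)))
  alen <- integer(nrow(records)); alen[rec_ids] <- aligned_len

  feat_ir <- IRanges::IRanges(start = features$start + 1L, end = features$end)
  blk_ir <- IRanges::IRanges(start = blocks$ref_start + 1L, width = blocks$width)
  hits <- IRanges::findOverlaps(blk_ir, feat_ir)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ovl <- IRanges::width(IRanges::pintersect(blk_ir[qh], feat_ir[sh]))
  # Sum overlap over a read's blocks per (read, feature).
  rec <- blocks$record[qh]
  key <- paste(rec, sh)
  agg <- rowsum(ovl, key)
  uk <- strsplit(rownames(agg), " ", fixed = TRUE)
  rec_u <- vapply(uk, function(x) as.integer(x[1L]), integer(1))
  feat_u <- vapply(uk, function(x) as.integer(x[2L]), integer(1))
  ovl_u <- as.integer(agg[, 1L])
  pass <- ovl_u >= min_overlap * alen[rec_u]
  rec_u <- rec_u[pass]; feat_u <- feat_u[pass]; ovl_u <- ovl_u[pass]
  if (!length(rec_u)) return(out)
  # Per read keep max-overlap feature(s); exact ties count in all.
  max_per_rec <- tapply(ovl_u, rec_u, max)
  is_max <- ovl_u == unname(max_per_rec[as.character(rec_u)])
  rec_u <- rec_u[is_max]; feat_u <- feat_u[is_max]
  tie <- rec_u %in% rec_u[duplicated(rec_u)]

  sense <- records$transcript_strand[rec_u] == features$strand[feat_u]
  add <- function(feat_idx) {
    t0 <- tabulate(feat_idx, nbins = n_feat)
    t0
  }
  out$sense_count <- add(feat_u[sense])
  out$antisense_count <- add(feat_u[!sense])
  out$ambiguous <- add(feat_u[tie])
  out
}

#' Transcripts-per-million normalization
#'
#' TPM_g = 1e6 * (count_g / length_g) / sum_h(count_h / length_h). With all
#' counts zero, all TPM are zero; otherwise the column sums to 1e6.
#'
#' @param counts non-negative numeric vector of read counts.
#' @param lengths positive numeric vector of CDS lengths (bp).
#' @return numeric vector of TPM values (names preserved from `counts`).
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(counts < 0)) stopf("negative read count")
  if (any(lengths <= 0)) stopf("non-positive CDS length")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) return(rep(0, length(counts)) |> stats::setNames(names(counts)))
  1e6 * rate / tot
}

#' Per-CDS expression table from alignments
#'
#' Runs [count_cds_reads()] and adds sense-read TPM. Antisense counts are
#' reported alongside but excluded from TPM, matching the convention of
#' quantifying coding-strand expression only.
#'
#' @inheritParams count_cds_reads
#' @return data.frame with `gene_id`, `length`, `strand`, `sense_count`,
#'   `antisense_count`, `ambiguous`, `tpm`.
#' @export
expression_table <- function(records, features, min_overlap = 0.5) {
  tab <- count_cds_reads(records, features, min_overlap = min_overlap)
  tab$tpm <- tpm(tab$sense_count, tab$length)
  tab
}

#' Ortholog expression correlation between two species
#'
#' Pearson correlation of transformed TPM over shared ortholog groups. The
#' default log10(TPM + 1) transform keeps the handful of very highly
#' expressed photosynthesis genes (psbA, rbcL) from dominating the
#' coefficient.
#'
#' @param table_a,table_b expression tables (from [expression_table()], or
#'   any data.frame with `gene_id` and `tpm`).
#' @param orthology data.frame with columns `group`, `species`, `gene_id`,
#'   or NULL when gene ids are directly comparable across species.
#' @param species a length-2 character vector naming the two species in
#'   `orthology` (required when `orthology` is given).
#' @param transform "log10p1" (default) or "raw".
#' @return list with `r`, `n`, `p`.
#' @export
ortholog_expression_correlation <- function(table_a, table_b, orthology = NULL,
                                            species = NULL,
                                            transform = c("log10p1", "raw")) {
  transform <- match.arg(transform)
  if (is.null(orthology)) {
    shared <- intersect(table_a$gene_id, table_b$gene_id)
    xa <- table_a$tpm[match(shared, table_a$gene_id)]
    xb <- table_b$tpm[match(shared, table_b$gene_id)]
  } else {
    stopifnot(!is.null(species), length(species) == 2L)
    oa <- orthology[orthology$species == species[1L], ]
    ob <- orthology[orthology$species == species[2L], ]
    groups <- intersect(oa$group, ob$group)
    ga <- oa$gene_id[match(groups, oa$group)]
    gb <- ob$gene_id[match(groups, ob$group)]
    keep <- ga %in% table_a$gene_id & gb %in% table_b$gene_id
    xa <- table_a$tpm[match(ga[keep], table_a$gene_id)]
    xb <- table_b$tpm[match(gb[keep], table_b$gene_id)]
  }
  if (length(xa) < 3L) stopf("fewer than 3 shared ortholog groups")
  if (transform == "log10p1") {
    xa <- log10(xa + 1)
    xb <- log10(xb + 1)
  }
  cor_test(xa, xb)
}

#' Pairwise ortholog expression correlation matrix
#'
#' @param tables named list of per-species expression tables.
#' @param orthology optional long-format orthology map (`group`, `species`,
#'   `gene_id`).
#' @param transform passed to [ortholog_expression_correlation()].
#' @return symmetric matrix of Pearson r with unit diagonal.
#' @export
expression_correlation_matrix <- function(tables, orthology = NULL,
                                          transform = "log10p1") {
  sp <- names(tables)
  stopifnot(!is.null(sp), length(sp) >= 2L)
  m <- matrix(1, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_len(i - 1L)) {
    ct <- ortholog_expression_correlation(
      tables[[i]], tables[[j]], orthology = orthology,
      species = c(sp[i], sp[j]), transform = transform
    )
    m[i, j] <- m[j, i] <- ct$r
  }
  m
}
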