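# I/O boundary: FASTA, GFF3, plain-text SAM subset, newick.
# Coordinate and strand conventions are fixed here and nowhere else.

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of upper-cased sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  if (!length(lines)) return(structure(character(), names = character()))
  hdr <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  if (any(nonblank) && !hdr[which(nonblank)[1L]]) {
    stopf("%s: line %d: sequence data before first header", path, which(nonblank)[1L])
  }
  bad <- which(nonblank & !hdr & grepl("[^ACGTNacgtn]", lines))
  if (length(bad)) {
    stopf("%s: line %d: invalid sequence character", path, bad[1L])
  }
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr & nonblank], rec[!hdr & nonblank]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- seqs
  toupper(out)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' package-internal 0-based half-open convention. In the circular "wrap
#' dialect" a feature spanning the origin is written with end > genome
#' length; such features are flagged `wraps_origin`.
#'
#' @param path file path.
#' @param genome_length genome length in bp (needed to recognize the wrap
#'   dialect); NULL disables wrap detection.
#' @param feature_type GFF3 type column value to keep (default "CDS").
#' @return data.frame of features sorted by start (see [plastome()]).
#' @export
read_gff3 <- function(path, genome_length = NULL, feature_type = "CDS") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) stopf("%s: malformed GFF3 row (expected 9 columns)", path)
  m <- do.call(rbind, parts)
  keep <- m[, 3L] %in% feature_type
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(empty_features())
  start1 <- as.integer(m[, 4L])
  end1 <- as.integer(m[, 5L])
  strand <- m[, 7L]
  if (any(!strand %in% c("+", "-"))) {
    stopf("%s: unknown strand symbol '%s'", path, strand[!strand %in% c("+", "-")][1L])
  }
  if (any(end1 < start1)) {
    i <- which(end1 < start1)[1L]
    stopf("%s: feature with end < start at row %d (wrap dialect writes end > genome length instead)",
          path, i)
  }
  phase <- suppressWarnings(as.integer(m[, 8L]))
  phase[is.na(phase)] <- 0L
  attrs <- m[, 9L]
  gene_id <- gff3_attr(attrs, "ID")
  alt <- gff3_attr(attrs, "gene")
  gene_id[is.na(gene_id)] <- alt[is.na(gene_id)]
  if (anyNA(gene_id)) stopf("%s: feature without ID or gene attribute", path)
  operon <- gff3_attr(attrs, "operon")
  wraps <- if (is.null(genome_length)) rep(FALSE, nrow(m)) else end1 > genome_length
  feats <- data.frame(
    gene_id = gene_id, start = start1 - 1L, end = end1,
    strand = strand, phase = phase, wraps_origin = wraps,
    operon_id = operon, stringsAsFactors = FALSE
  )
  key <- paste(feats$gene_id, feats$start, feats$end, feats$strand)
  if (anyDuplicated(key)) {
    warnf("%s: %d duplicate feature row(s) removed", path, sum(duplicated(key)))
    feats <- feats[!duplicated(key), , drop = FALSE]
  }
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(x) if (length(x) >= 3L) x[3L] else NA_character_,
         character(1))
}

#' Write features to GFF3
#'
#' @param genome a [plastome()], or a features data.frame plus `seqid`.
#' @param path output path.
#' @param seqid sequence id for column 1 when `genome` is a data.frame.
#' @export
write_gff3 <- function(genome, path, seqid = NULL) {
  if (inherits(genome, "plastome")) {
    feats <- genome$features
    seqid <- genome$id
    hdr <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, genome$length))
  } else {
    feats <- genome
    hdr <- "##gff-version 3"
  }
  rows <- sprintf("%s\tplastidflow\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s%s",
                  seqid, feats$start + 1L, feats$end, feats$strand, feats$phase,
                  feats$gene_id,
                  ifelse(is.na(feats$operon_id), "", paste0(";operon=", feats$operon_id)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

SAM_DROP_FLAGS <- bitwOr(bitwOr(0x4, 0x100), 0x800) # unmapped|secondary|supplementary

#' Read a plain-text SAM subset with transcript-strand assignment
#'
#' Parses the SAM dialect the simulator emits and mappers produce for
#' plastome work: header `@SQ` lines plus alignment records with CIGAR ops
#' M/I/D/S. Unmapped, secondary and supplementary records are dropped. Each
#' kept record is assigned the strand of the transcript it came from under
#' the configured strand-specific library convention.
#'
#' For the dUTP protocol (`fr-firststrand`) the first read of a pair aligns
#' antisense to the transcript, so R1 mapped to the reference minus strand
#' reports transcript strand "+", and R2 follows its own mapping strand.
#' `fr-secondstrand` is the mirror image. Single-end conventions: `reverse`
#' (read antisense to transcript) and `forward`.
#'
#' @param path SAM file path.
#' @param library_convention one of "fr-firststrand", "fr-secondstrand",
#'   "reverse", "forward".
#' @return data.frame with one row per kept record: `read_id`, `flag`,
#'   `ref_id`, `pos` (0-based), `mapq`, `cigar`, `seq`, `is_first`,
#'   `is_reverse`, `ref_width`, `transcript_strand`.
#' @export
read_sam <- function(path, library_convention = c("fr-firststrand", "fr-secondstrand",
                                                  "reverse", "forward")) {
  library_convention <- match.arg(library_convention)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  refs <- character()
  for (h in lines[hdr]) {
    if (startsWith(h, "@SQ")) {
      f <- strsplit(h, "\t", fixed = TRUE)[[1L]]
      sn <- sub("^SN:", "", f[startsWith(f, "SN:")])
      ln <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")]))
      refs[sn] <- ln
    }
  }
  body <- lines[!hdr]
  if (!length(body)) {
    return(sam_records(character(), integer(), character(), integer(),
                       integer(), character(), character(), library_convention))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 11L)) stopf("%s: SAM record with fewer than 11 fields", path)
  m <- t(vapply(parts, function(x) x[1:11], character(11)))
  flag <- as.integer(m[, 2L])
  keep <- bitwAnd(flag, SAM_DROP_FLAGS) == 0L
  m <- m[keep, , drop = FALSE]
  flag <- flag[keep]
  ref_id <- m[, 3L]
  unknown <- setdiff(unique(ref_id), names(refs))
  if (length(unknown)) stopf("%s: record references '%s' with no @SQ header line", path, unknown[1L])
  sam_records(read_id = m[, 1L], flag = flag, ref_id = ref_id,
              pos = as.integer(m[, 4L]) - 1L, mapq = as.integer(m[, 5L]),
              cigar = m[, 6L], seq = m[, 10L],
              library_convention = library_convention)
}

# Assemble the alignment-record data.frame and derive transcript_strand.
sam_records <- function(read_id, flag, ref_id, pos, mapq, cigar, seq,
                        library_convention) {
  ref_width <- cigar_ref_width(cigar)
  is_paired <- bitwAnd(flag, 0x1) > 0L
  is_first <- bitwAnd(flag, 0x40) > 0L
  is_reverse <- bitwAnd(flag, 0x10) > 0L
  map_strand <- ifelse(is_reverse, "-", "+")
  ts <- switch(library_convention,
    "fr-firststrand" = ifelse(is_paired & is_first,
                              ifelse(is_reverse, "+", "-"),
                              ifelse(is_reverse, "-", "+")),
    "fr-secondstrand" = ifelse(is_paired & is_first,
                               ifelse(is_reverse, "-", "+"),
                               ifelse(is_reverse, "+", "-")),
    "reverse" = ifelse(is_reverse, "+", "-"),
    "forward" = map_strand
  )
  data.frame(read_id = read_id, flag = flag, ref_id = ref_id, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq,
             is_first = is_first, is_reverse = is_reverse,
             ref_width = ref_width, transcript_strand = ts,
             stringsAsFactors = FALSE)
}

# Reference span consumed by a CIGAR (M and D ops). Errors on unsupported ops.
cigar_ref_width <- function(cigar) {
  if (!length(cigar)) return(integer())
  u <- unique(cigar)
  w <- vapply(u, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "D")])
  }, integer(1))
  unname(w[match(cigar, u)])
}

cigar_ops <- function(cg) {
  m <- gregexpr("[0-9]+[A-Z=]", cg)[[1L]]
  toks <- regmatches(cg, list(m))[[1L]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(cg)) {
    stopf("malformed CIGAR: %s", cg)
  }
  op <- substr(toks, nchar(toks), nchar(toks))
  bad <- setdiff(op, c("M", "I", "D", "S"))
  if (length(bad)) stopf("unsupported CIGAR op '%s' in %s (supported: M/I/D/S)", bad[1L], cg)
  list(op = op, len = as.integer(sub("[A-Z=]$", "", toks)))
}

# Per-record aligned (M) blocks in reference and query coordinates.
# Returns data.frame(record, ref_start (0-based), width, query_start (0-based)).
cigar_m_blocks <- function(cigar, pos) {
  u <- unique(cigar)
  per <- lapply(u, function(cg) {
    ops <- cigar_ops(cg)
    ref_off <- 0L; q_off <- 0L
    out <- list()
    for (i in seq_along(ops$op)) {
      op <- ops$op[i]; len <- ops$len[i]
      if (op == "M") {
        out[[length(out) + 1L]] <- c(ref_off, len, q_off)
        ref_off <- ref_off + len; q_off <- q_off + len
      } else if (op == "D") {
        ref_off <- ref_off + len
      } else { # I or S consume query only
        q_off <- q_off + len
      }
    }
    do.call(rbind, out)
  })
  names(per) <- u
  idx <- match(cigar, u)
  nb <- vapply(per, nrow, integer(1))[idx]
  rec <- rep(seq_along(cigar), nb)
  blk <- do.call(rbind, per[idx])
  data.frame(record = rec,
             ref_start = pos[rec] + blk[, 1L],
             width = blk[, 2L],
             query_start = blk[, 3L])
}

#' Write alignment records to a plain-text SAM file
#'
#' @param records alignment-record data.frame (as from [read_sam()] or the
#'   simulator); columns beyond the SAM fields are ignored.
#' @param refs named integer vector of reference lengths for `@SQ` lines.
#' @param path output path.
#' @export
write_sam <- function(records, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  if (nrow(records)) {
    rnext <- records$rnext %||% rep("=", nrow(records))
    pnext <- records$pnext %||% rep(0L, nrow(records))
    tlen <- records$tlen %||% rep(0L, nrow(records))
    rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                    records$read_id, records$flag, records$ref_id,
                    records$pos + 1L, records$mapq %||% 60L, records$cigar,
                    rnext, pnext + 1L, tlen, records$seq)
  } else rows <- character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a phylogenetic tree from a newick file
#'
#' @param path newick file path.
#' @return an [ape::read.tree()] "phylo" object; missing branch lengths are
#'   replaced by 0 with a warning.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("%s: newick parse error: %s", path, conditionMessage(e)))
  if (is.null(tree)) stopf("%s: newick parse error", path)
  if (is.null(tree$edge.length)) {
    warnf("%s: tree has no branch lengths; using 0", path)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warnf("%s: %d branch(es) without length; using 0", path, sum(is.na(tree$edge.length)))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Validate a plastome against its annotations
#'
#' Checks the structural invariants: sequence alphabet, feature intervals in
#' range after circular normalization, and frame-completeness of CDSs.
#'
#' @param genome a [plastome()].
#' @return TRUE invisibly; errors describe the first violated invariant.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "plastome"))
  if (genome$length != nchar(genome$sequence)) stopf("length field disagrees with sequence")
  f <- genome$features
  if (nrow(f)) {
    if (any(f$start < 0L | f$start >= genome$length)) stopf("feature start outside [0, length)")
    if (any(!f$wraps_origin & f$end > genome$length)) stopf("non-wrapping feature beyond genome end")
    if (any(f$wraps_origin & (f$end - genome$length) > f$start)) stopf("wrapping feature longer than genome")
    off <- (f$end - f$start) %% 3L != 0L
    if (any(off)) warnf("CDS length not a multiple of 3 for: %s",
                        paste(f$gene_id[off], collapse = ", "))
  }
  invisible(TRUE)
}
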