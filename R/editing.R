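# Strand-aware C-to-U RNA-editing detection and classification.
#
# Editing is read out per transcript strand: a site on a '+' transcript is a
# reference C whose covering '+'-strand reads show T; a site on a '-'
# transcript is a reference G on the plus strand (a C on the transcript)
# whose covering '-'-strand reads show A when projected onto the plus
# strand. Pileups are therefore kept separately per transcript strand, with
# all read bases projected to plus-strand coordinates.

BASES <- c("A", "C", "G", "T")

#' Strand-separated base pileup
#'
#' Per position and per transcript strand, the counts of A/C/G/T among
#' covering read bases (projected onto the plus reference strand).
#' Soft-clipped bases are excluded and deletions skipped; each mate of a
#' pair is counted independently.
#'
#' @param records alignment-record data.frame with `pos`, `cigar`, `seq`,
#'   `transcript_strand`.
#' @param genome a [plastome()] (or integer genome length).
#' @return list with `plus` and `minus`: integer matrices of dimension
#'   genome length x 4 with columns A, C, G, T.
#' @export
build_pileup <- function(records, genome) {
  L <- if (inherits(genome, "plastome")) genome$length else as.integer(genome)
  empty <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  out <- list(plus = empty, minus = empty)
  if (!nrow(records)) return(out)
  blocks <- cigar_m_blocks(records$cigar, records$pos)
  if (any(blocks$ref_start < 0L) || any(blocks$ref_start + blocks$width > L)) {
    stopf("alignment beyond genome bounds (length %d)", L)
  }
  # Expand M blocks to (position, base) pairs.
  n_bases <- sum(blocks$width)
  rec <- rep.int(blocks$record, blocks$width)
  offs <- sequence(blocks$width) - 1L
  pos <- rep.int(blocks$ref_start, blocks$width) + offs
  qpos <- rep.int(blocks$query_start, blocks$width) + offs
  base_chr <- substring(records$seq[rec], qpos + 1L, qpos + 1L)
  code <- match(base_chr, BASES) # N and others -> NA, dropped
  strand <- records$transcript_strand[rec]
  for (s in c("+", "-")) {
    sel <- strand == s & !is.na(code)
    if (!any(sel)) next
    lin <- (code[sel] - 1L) * L + pos[sel] + 1L
    cnt <- tabulate(lin, nbins = 4L * L)
    out[[if (s == "+") "plus" else "minus"]] <- matrix(
      cnt, nrow = L, ncol = 4L, dimnames = list(NULL, BASES)
    )
  }
  out
}

#' Caller thresholds for C-to-U editing detection
#'
#' Defaults follow the standard variant-style filter for plastid editing:
#' minimum coverage 50, minimum variant frequency 0.1 and maximum variant
#' p-value 1e-6, with the p-value from an exact one-sided binomial tail
#' test against a per-base sequencing error rate (default 0.001, about
#' Q30).
#'
#' @param min_coverage minimum edited+unedited base count at the site.
#' @param min_variant_frequency minimum edited/(edited+unedited).
#' @param max_p_value maximum binomial tail probability.
#' @param base_error_rate assumed per-base error rate for the null.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(min_coverage = 50L, min_variant_frequency = 0.1,
                          max_p_value = 1e-6, base_error_rate = 0.001) {
  stopifnot(min_coverage >= 1L,
            min_variant_frequency >= 0, min_variant_frequency <= 1,
            max_p_value > 0, max_p_value <= 1,
            base_error_rate >= 0, base_error_rate < 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_variant_frequency = min_variant_frequency,
                 max_p_value = max_p_value,
                 base_error_rate = base_error_rate),
            class = "caller_config")
}

#' Call C-to-U editing sites from a stranded pileup
#'
#' A site is called at (position, strand) when the transcript-strand
#' reference base is C (a plus-strand C for '+' transcripts, a plus-strand
#' G for '-' transcripts, whose edited reads show plus-strand A), the
#' informative coverage n = edited + unedited is at least `min_coverage`,
#' the editing fraction edited/n is at least `min_variant_frequency`, and
#' the one-sided binomial tail P(X >= edited | n, error rate) is at most
#' `max_p_value`. Bases other than the C-like and T-like states are
#' excluded from n.
#'
#' @param pileup stranded pileup from [build_pileup()].
#' @param genome a [plastome()].
#' @param config a [caller_config()].
#' @return data.frame of editing sites: `position` (0-based), `strand`,
#'   `edited_count`, `unedited_count`, `efficiency`, `edited_unedited_ratio`,
#'   `p_value`.
#' @export
call_c2u <- function(pileup, genome, config = caller_config()) {
  stopifnot(inherits(genome, "plastome"), inherits(config, "caller_config"))
  ref <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  call_one <- function(mat, strand) {
    if (strand == "+") {
      cand <- which(ref == "C")
      unedited <- mat[cand, "C"]
      edited <- mat[cand, "T"]
    } else {
      cand <- which(ref == "G")
      unedited <- mat[cand, "G"]
      edited <- mat[cand, "A"]
    }
    n <- edited + unedited
    keep <- n >= config$min_coverage & edited / pmax(n, 1L) >= config$min_variant_frequency
    if (!any(keep)) return(NULL)
    cand <- cand[keep]; edited <- edited[keep]; unedited <- unedited[keep]; n <- n[keep]
    p <- stats::pbinom(edited - 1L, n, config$base_error_rate, lower.tail = FALSE)
    keep2 <- p <= config$max_p_value
    if (!any(keep2)) return(NULL)
    data.frame(position = cand[keep2] - 1L, strand = strand,
               edited_count = edited[keep2], unedited_count = unedited[keep2],
               efficiency = edited[keep2] / n[keep2],
               edited_unedited_ratio = edited[keep2] / pmax(unedited[keep2], 1L),
               p_value = p[keep2], stringsAsFactors = FALSE)
  }
  out <- rbind(call_one(pileup$plus, "+"), call_one(pileup$minus, "-"))
  if (is.null(out)) {
    out <- data.frame(position = integer(), strand = character(),
                      edited_count = integer(), unedited_count = integer(),
                      efficiency = numeric(), edited_unedited_ratio = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  }
  out[order(out$position), , drop = FALSE]
}

#' Classify editing sites as silent, non-silent, antisense or noncoding
#'
#' A site inside a CDS whose coding strand equals the site's transcript
#' strand is translated (plastid/bacterial genetic code, table 11) before
#' and after the C-to-U change: an unchanged amino acid is `silent`,
#' otherwise `non_silent`. A site inside a CDS on the opposite transcript
#' strand is `antisense`; a site outside all CDSs is `noncoding`. When
#' CDSs overlap, a sense assignment takes priority over antisense.
#'
#' @param sites data.frame from [call_c2u()].
#' @param features CDS features (frame-complete for sense classification),
#'   or a [plastome()].
#' @param genome a [plastome()].
#' @return `sites` with added columns `category`, `gene_id`,
#'   `codon_position` (1-3), `aa_change` (e.g. "S->L").
#' @export
classify_sites <- function(sites, features, genome) {
  if (inherits(features, "plastome")) features <- features$features
  n <- nrow(sites)
  sites$category <- rep(NA_character_, n)
  sites$gene_id <- rep(NA_character_, n)
  sites$codon_position <- rep(NA_integer_, n)
  sites$aa_change <- rep(NA_character_, n)
  if (!n) return(sites)
  code11 <- Biostrings::getGeneticCode("11")
  cds_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    pos <- sites$position[i]
    ts <- sites$strand[i]
    # Features containing pos (incl. origin-wrapping features, unrolled).
    inside <- (pos >= features$start & pos < features$end) |
      (features$wraps_origin & (pos + genome$length) >= features$start &
         (pos + genome$length) < features$end)
    if (!any(inside)) {
      sites$category[i] <- "noncoding"
      next
    }
    idx <- which(inside)
    sense_idx <- idx[features$strand[idx] == ts]
    if (!length(sense_idx)) {
      sites$category[i] <- "antisense"
      sites$gene_id[i] <- features$gene_id[idx[1L]]
      next
    }
    fi <- sense_idx[1L]
    feat <- features[fi, ]
    if ((feat$end - feat$start) %% 3L != 0L) {
      warnf("site %d: CDS '%s' length not a multiple of 3; classification skipped",
            pos, feat$gene_id)
      sites$gene_id[i] <- feat$gene_id
      next
    }
    key <- feat$gene_id
    if (is.null(cds_cache[[key]])) cds_cache[[key]] <- cds_sequence(genome, feat)
    cds <- cds_cache[[key]]
    upos <- if (feat$wraps_origin && pos < feat$start) pos + genome$length else pos
    pos_in_cds <- if (feat$strand == "+") upos - feat$start else feat$end - 1L - upos
    codon_i <- pos_in_cds %/% 3L
    off <- pos_in_cds %% 3L
    codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    if (substr(codon, off + 1L, off + 1L) != "C") {
      stopf("internal error: site %d is not a C on the coding strand of '%s'",
            pos, feat$gene_id)
    }
    edited <- codon
    substr(edited, off + 1L, off + 1L) <- "T"
    aa0 <- unname(code11[codon])
    aa1 <- unname(code11[edited])
    sites$category[i] <- if (identical(aa0, aa1)) "silent" else "non_silent"
    sites$gene_id[i] <- feat$gene_id
    sites$codon_position[i] <- off + 1L
    sites$aa_change[i] <- paste0(aa0, "->", aa1)
  }
  sites
}

#' Codon-aware ortholog alignment positions
#'
#' Aligns orthologous CDS nucleotide sequences via their amino-acid
#' translations (plastid/bacterial code, global alignment with affine
#' gaps, BLOSUM62), then back-maps to nucleotide columns. Multiple species
#' are handled as a star alignment around the longest sequence: every
#' nucleotide position is assigned the coordinate of the centre-sequence
#' position it aligns to (NA for insertions relative to the centre), so two
#' positions from different species share an alignment column iff they map
#' to the same centre coordinate.
#'
#' @param seqs named character vector of CDS nucleotide sequences (coding
#'   orientation; lengths multiples of 3). Sequences with internal stop
#'   codons are excluded with a warning.
#' @param gap_opening,gap_extension affine gap penalties for the
#'   amino-acid alignment.
#' @return list with `columns`: per-species integer vector mapping each
#'   0-based nucleotide position to a 0-based alignment column (NA =
#'   insertion relative to the centre); `center`: name of the centre
#'   sequence; `scores`: per-species amino-acid alignment score against the
#'   centre (NA for the centre itself); `excluded`: names of excluded
#'   sequences.
#' @export
align_orthologs <- function(seqs, gap_opening = 10, gap_extension = 0.5) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  bad_len <- nchar(seqs) %% 3L != 0L
  if (any(bad_len)) stopf("CDS length not a multiple of 3: %s",
                          paste(names(seqs)[bad_len], collapse = ", "))
  code11 <- Biostrings::getGeneticCode("11")
  aa <- vapply(seqs, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       genetic.code = code11, no.init.codon = TRUE))
  }, character(1))
  # Trim one trailing stop; internal stops disqualify the sequence.
  aa <- sub("\\*$", "", aa)
  internal_stop <- grepl("\\*", aa)
  if (any(internal_stop)) {
    warnf("internal stop codon, excluded from alignment: %s",
          paste(names(seqs)[internal_stop], collapse = ", "))
  }
  keep <- names(seqs)[!internal_stop]
  if (length(keep) < 2L) stopf("fewer than 2 alignable sequences")
  center <- keep[which.max(nchar(seqs[keep]))]
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- data_env$BLOSUM62
  columns <- vector("list", length(keep))
  names(columns) <- keep
  scores <- stats::setNames(rep(NA_real_, length(keep)), keep)
  for (sp in keep) {
    n_nt <- nchar(seqs[[sp]])
    if (sp == center) {
      columns[[sp]] <- seq_len(n_nt) - 1L
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(aa[[sp]]),
      subject = Biostrings::AAString(aa[[center]]),
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    scores[sp] <- Biostrings::score(aln)
    p_chr <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    s_chr <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    # Map each pattern (species) AA index to a subject (centre) AA index.
    aa_map <- rep(NA_integer_, nchar(aa[[sp]]))
    pi <- 0L; si <- 0L
    for (k in seq_along(p_chr)) {
      is_p <- p_chr[k] != "-"
      is_s <- s_chr[k] != "-"
      if (is_p) pi <- pi + 1L
      if (is_s) si <- si + 1L
      if (is_p && is_s) aa_map[pi] <- si
    }
    nt_map <- rep(NA_integer_, n_nt)
    pos <- seq_len(n_nt) - 1L
    aa_idx <- pos %/% 3L + 1L
    valid <- aa_idx <= length(aa_map) & !is.na(aa_map[aa_idx])
    nt_map[valid] <- (aa_map[aa_idx[valid]] - 1L) * 3L + pos[valid] %% 3L
    columns[[sp]] <- nt_map
  }
  list(columns = columns, center = center, scores = scores,
       excluded = names(seqs)[internal_stop])
}

# Map a site's genomic position to a 0-based position within its CDS,
# in coding orientation.
site_pos_in_cds <- function(position, feature, genome_length) {
  upos <- if (feature$wraps_origin && position < feature$start) {
    position + genome_length
  } else position
  if (feature$strand == "+") upos - feature$start else feature$end - 1L - upos
}

#' Shared vs specific editing sites across species
#'
#' Maps each classified site to a codon-aware alignment column of its
#' ortholog group and labels it `shared` when two or more species carry a
#' called site of the same strand class (sense/antisense) in the same
#' column of the same group, otherwise `specific`. Sites in genes absent
#' from the orthology map stay `specific` with a warning. Also returns
#' UpSet-style exclusive intersection counts over species combinations.
#'
#' @param sites_by_species named list of classified site tables
#'   ([classify_sites()] output; sense sites need `gene_id`).
#' @param genomes named list of [plastome()] objects (same names).
#' @param orthology long-format data.frame (`group`, `species`, `gene_id`).
#' @return list with `sites` (row-bound site table with `species`,
#'   `group`, `column`, `sharing` columns) and `intersections`
#'   (data.frame `combo`, `count`: exclusive counts of distinct shared-site
#'   columns per species combination).
#' @export
shared_specific <- function(sites_by_species, genomes, orthology) {
  sp <- names(sites_by_species)
  stopifnot(!is.null(sp), all(sp %in% names(genomes)))
  all_sites <- do.call(rbind, lapply(sp, function(s) {
    x <- sites_by_species[[s]]
    if (!nrow(x)) return(NULL)
    x$species <- s
    x
  }))
  if (is.null(all_sites) || !nrow(all_sites)) {
    return(list(sites = data.frame(), intersections = data.frame(combo = character(), count = integer())))
  }
  all_sites$group <- NA_character_
  all_sites$column <- NA_integer_
  # Sense class uses the site's own gene; antisense uses the overlapped gene
  # too (gene_id is filled for both by classify_sites).
  with_gene <- which(!is.na(all_sites$gene_id))
  if (length(with_gene)) {
    key <- paste(all_sites$species[with_gene], all_sites$gene_id[with_gene])
    okey <- paste(orthology$species, orthology$gene_id)
    grp <- orthology$group[match(key, okey)]
    all_sites$group[with_gene] <- grp
    orphan <- with_gene[is.na(grp)]
    if (length(orphan)) {
      warnf("%d site(s) in genes absent from the orthology map; labelled specific",
            length(orphan))
    }
  }
  # Align each ortholog group once and map site positions to columns.
  for (g in unique(stats::na.omit(all_sites$group))) {
    rows <- which(all_sites$group == g)
    gsp <- orthology[orthology$group == g, ]
    gsp <- gsp[gsp$species %in% sp, ]
    seqs <- vapply(seq_len(nrow(gsp)), function(k) {
      gen <- genomes[[gsp$species[k]]]
      fi <- which(gen$features$gene_id == gsp$gene_id[k])[1L]
      if (is.na(fi)) return(NA_character_)
      cds_sequence(gen, gen$features[fi, ])
    }, character(1))
    names(seqs) <- gsp$species
    seqs <- seqs[!is.na(seqs) & nchar(seqs) %% 3L == 0L]
    if (length(seqs) < 2L) next
    aln <- tryCatch(align_orthologs(seqs), error = function(e) NULL)
    if (is.null(aln)) next
    for (r in rows) {
      s <- all_sites$species[r]
      if (!s %in% names(aln$columns)) next
      gen <- genomes[[s]]
      fi <- which(gen$features$gene_id == all_sites$gene_id[r])[1L]
      pic <- site_pos_in_cds(all_sites$position[r], gen$features[fi, ], gen$length)
      if (pic >= 0L && pic < length(aln$columns[[s]])) {
        all_sites$column[r] <- aln$columns[[s]][pic + 1L]
      }
    }
  }
  # Strand class: sense vs antisense relative to the gene.
  strand_class <- ifelse(all_sites$category == "antisense", "antisense", "sense")
  site_key <- ifelse(is.na(all_sites$group) | is.na(all_sites$column),
                     NA_character_,
                     paste(all_sites$group, all_sites$column, strand_class))
  all_sites$sharing <- "specific"
  if (any(!is.na(site_key))) {
    nsp <- tapply(all_sites$species, site_key, function(x) length(unique(x)))
    shared_keys <- names(nsp)[nsp >= 2L]
    all_sites$sharing[!is.na(site_key) & site_key %in% shared_keys] <- "shared"
  }
  # Exclusive intersection counts over distinct site keys (UpSet-style);
  # keyless sites count as singleton combos of their own species.
  combo_of <- character(0)
  ok <- !is.na(site_key)
  if (any(ok)) {
    combo_of <- tapply(all_sites$species[ok], site_key[ok],
                       function(x) paste(sort(unique(x)), collapse = "&"))
  }
  lone <- all_sites$species[!ok]
  combos <- c(as.character(combo_of), lone)
  tab <- table(combos)
  intersections <- data.frame(combo = names(tab), count = as.integer(tab),
                              stringsAsFactors = FALSE)
  list(sites = all_sites, intersections = intersections)
}

#' Per-species editing summary
#'
#' Counts and proportions per category, the efficiency distribution per
#' category, and (when present) shared/specific proportions.
#'
#' @param sites classified site table for one species (optionally with a
#'   `sharing` column).
#' @return list with `n_sites`, `category_counts`, `category_proportions`,
#'   `efficiency_by_category` (summary stats), and `sharing_counts` if
#'   available.
#' @export
editing_summary <- function(sites) {
  cats <- c("silent", "non_silent", "antisense", "noncoding")
  if (!nrow(sites)) {
    return(list(n_sites = 0L,
                category_counts = stats::setNames(integer(4), cats),
                category_proportions = stats::setNames(rep(NA_real_, 4), cats),
                efficiency_by_category = NULL))
  }
  cc <- stats::setNames(integer(4), cats)
  tab <- table(factor(sites$category, levels = cats))
  cc[names(tab)] <- as.integer(tab)
  eff <- lapply(split(sites$efficiency, factor(sites$category, levels = cats)),
                function(x) if (length(x)) c(mean = mean(x), median = stats::median(x),
                                             min = min(x), max = max(x)) else NULL)
  out <- list(n_sites = nrow(sites),
              category_counts = cc,
              category_proportions = cc / nrow(sites),
              efficiency_by_category = eff)
  if ("sharing" %in% names(sites)) {
    out$sharing_counts <- table(factor(sites$sharing, levels = c("shared", "specific")))
  }
  out
}
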