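# Synthetic plastomes and stranded transcriptome simulation.
#
# The generator states a small world with the features the analysis needs
# to be exercised against: a circular genome of operon-structured genes on
# both strands, segmental inversions with endpoints in intergenic spacers,
# polycistronic transcription with geometric read-through past terminators,
# a pervasive low-level antisense/intergenic background (so combined-strand
# transcribed fraction approaches 100%), injected C-to-U edits at set
# efficiencies, and dUTP-protocol (fr-firststrand) paired reads with
# per-base errors, emitted directly as alignments. Every stochastic step is
# a pure function of (inputs, seed); the transcript pool itself is the
# model's deterministic expectation, so manifest quantities are exact.

#' Simulation configuration
#'
#' @param n_genes number of CDSs.
#' @param n_operons number of operons (contiguous same-strand gene groups).
#' @param gene_length_range min/max CDS length in bp (rounded to codons);
#'   the default spans the typical plastid CDS range (psbA ~1.1 kb,
#'   rbcL ~1.4 kb, many ribosomal-protein genes 300-500 bp).
#' @param spacer_length_range min/max intergenic spacer length in bp.
#' @param n_read_pairs number of read pairs to simulate.
#' @param read_length read length in bp.
#' @param fragment_length constant fragment (insert) length in bp.
#' @param base_error_rate per-base sequencing error rate (< 0.1).
#' @param readthrough_prob probability that transcription continues past an
#'   operon terminator into the next downstream unit (geometric per
#'   terminator).
#' @param antisense_rate genome-wide pervasive transcription rate relative
#'   to the mean operon rate.
#' @param rate_sdlog log-normal sd of per-operon transcription rates
#'   (meanlog 0), giving the orders-of-magnitude spread seen between
#'   photosystem genes and lowly expressed CDSs.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 24L, n_operons = 8L,
                       gene_length_range = c(300L, 1500L),
                       spacer_length_range = c(60L, 200L),
                       n_read_pairs = 20000L, read_length = 100L,
                       fragment_length = 180L, base_error_rate = 0.001,
                       readthrough_prob = 0.2, antisense_rate = 0.02,
                       rate_sdlog = 1, seed = 1L) {
  stopifnot(n_genes >= 2L, n_operons >= 1L, n_operons <= n_genes,
            n_read_pairs >= 1L, read_length >= 1L,
            fragment_length >= read_length,
            base_error_rate >= 0, base_error_rate < 0.1,
            readthrough_prob >= 0, readthrough_prob <= 1,
            antisense_rate >= 0, rate_sdlog >= 0,
            gene_length_range[1L] >= 3L,
            spacer_length_range[1L] >= 1L)
  structure(list(n_genes = as.integer(n_genes), n_operons = as.integer(n_operons),
                 gene_length_range = as.integer(gene_length_range),
                 spacer_length_range = as.integer(spacer_length_range),
                 n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 base_error_rate = base_error_rate,
                 readthrough_prob = readthrough_prob,
                 antisense_rate = antisense_rate,
                 rate_sdlog = rate_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a synthetic operon-structured plastome
#'
#' Genes are laid out without overlap, grouped into contiguous operons that
#' alternate strand at random; per-operon transcription rates are
#' log-normal. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param id genome identifier.
#' @return list with `genome` ([plastome()]), `model` (operon model: data
#'   frame of operons plus read-through and antisense parameters) and
#'   `manifest` (ground-truth accumulator).
#' @export
build_genome <- function(config, id = "synth1") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    no <- config$n_operons
    glr <- config$gene_length_range
    slr <- config$spacer_length_range
    gene_len <- 3L * sample(seq(glr[1L] %/% 3L, glr[2L] %/% 3L), ng, replace = TRUE)
    spacer_len <- sample(seq(slr[1L], slr[2L]), ng + 1L, replace = TRUE)
    # Contiguous operon membership: split genes into no groups.
    sizes <- rep(ng %/% no, no) + c(rep(1L, ng %% no), rep(0L, no - ng %% no))
    op_of_gene <- rep(seq_len(no), sizes)
    op_strand <- sample(c("+", "-"), no, replace = TRUE)
    pos <- 0L
    start <- integer(ng); end <- integer(ng)
    for (i in seq_len(ng)) {
      pos <- pos + spacer_len[i]
      start[i] <- pos
      end[i] <- pos + gene_len[i]
      pos <- end[i]
    }
    L <- pos + spacer_len[ng + 1L]
    seq_chr <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    feats <- data.frame(
      gene_id = sprintf("g%02d", seq_len(ng)),
      start = start, end = end,
      strand = op_strand[op_of_gene],
      phase = 0L, wraps_origin = FALSE,
      operon_id = sprintf("op%02d", op_of_gene),
      stringsAsFactors = FALSE
    )
    genome <- plastome(id, seq_chr, feats)
    rate <- stats::rlnorm(no, meanlog = 0, sdlog = config$rate_sdlog)
    ops <- data.frame(
      operon_id = sprintf("op%02d", seq_len(no)),
      strand = op_strand,
      start = vapply(seq_len(no), function(o) min(start[op_of_gene == o]), integer(1)),
      end = vapply(seq_len(no), function(o) max(end[op_of_gene == o]), integer(1)),
      rate = rate, stringsAsFactors = FALSE
    )
    model <- structure(list(operons = ops,
                            readthrough_prob = config$readthrough_prob,
                            antisense_rate = config$antisense_rate),
                       class = "operon_model")
    manifest <- list(inversions = data.frame(start = integer(), end = integer()),
                     edits = NULL)
    list(genome = genome, model = model, manifest = manifest)
  })
}

# Intergenic spacer intervals strictly between consecutive genes.
internal_spacers <- function(genome) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  n <- nrow(f)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = f$end[-n], end = f$start[-1L])
}

#' Apply segmental inversions with endpoints in intergenic spacers
#'
#' Draws `2k` distinct internal spacers, pairs them in coordinate order
#' into `k` disjoint intervals (so inversions are endpoint-disjoint and
#' each contains at least one whole gene), and inverts each: the sequence
#' is reverse-complemented and contained features are strand-flipped and
#' reordered. Gene integrity is preserved because endpoints never fall
#' inside genes.
#'
#' @param genome a [plastome()].
#' @param k number of inversions (>= 0).
#' @param seed RNG seed.
#' @param log an inversion log to re-apply instead of drawing new
#'   intervals (applying a log twice restores the original genome).
#' @return list with `genome` (derived [plastome()]) and `log`
#'   (data.frame `start`, `end` of each inverted interval).
#' @export
apply_inversions <- function(genome, k, seed = 1L, log = NULL) {
  stopifnot(inherits(genome, "plastome"))
  if (is.null(log)) {
    stopifnot(k >= 0L)
    if (k == 0L) return(list(genome = genome, log = data.frame(start = integer(), end = integer())))
    sp <- internal_spacers(genome)
    if (2L * k > nrow(sp)) {
      stopf("k = %d inversions need %d distinct spacers; only %d available", k, 2L * k, nrow(sp))
    }
    log <- with_seed(seed, {
      picks <- sort(sample.int(nrow(sp), 2L * k))
      cuts <- (sp$start[picks] + sp$end[picks]) %/% 2L
      data.frame(start = cuts[seq(1L, 2L * k, by = 2L)],
                 end = cuts[seq(2L, 2L * k, by = 2L)])
    })
  }
  seq_chr <- genome$sequence
  feats <- genome$features
  for (i in seq_len(nrow(log))) {
    a <- log$start[i]; b <- log$end[i]
    stopifnot(a < b, b <= genome$length)
    inside <- feats$start >= a & feats$end <= b
    straddle <- !inside & feats$start < b & feats$end > a
    if (any(straddle)) stopf("inversion [%d,%d) cuts feature '%s'", a, b,
                             feats$gene_id[straddle][1L])
    seq_chr <- paste0(substr(seq_chr, 1L, a),
                      revcomp(substr(seq_chr, a + 1L, b)),
                      substr(seq_chr, b + 1L, nchar(seq_chr)))
    new_start <- a + (b - feats$end[inside])
    new_end <- a + (b - feats$start[inside])
    feats$start[inside] <- new_start
    feats$end[inside] <- new_end
    feats$strand[inside] <- ifelse(feats$strand[inside] == "+", "-", "+")
  }
  list(genome = plastome(genome$id, seq_chr, feats), log = log)
}

# Rebuild transcription units on a (possibly rearranged) genome: maximal
# runs of coordinate-adjacent genes sharing operon_id and strand. A unit
# inherits its source operon's rate, so an operon split by an inversion
# yields two units transcribed at the old rate.
derive_operon_model <- function(genome, model) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  if (!nrow(f)) stopf("genome has no features")
  brk <- c(TRUE, f$operon_id[-1L] != f$operon_id[-nrow(f)] |
             f$strand[-1L] != f$strand[-nrow(f)])
  unit <- cumsum(brk)
  rate_of <- stats::setNames(model$operons$rate, model$operons$operon_id)
  ops <- do.call(rbind, lapply(split(seq_len(nrow(f)), unit), function(ix) {
    data.frame(operon_id = paste0(f$operon_id[ix[1L]], letters[sum(unit[seq_len(ix[1L])] == unit[ix[1L]])]),
               strand = f$strand[ix[1L]],
               start = min(f$start[ix]), end = max(f$end[ix]),
               rate = unname(rate_of[f$operon_id[ix[1L]]]),
               stringsAsFactors = FALSE)
  }))
  ops$operon_id <- sprintf("u%02d", seq_len(nrow(ops)))
  rownames(ops) <- NULL
  structure(list(operons = ops,
                 readthrough_prob = model$readthrough_prob,
                 antisense_rate = model$antisense_rate),
            class = "operon_model")
}

#' Expected transcript pool under the operon model
#'
#' Emits the model's expectation as a deterministic pool of weighted
#' intervals: each transcription unit yields its primary transcript at
#' weight rate*(1-p) plus geometric read-through extensions into the next
#' m downstream units at weight rate*p^m*(1-p) (the final, one-lap-capped
#' extension absorbs the remaining tail mass), and a tiling of low-weight
#' background fragments on both strands models pervasive antisense and
#' intergenic transcription, so the combined-strand expected coverage
#' support is the whole genome. Randomness enters only at read sampling;
#' `seed` is accepted for interface stability but unused.
#'
#' @param genome a [plastome()].
#' @param model an operon model (see [build_genome()]).
#' @param seed unused (deterministic expectation).
#' @param bg_tile background tile width in bp.
#' @return data.frame pool: `start`, `end`, `strand`, `weight`, `kind`,
#'   `unit_id`.
#' @export
simulate_transcripts <- function(genome, model, seed = NULL, bg_tile = 400L) {
  ops <- model$operons
  if (all(ops$rate == 0) && model$antisense_rate == 0) stopf("all transcription rates are zero")
  p <- model$readthrough_prob
  L <- genome$length
  rows <- list()
  ord <- order(ops$start)
  ops <- ops[ord, , drop = FALSE]
  nu <- nrow(ops)
  for (i in seq_len(nu)) {
    s <- ops$strand[i]
    # Downstream units in transcription direction, without wrapping.
    down <- if (s == "+") which(ops$start > ops$start[i]) else rev(which(ops$start < ops$start[i]))
    M <- length(down)
    for (m in 0:M) {
      w <- if (m < M || p < 1) ops$rate[i] * p^m * (1 - p) else ops$rate[i]
      if (m == M && p < 1) w <- ops$rate[i] * p^M # absorb tail at the cap
      if (w <= 0) next
      if (m == 0L) {
        a <- ops$start[i]; b <- ops$end[i]
      } else if (s == "+") {
        a <- ops$start[i]; b <- ops$end[down[m]]
      } else {
        a <- ops$start[down[m]]; b <- ops$end[i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = a, end = b, strand = s, weight = w,
        kind = if (m == 0L) "operon" else "readthrough",
        unit_id = ops$operon_id[i], stringsAsFactors = FALSE
      )
    }
  }
  # Pervasive background: tiles covering every base on both strands.
  if (model$antisense_rate > 0) {
    w_bg <- model$antisense_rate * mean(ops$rate)
    starts <- unique(c(seq(0L, max(L - bg_tile, 0L), by = bg_tile), max(L - bg_tile, 0L)))
    for (s in c("+", "-")) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = starts, end = pmin(starts + bg_tile, L), strand = s,
        weight = w_bg, kind = "background", unit_id = "bg",
        stringsAsFactors = FALSE
      )
    }
  }
  pool <- do.call(rbind, rows)
  rownames(pool) <- NULL
  pool
}

#' Register C-to-U edit sites for injection into simulated reads
#'
#' Validates that each site's reference base on its transcript strand is a
#' C (a plus-strand C for '+' sites, a plus-strand G for '-' sites) and
#' attaches the site list to the pool; [simulate_reads()] then flips the
#' base independently in each covering transcript fragment with
#' probability equal to the site's efficiency.
#'
#' @param pool transcript pool from [simulate_transcripts()].
#' @param genome a [plastome()].
#' @param sites data.frame with `position` (0-based), `strand`,
#'   `efficiency`.
#' @return the pool with the validated site list attached.
#' @export
inject_edits <- function(pool, genome, sites) {
  stopifnot(all(c("position", "strand", "efficiency") %in% names(sites)))
  if (any(sites$efficiency < 0 | sites$efficiency > 1)) stopf("efficiency outside [0,1]")
  ref <- substring(genome$sequence, sites$position + 1L, sites$position + 1L)
  want <- ifelse(sites$strand == "+", "C", "G")
  bad <- ref != want
  if (any(bad)) {
    stopf("edit site at %d on '%s' is not a C on its transcript strand (plus-strand base '%s')",
          sites$position[bad][1L], sites$strand[bad][1L], ref[bad][1L])
  }
  attr(pool, "edits") <- sites
  pool
}

#' Simulate strand-specific paired alignments from a transcript pool
#'
#' Fragments of constant length are drawn from pool intervals with
#' probability proportional to weight times the number of fragment start
#' positions; injected edits are applied per fragment at their target
#' efficiency, then per-base errors at rate epsilon. Each fragment yields a
#' proper dUTP pair: under fr-firststrand the first read aligns antisense
#' to the transcript, so [read_sam()] recovers each fragment's true
#' transcript strand. Alignments are emitted directly (no aligner).
#'
#' @param pool transcript pool, optionally with edits attached by
#'   [inject_edits()].
#' @param genome a [plastome()].
#' @param config a [sim_config()] (`n_read_pairs`, `read_length`,
#'   `fragment_length`, `base_error_rate`).
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `records` (alignment-record data.frame, two rows per
#'   pair, same schema as [read_sam()] output) and `fragments`
#'   (data.frame `start`, `end`, `strand` of each fragment).
#' @export
simulate_reads <- function(pool, genome, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_read_pairs
  if (n <= 0L) stopf("n_read_pairs must be positive")
  Fr <- config$fragment_length
  Lr <- config$read_length
  elig <- pool[pool$end - pool$start >= Fr, , drop = FALSE]
  if (!nrow(elig)) stopf("no pool interval is at least fragment_length (%d bp) long", Fr)
  S <- elig$end - elig$start - Fr + 1L
  with_seed(seed, {
    idx <- sample.int(nrow(elig), n, replace = TRUE, prob = elig$weight * S)
    fs <- elig$start[idx] + floor(stats::runif(n) * S[idx])
    fe <- fs + Fr
    strand <- elig$strand[idx]
    frag <- substring(genome$sequence, fs + 1L, fe)
    edits <- attr(pool, "edits")
    if (!is.null(edits) && nrow(edits)) {
      for (e in seq_len(nrow(edits))) {
        covering <- which(strand == edits$strand[e] &
                            fs <= edits$position[e] & edits$position[e] < fe)
        if (!length(covering)) next
        hit <- covering[stats::runif(length(covering)) < edits$efficiency[e]]
        if (!length(hit)) next
        rel <- edits$position[e] - fs[hit] + 1L
        substring(frag[hit], rel, rel) <- if (edits$strand[e] == "+") "T" else "A"
      }
    }
    # Plus-strand projected read sequences at both fragment ends.
    seq_left <- substr(frag, 1L, Lr)
    seq_right <- substr(frag, Fr - Lr + 1L, Fr)
    # Sequencing errors, uniform over all read bases.
    seqs <- c(seq_left, seq_right)
    n_err <- stats::rbinom(1L, 2L * n * Lr, config$base_error_rate)
    if (n_err > 0L) {
      at <- sample.int(2L * n * Lr, n_err)
      ri <- (at - 1L) %/% Lr + 1L
      off <- (at - 1L) %% Lr + 1L
      for (k in seq_len(n_err)) {
        cur <- substring(seqs[ri[k]], off[k], off[k])
        substring(seqs[ri[k]], off[k], off[k]) <- sample(setdiff(BASES, cur), 1L)
      }
    }
    seq_left <- seqs[seq_len(n)]
    seq_right <- seqs[n + seq_len(n)]
    plus <- strand == "+"
    # fr-firststrand: R1 antisense to the transcript.
    # '+' fragment: R1 reverse at the right end (flag 83), R2 forward at the
    # left end (163). '-' fragment: R1 forward left (99), R2 reverse right (147).
    r1_pos <- ifelse(plus, fe - Lr, fs)
    r2_pos <- ifelse(plus, fs, fe - Lr)
    r1_seq <- ifelse(plus, seq_right, seq_left)
    r2_seq <- ifelse(plus, seq_left, seq_right)
    ids <- sprintf("pair%07d", seq_len(n))
    cg <- paste0(Lr, "M")
    rec <- data.frame(
      read_id = c(ids, ids),
      flag = c(ifelse(plus, 83L, 99L), ifelse(plus, 163L, 147L)),
      ref_id = genome$id,
      pos = c(r1_pos, r2_pos),
      mapq = 60L,
      cigar = cg,
      seq = c(r1_seq, r2_seq),
      is_first = rep(c(TRUE, FALSE), each = n),
      is_reverse = c(plus, !plus),
      ref_width = Lr,
      transcript_strand = c(strand, strand),
      rnext = "=",
      pnext = c(r2_pos, r1_pos),
      tlen = c(ifelse(plus, -Fr, Fr), ifelse(plus, Fr, -Fr)),
      stringsAsFactors = FALSE
    )
    list(records = rec, fragments = data.frame(start = fs, end = fe, strand = strand,
                                               stringsAsFactors = FALSE))
  })
}

# ---- Ground-truth manifest quantities (exact expectations from the pool) ----

#' Expected per-gene sense/antisense read counts under the 50%-overlap rule
#'
#' For each eligible pool interval, fragment starts are uniform; the number
#' of start positions whose left or right read overlaps a CDS by at least
#' half the read length is counted exactly and weighted by the interval's
#' sampling probability.
#'
#' @param pool transcript pool.
#' @param features CDS features (or a [plastome()]).
#' @param config a [sim_config()].
#' @param n_pairs number of read pairs (defaults to the config value).
#' @return data.frame `gene_id`, `expected_sense`, `expected_antisense`.
#' @export
expected_gene_counts <- function(pool, features, config, n_pairs = config$n_read_pairs) {
  if (inherits(features, "plastome")) features <- features$features
  Fr <- config$fragment_length; Lr <- config$read_length
  h <- ceiling(Lr / 2)
  elig <- pool[pool$end - pool$start >= Fr, , drop = FALSE]
  S <- elig$end - elig$start - Fr + 1L
  p_int <- elig$weight * S / sum(elig$weight * S)
  ng <- nrow(features)
  out <- data.frame(gene_id = features$gene_id,
                    expected_sense = numeric(ng), expected_antisense = numeric(ng))
  count_starts <- function(lo, hi, a, b) pmax(0L, pmin(hi, b) - pmax(lo, a) + 1L)
  for (g in seq_len(ng)) {
    gs <- features$start[g]; ge <- features$end[g]
    # Fragment starts t whose left read [t, t+L) overlaps >= h:
    lo1 <- gs - Lr + h; hi1 <- ge - h
    # ... and whose right read [t+F-L, t+F) overlaps >= h:
    lo2 <- gs - Fr + h; hi2 <- ge - h - Fr + Lr
    for (s in c("+", "-")) {
      rows <- which(elig$strand == s)
      if (!length(rows)) next
      a <- elig$start[rows]; b <- a + S[rows] - 1L
      n1 <- count_starts(lo1, hi1, a, b)
      n2 <- count_starts(lo2, hi2, a, b)
      e <- n_pairs * sum(p_int[rows] * (n1 + n2) / S[rows])
      if (s == features$strand[g]) out$expected_sense[g] <- out$expected_sense[g] + e
      else out$expected_antisense[g] <- out$expected_antisense[g] + e
    }
  }
  out
}

#' Expected per-base coverage from the pool
#'
#' @param pool transcript pool.
#' @param config a [sim_config()].
#' @param genome_length genome length in bp.
#' @param n_pairs number of read pairs.
#' @return list with numeric vectors `plus`, `minus` of expected read
#'   counts per base.
#' @export
pool_expected_coverage <- function(pool, config, genome_length,
                                   n_pairs = config$n_read_pairs) {
  Fr <- config$fragment_length; Lr <- config$read_length
  elig <- pool[pool$end - pool$start >= Fr, , drop = FALSE]
  S <- elig$end - elig$start - Fr + 1L
  p_int <- elig$weight * S / sum(elig$weight * S)
  out <- list(plus = numeric(genome_length), minus = numeric(genome_length))
  for (i in seq_len(nrow(elig))) {
    key <- if (elig$strand[i] == "+") "plus" else "minus"
    scale <- n_pairs * p_int[i] / S[i]
    for (off in c(0L, Fr - Lr)) { # left read, right read
      a <- elig$start[i] + off
      xs <- a:(a + S[i] + Lr - 2L)
      tri <- pmin(xs - a + 1L, a + S[i] + Lr - 1L - xs, Lr, S[i])
      keep <- xs >= 0L & xs < genome_length
      out[[key]][xs[keep] + 1L] <- out[[key]][xs[keep] + 1L] + scale * tri[keep]
    }
  }
  out
}

#' True per-gene sense transcript abundance implied by the pool
#'
#' The overlap-weighted sum of same-strand pool weights over the gene body:
#' the molar abundance of transcript copies covering the gene, the quantity
#' TPM estimates.
#'
#' @param pool transcript pool.
#' @param features CDS features (or a [plastome()]).
#' @return named numeric vector of abundances.
#' @export
gene_abundance <- function(pool, features) {
  if (inherits(features, "plastome")) features <- features$features
  vapply(seq_len(nrow(features)), function(g) {
    same <- pool$strand == features$strand[g]
    ovl <- pmax(0L, pmin(pool$end, features$end[g]) - pmax(pool$start, features$start[g]))
    sum(pool$weight[same] * ovl[same]) / (features$end[g] - features$start[g])
  }, numeric(1)) |> stats::setNames(features$gene_id)
}

#' Simulate one synthetic species end to end
#'
#' Convenience wrapper: build (or derive) the genome, apply `k` inversions,
#' rebuild transcription units, emit the expected transcript pool, inject
#' edits, simulate reads and assemble the ground-truth manifest.
#'
#' @param config a [sim_config()].
#' @param id species/genome id.
#' @param k_inversions inversions applied to the freshly built genome.
#' @param edit_sites optional data.frame (`position`, `strand`,
#'   `efficiency`); positions must be valid C-to-U targets.
#' @param n_edit_sites when `edit_sites` is NULL and this is > 0, draw this
#'   many eligible sites inside gene bodies with efficiencies uniform in
#'   `edit_efficiency_range`.
#' @param edit_efficiency_range range for drawn efficiencies.
#' @return list with `genome`, `model`, `pool`, `records`, `manifest`
#'   (`inversions`, `edits`, `abundance`, `expected_counts`,
#'   `expected_coverage`).
#' @export
simulate_species <- function(config, id = "synth1", k_inversions = 0L,
                             edit_sites = NULL, n_edit_sites = 0L,
                             edit_efficiency_range = c(0.2, 0.9)) {
  built <- build_genome(config, id = id)
  genome <- built$genome
  inv_log <- data.frame(start = integer(), end = integer())
  if (k_inversions > 0L) {
    inv <- apply_inversions(genome, k_inversions, seed = child_seed(config$seed, 1L))
    genome <- inv$genome
    inv_log <- inv$log
  }
  model <- derive_operon_model(genome, built$model)
  pool <- simulate_transcripts(genome, model)
  if (is.null(edit_sites) && n_edit_sites > 0L) {
    edit_sites <- draw_edit_sites(genome, n_edit_sites, edit_efficiency_range,
                                  seed = child_seed(config$seed, 2L))
  }
  if (!is.null(edit_sites) && nrow(edit_sites)) {
    pool <- inject_edits(pool, genome, edit_sites)
  }
  sim <- simulate_reads(pool, genome, config, seed = child_seed(config$seed, 3L))
  manifest <- list(
    inversions = inv_log,
    edits = edit_sites,
    abundance = gene_abundance(pool, genome),
    expected_counts = expected_gene_counts(pool, genome, config),
    expected_coverage = pool_expected_coverage(pool, config, genome$length)
  )
  list(genome = genome, model = model, pool = pool,
       records = sim$records, fragments = sim$fragments, manifest = manifest)
}

#' Draw eligible C-to-U edit sites inside gene bodies
#'
#' Picks positions whose transcript-strand base is C on the gene's coding
#' strand (so injected edits are sense edits), at most one per gene.
#'
#' @param genome a [plastome()].
#' @param n number of sites.
#' @param efficiency_range uniform range for target efficiencies.
#' @param seed RNG seed.
#' @return data.frame `position`, `strand`, `efficiency`, `gene_id`.
#' @export
draw_edit_sites <- function(genome, n, efficiency_range = c(0.2, 0.9), seed = 1L) {
  f <- genome$features
  if (!nrow(f)) stopf("genome has no features")
  with_seed(seed, {
    genes <- sample(seq_len(nrow(f)), min(n, nrow(f)))
    out <- lapply(genes, function(g) {
      want <- if (f$strand[g] == "+") "C" else "G"
      span <- (f$start[g]):(f$end[g] - 1L)
      bases <- substring(genome$sequence, span + 1L, span + 1L)
      cand <- span[bases == want]
      if (!length(cand)) return(NULL)
      data.frame(position = sample(cand, 1L), strand = f$strand[g],
                 efficiency = stats::runif(1L, efficiency_range[1L], efficiency_range[2L]),
                 gene_id = f$gene_id[g], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) stopf("no eligible edit positions found")
    out[order(out$position), , drop = FALSE]
  })
}

#' Simulate a coupled (or null) rearrangement-expression study
#'
#' Generates a chain of species by successive segmental inversions and a
#' per-species ortholog expression table in which, under the coupled
#' scenario, every inversion event perturbs the log-expression of the genes
#' it relocates; under the uncoupled null each species instead receives an
#' independent perturbation of matched magnitude, so expression divergence
#' carries no information about rearrangement counts. Rearrangement counts
#' (PR) are then recomputed from the derived genomes via synteny blocks and
#' DCJ, and TPM tables via Poisson count sampling, so the headline
#' statistics are exercised through the package's own modules.
#'
#' @param n_species number of species in the chain.
#' @param config a [sim_config()] for the ancestral genome.
#' @param k_step inversions per speciation step.
#' @param coupled logical: tie expression perturbations to inversions?
#' @param sigma_base log10 sd of baseline gene expression across genes.
#' @param sigma_event log10 sd of the per-gene perturbation applied by one
#'   inversion event to the genes it relocates (coupled) or by one
#'   speciation step to a random gene subset of the same size (uncoupled).
#' @param sigma_noise log10 sd of per-species measurement noise.
#' @param depth expected total read count per species for Poisson count
#'   sampling.
#' @param seed RNG seed.
#' @return list with `tables` (per-species expression tables), `genomes`
#'   (per-species [plastome()]s), `pr_matrix`, `expr_matrix`,
#'   `dist_matrix`, `pair_table`, `headline`.
#' @export
simulate_coupled_study <- function(n_species = 6L, config = sim_config(n_genes = 40L, n_operons = 12L),
                                   k_step = 2L, coupled = TRUE,
                                   sigma_base = 0.8, sigma_event = 0.6,
                                   sigma_noise = 0.1, depth = 2e5, seed = 1L) {
  stopifnot(n_species >= 3L)
  built <- build_genome(config, id = "sp1")
  genomes <- vector("list", n_species)
  names(genomes) <- paste0("sp", seq_len(n_species))
  genomes[[1L]] <- built$genome
  ng <- config$n_genes
  gene_ids <- built$genome$features$gene_id
  lens <- stats::setNames(built$genome$features$end - built$genome$features$start,
                          gene_ids)
  event_effects <- list() # per speciation step: named per-gene log10 shifts
  tables <- with_seed(seed, {
    for (i in 2L:n_species) {
      prev <- genomes[[i - 1L]]
      inv <- apply_inversions(prev, k_step, seed = sample.int(2^30, 1L))
      genomes[[i]] <- inv$genome
      shift <- stats::setNames(numeric(ng), gene_ids)
      if (coupled) {
        for (r in seq_len(nrow(inv$log))) {
          f <- prev$features
          moved <- f$gene_id[f$start >= inv$log$start[r] & f$end <= inv$log$end[r]]
          shift[moved] <- shift[moved] + stats::rnorm(length(moved), 0, sigma_event)
        }
      }
      event_effects[[i - 1L]] <- shift
    }
    base_log <- stats::rnorm(ng, mean = 1.5, sd = sigma_base)
    names(base_log) <- gene_ids
    # Under the null every species receives one independent, exchangeable
    # perturbation of magnitude matched to a typical speciation step, so
    # expression divergence carries no information about inversion counts.
    null_shift <- lapply(seq_len(n_species), function(i) {
      moved <- sample(gene_ids, max(1L, round(ng / 3)))
      s <- stats::setNames(numeric(ng), gene_ids)
      s[moved] <- stats::rnorm(length(moved), 0, sigma_event)
      s
    })
    lapply(seq_len(n_species), function(i) {
      lg <- base_log
      if (coupled) {
        if (i > 1L) for (j in seq_len(i - 1L)) lg <- lg + event_effects[[j]]
      } else {
        lg <- lg + null_shift[[i]]
      }
      lg <- lg + stats::rnorm(ng, 0, sigma_noise)
      abun <- 10^lg
      lambda <- depth * abun * lens / sum(abun * lens)
      counts <- stats::rpois(ng, lambda)
      data.frame(gene_id = gene_ids, length = unname(lens),
                 sense_count = counts, tpm = tpm(counts, lens),
                 stringsAsFactors = FALSE)
    })
  })
  names(tables) <- names(genomes)
  orders <- lapply(genomes, gene_order)
  blocks <- find_synteny_blocks(orders)
  pr <- pairwise_matrix(blocks$genomes, method = "dcj")
  expr <- expression_correlation_matrix(tables)
  # Clock-like genetic distances along the chain, unrelated to inversions.
  idx <- seq_len(n_species)
  dist_m <- outer(idx, idx, function(a, b) abs(a - b) * 0.01)
  dimnames(dist_m) <- list(names(genomes), names(genomes))
  pair_table <- build_pair_table(expr, pr, dist_m)
  list(tables = tables, genomes = genomes, pr_matrix = pr, expr_matrix = expr,
       dist_matrix = dist_m, pair_table = pair_table,
       headline = headline_analysis(pair_table))
}
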