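# Gene-order rearrangement distances on circular signed permutations.
#
# A genome is a circular ordered list of signed blocks. Each block b has two
# extremities, its tail "b.t" and head "b.h"; a block traversed forward
# (+b) exposes tail then head, reversed (-b) head then tail. The circular
# order induces a perfect matching on extremities (the adjacency set), which
# is the representation both distances work on, making every distance
# rotation- and reflection-invariant by construction.

# Oriented adjacency set of a circular signed permutation.
# perm: integer vector of signed block ids (each id appears once in |perm|).
# Returns character vector of canonical "e1|e2" keys (sorted within pair).
block_adjacencies <- function(perm) {
  n <- length(perm)
  if (n == 0L) return(character())
  b <- abs(perm)
  left <- ifelse(perm > 0L, paste0(b, ".t"), paste0(b, ".h"))
  right <- ifelse(perm > 0L, paste0(b, ".h"), paste0(b, ".t"))
  nxt <- c(2:n, 1L)[seq_len(n)]
  e1 <- right
  e2 <- left[nxt]
  apply(cbind(e1, e2), 1L, function(x) paste(sort(x), collapse = "|"))
}

check_block_sets <- function(gA, gB) {
  if (length(gA) != length(gB) || !setequal(abs(gA), abs(gB))) {
    stopf("genomes are over different block sets")
  }
  if (anyDuplicated(abs(gA)) || anyDuplicated(abs(gB))) {
    stopf("each block must appear exactly once")
  }
}

#' Breakpoint distance between circular signed gene orders
#'
#' Counts the oriented adjacencies of genome A that are absent from genome
#' B. A single segmental inversion breaks two adjacencies, so one inversion
#' gives distance 2 under this metric.
#'
#' @param gA,gB circular signed permutations over the same block set
#'   (integer vectors of signed block ids).
#' @return non-negative integer.
#' @export
breakpoint_distance <- function(gA, gB) {
  check_block_sets(gA, gB)
  adjA <- block_adjacencies(gA)
  adjB <- block_adjacencies(gB)
  sum(!adjA %in% adjB)
}

#' DCJ distance between circular signed gene orders
#'
#' Minimal number of double-cut-and-join operations transforming one
#' unichromosomal circular genome into the other. For this case the closed
#' form is N - C, where N is the number of blocks and C the number of
#' cycles in the adjacency graph of the two genomes.
#'
#' @inheritParams breakpoint_distance
#' @return non-negative integer.
#' @export
dcj_distance <- function(gA, gB) {
  check_block_sets(gA, gB)
  n <- length(gA)
  if (n == 0L) return(0L)
  adjA <- adjacency_pairs(gA)
  adjB <- adjacency_pairs(gB)
  # Walk cycles alternating A-edges and B-edges over the 2n extremities.
  nextA <- c(adjA[, 2L], adjA[, 1L]); names(nextA) <- c(adjA[, 1L], adjA[, 2L])
  nextB <- c(adjB[, 2L], adjB[, 1L]); names(nextB) <- c(adjB[, 1L], adjB[, 2L])
  seen <- structure(logical(2L * n), names = names(nextA))
  cycles <- 0L
  for (start in names(nextA)) {
    if (seen[start]) next
    cycles <- cycles + 1L
    v <- start
    repeat {
      seen[v] <- TRUE
      w <- nextA[[v]]
      seen[w] <- TRUE
      v <- nextB[[w]]
      if (v == start) break
    }
  }
  n - cycles
}

# Adjacencies as a 2-column character matrix of extremity labels.
adjacency_pairs <- function(perm) {
  n <- length(perm)
  b <- abs(perm)
  left <- ifelse(perm > 0L, paste0(b, ".t"), paste0(b, ".h"))
  right <- ifelse(perm > 0L, paste0(b, ".h"), paste0(b, ".t"))
  nxt <- c(2:n, 1L)[seq_len(n)]
  cbind(right, left[nxt])
}

#' Canonicalize a circular signed permutation
#'
#' Rotates the permutation so the anchor block comes first with positive
#' sign; if the anchor is negative the whole circle is reflected (reversed
#' with all signs flipped), which denotes the same circular molecule.
#'
#' @param perm signed integer vector.
#' @param anchor block id to place first (default: smallest id).
#' @return canonical signed integer vector.
#' @export
canonicalize_perm <- function(perm, anchor = min(abs(perm))) {
  i <- which(abs(perm) == anchor)
  if (!length(i)) stopf("anchor block %d not present", anchor)
  if (perm[i] < 0L) perm <- -rev(perm)
  i <- which(abs(perm) == anchor)
  if (i > 1L) perm <- c(perm[i:length(perm)], perm[seq_len(i - 1L)])
  perm
}

#' Identify syntenic blocks across species' gene orders
#'
#' Restricted to genes present exactly once in every species, a syntenic
#' block is a maximal run of genes whose order and relative orientation are
#' conserved in all species (an oriented gene adjacency conserved
#' everywhere never separates two blocks). Every shared gene belongs to
#' exactly one block; each species' block order is returned as a circular
#' signed permutation, the input to the distance functions.
#'
#' @param orders named list of signed circular gene orders (named integer
#'   vectors of +1/-1, as from [gene_order()]).
#' @return list with `blocks` (list of gene-id vectors in block orientation,
#'   named "B1".."Bn"), `genomes` (named list of signed block permutations),
#'   and `n_blocks`.
#' @export
find_synteny_blocks <- function(orders) {
  stopifnot(is.list(orders), length(orders) >= 2L)
  if (is.null(names(orders))) names(orders) <- paste0("sp", seq_along(orders))
  counts <- table(unlist(lapply(orders, names)))
  shared <- names(counts)[counts == length(orders)]
  single <- shared[vapply(shared, function(g) {
    all(vapply(orders, function(o) sum(names(o) == g) == 1L, logical(1)))
  }, logical(1))]
  if (length(single) < 2L) stopf("fewer than 2 single-copy genes shared by all species")
  sub <- lapply(orders, function(o) o[names(o) %in% single])

  # Oriented gene adjacencies conserved in every species.
  gid <- seq_along(single); names(gid) <- single
  adj_sets <- lapply(sub, function(o) {
    perm <- unname(gid[names(o)]) * as.integer(o)
    block_adjacencies(perm)
  })
  conserved <- Reduce(intersect, adj_sets)

  # Cut the first species' circle at every non-conserved adjacency.
  ref <- sub[[1L]]
  n <- length(ref)
  ref_perm <- unname(gid[names(ref)]) * as.integer(ref)
  ref_adj <- block_adjacencies(ref_perm) # adjacency i joins position i and i+1 (mod n)
  is_break <- !ref_adj %in% conserved
  if (!any(is_break)) {
    # Fully conserved circle: one block containing everything.
    blocks <- list(B1 = names(ref))
    genomes <- lapply(orders, function(o) 1L)
    return(list(blocks = blocks, genomes = genomes, n_blocks = 1L))
  }
  # Rotate so position 1 starts a new block.
  first_break <- which(is_break)[1L] # break after position first_break
  rot <- c(seq_len(n)[-seq_len(first_break)], seq_len(first_break))
  ref_rot <- ref[rot]
  breaks_rot <- is_break[c(seq_len(n)[-seq_len(first_break)], seq_len(first_break))]
  block_id <- cumsum(c(TRUE, breaks_rot[-n]))
  blocks <- split(names(ref_rot), block_id)
  block_strand_ref <- split(as.integer(ref_rot), block_id)
  # Store blocks oriented as in the reference species.
  names(blocks) <- paste0("B", seq_along(blocks))
  n_blocks <- length(blocks)

  # Gene -> (block, index within block, reference sign of gene).
  gene_block <- integer(0); gene_idx <- integer(0); gene_sign <- integer(0)
  for (bi in seq_len(n_blocks)) {
    gs <- blocks[[bi]]
    gene_block[gs] <- bi
    gene_idx[gs] <- seq_along(gs)
    gene_sign[gs] <- block_strand_ref[[bi]]
  }

  genomes <- lapply(sub, function(o) {
    genes <- names(o)
    bl <- gene_block[genes]
    m <- length(genes)
    # Rotate this species so position 1 is the first gene of some block
    # occurrence (block boundary at the seam).
    sizes <- lengths(blocks)
    starts_fwd <- gene_idx[genes] == 1L & as.integer(o) == gene_sign[genes]
    starts_rev <- gene_idx[genes] == sizes[bl] & as.integer(o) == -gene_sign[genes]
    start_pos <- which(starts_fwd | starts_rev)[1L]
    if (is.na(start_pos)) stopf("internal error: no block start found in species order")
    rot <- c(start_pos:m, if (start_pos > 1L) 1:(start_pos - 1L))
    o2 <- o[rot]
    genes2 <- names(o2)
    bl2 <- gene_block[genes2]
    run <- cumsum(c(TRUE, bl2[-m] != bl2[-1L]))
    perm <- integer(0)
    for (r in unique(run)) {
      idx <- which(run == r)
      b <- bl2[idx[1L]]
      if (length(idx) != sizes[b]) {
        stopf("internal error: block B%d split in a species (non-conserved adjacency missed)", b)
      }
      g1 <- genes2[idx[1L]]
      fwd <- gene_idx[g1] == 1L && as.integer(o2[idx[1L]]) == gene_sign[g1]
      perm <- c(perm, if (fwd) b else -b)
    }
    perm
  })
  names(genomes) <- names(orders)
  list(blocks = blocks, genomes = genomes, n_blocks = n_blocks)
}

#' Pairwise rearrangement-distance matrix
#'
#' @param genomes named list of circular signed block permutations over a
#'   common block set (e.g. `find_synteny_blocks(...)$genomes`).
#' @param method "dcj" (default) or "breakpoint".
#' @return symmetric integer matrix with zero diagonal.
#' @export
pairwise_matrix <- function(genomes, method = c("dcj", "breakpoint")) {
  method <- match.arg(method)
  stopifnot(is.list(genomes), length(genomes) >= 2L)
  if (is.null(names(genomes))) names(genomes) <- paste0("sp", seq_along(genomes))
  fun <- if (method == "dcj") dcj_distance else breakpoint_distance
  s <- names(genomes)
  m <- matrix(0L, length(s), length(s), dimnames = list(s, s))
  for (i in seq_along(s)) for (j in seq_len(i - 1L)) {
    d <- fun(genomes[[i]], genomes[[j]])
    m[i, j] <- d
    m[j, i] <- d
  }
  m
}
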