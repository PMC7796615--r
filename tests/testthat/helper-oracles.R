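# Independent oracles and small fixture builders used across the suite.

# ---- rearrangement oracles ---------------------------------------------

# Extremity adjacency keys of a circular signed permutation (definitional).
oracle_adjacencies <- function(perm) {
  n <- length(perm)
  b <- abs(perm)
  left <- ifelse(perm > 0, paste0(b, ".t"), paste0(b, ".h"))
  right <- ifelse(perm > 0, paste0(b, ".h"), paste0(b, ".t"))
  vapply(seq_len(n), function(i) {
    paste(sort(c(right[i], left[if (i == n) 1L else i + 1L])), collapse = "|")
  }, character(1))
}

# Breakpoint distance by direct enumeration of ordered signed neighbour
# pairs: adjacency (a, b) of A is conserved in B iff B contains (a, b) or
# the reflected (-b, -a) as consecutive elements (circularly).
oracle_breakpoint <- function(gA, gB) {
  n <- length(gA)
  pairsB <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pairsB <- rbind(pairsB, c(gB[i], gB[j]), c(-gB[j], -gB[i]))
  }
  miss <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    hit <- any(pairsB[, 1L] == gA[i] & pairsB[, 2L] == gA[j])
    if (!hit) miss <- miss + 1L
  }
  miss
}

# Breadth-first search over perfect matchings of extremities: one DCJ step
# replaces adjacencies {p,q},{r,s} by {p,r},{q,s} or {p,s},{q,r}. Returns
# an environment mapping matching-state keys to their minimal DCJ distance
# from `start_perm`'s adjacency set.
oracle_dcj_bfs_map <- function(start_perm, max_depth = 10L) {
  state_key <- function(adjs) paste(sort(adjs), collapse = ";")
  adj_key <- function(e1, e2) paste(sort(c(e1, e2)), collapse = "|")
  start <- oracle_adjacencies(start_perm)
  dist <- new.env(parent = emptyenv())
  assign(state_key(start), 0L, dist)
  frontier <- list(start)
  d <- 0L
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    nxt <- list()
    for (s in frontier) {
      ns <- length(s)
      parts <- strsplit(s, "|", fixed = TRUE)
      for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
        p <- parts[[i]]; q <- parts[[j]]
        for (v in 1:2) {
          new_i <- if (v == 1L) adj_key(p[1L], q[1L]) else adj_key(p[1L], q[2L])
          new_j <- if (v == 1L) adj_key(p[2L], q[2L]) else adj_key(p[2L], q[1L])
          s2 <- s
          s2[i] <- new_i
          s2[j] <- new_j
          k <- state_key(s2)
          if (!exists(k, envir = dist, inherits = FALSE)) {
            assign(k, d, dist)
            nxt[[length(nxt) + 1L]] <- s2
          }
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_dcj_lookup <- function(dist_map, perm) {
  k <- paste(sort(oracle_adjacencies(perm)), collapse = ";")
  if (!exists(k, envir = dist_map, inherits = FALSE)) stop("state not reached in BFS")
  get(k, envir = dist_map)
}

# All circular signed permutations of n blocks in canonical form
# (block 1 fixed as +1, so each circular molecule appears once per
# reflection class representative choice).
all_signed_circular_perms <- function(n) {
  if (n == 1L) return(list(1L))
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  rest <- perms_of(2:n)
  out <- list()
  for (p in rest) {
    for (mask in 0:(2^(n - 1L) - 1L)) {
      signs <- ifelse(bitwAnd(mask, 2^(seq_len(n - 1L) - 1L)) > 0L, -1L, 1L)
      out[[length(out) + 1L]] <- c(1L, p * signs)
    }
  }
  out
}

random_signed_perm <- function(n) {
  c(1L, sample(2:n) * sample(c(-1L, 1L), n - 1L, replace = TRUE))
}

# ---- statistics oracles -------------------------------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# ---- alignment oracle ---------------------------------------------------

# Global affine-gap alignment score by direct dynamic programming, with the
# same convention as Biostrings::pairwiseAlignment: a gap of length k
# costs gapOpening + k * gapExtension.
oracle_nw_affine <- function(a, b, submat, go = 10, ge = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (a[i] unmatched)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a
  M[1L, 1L] <- 0
  for (i in 1:n + 1L) X[i, 1L] <- -(go + (i - 1L) * ge)
  for (j in 1:m + 1L) Y[1L, j] <- -(go + (j - 1L) * ge)
  for (i in 1:n + 1L) for (j in 1:m + 1L) {
    s <- submat[a[i - 1L], b[j - 1L]]
    M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + s
    X[i, j] <- max(X[i, j], M[i - 1L, j] - go - ge, X[i - 1L, j] - ge)
    Y[i, j] <- max(Y[i, j], M[i, j - 1L] - go - ge, Y[i, j - 1L] - ge)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# ---- fixture builders ---------------------------------------------------

# A tiny hand-laid plastome: two genes on '+', one on '-'.
toy_plastome <- function() {
  # gA '+' [10, 22): ATG ACC TCA AAA (ACC 3rd-pos C at 15, TCA 2nd-pos C at 17)
  # gB '-' [30, 39): plus "TTAATGCAT", transcript ATG CAT TAA
  #                  (transcript C at cds pos 3 <=> plus-strand G at 35)
  # gC '+' [50, 62): ATG GGA TGC TGA
  s <- paste(rep("A", 100), collapse = "")
  substr(s, 11, 22) <- "ATGACCTCAAAA"
  substr(s, 31, 39) <- "TTAATGCAT"
  substr(s, 51, 62) <- "ATGGGATGCTGA"
  feats <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    start = c(10L, 30L, 50L), end = c(22L, 39L, 62L),
    strand = c("+", "-", "+"), phase = 0L, wraps_origin = FALSE,
    operon_id = c("op1", "op1", "op2"), stringsAsFactors = FALSE
  )
  plastome("toy", s, feats)
}

# Minimal alignment-record data.frame for hand-built reads.
toy_records <- function(pos, strand, len = 100L, seq = NULL, L = NULL) {
  n <- length(pos)
  if (length(len) == 1L) len <- rep(len, n)
  if (is.null(seq)) seq <- vapply(len, function(l) paste(rep("A", l), collapse = ""), "")
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)), flag = rep(0L, n),
    ref_id = rep("toy", n), pos = as.integer(pos), mapq = rep(60L, n),
    cigar = if (n) paste0(len, "M") else character(0),
    seq = seq, is_first = rep(TRUE, n),
    is_reverse = rep(FALSE, n), ref_width = as.integer(len),
    transcript_strand = strand, stringsAsFactors = FALSE
  )
}

# Small stranded pileup with a single candidate position set by hand.
toy_pileup_site <- function(L, pos, strand, ref_count, alt_count, genome) {
  empty <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  pu <- list(plus = empty, minus = empty)
  key <- if (strand == "+") "plus" else "minus"
  if (strand == "+") {
    pu[[key]][pos + 1L, "C"] <- ref_count
    pu[[key]][pos + 1L, "T"] <- alt_count
  } else {
    pu[[key]][pos + 1L, "G"] <- ref_count
    pu[[key]][pos + 1L, "A"] <- alt_count
  }
  pu
}

# Memoized mid-size simulated species shared by several test files.
.shared_sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.shared_sim_cache$sim)) {
    cfg <- sim_config(n_genes = 12, n_operons = 4, n_read_pairs = 20000, seed = 42)
    .shared_sim_cache$sim <- simulate_species(cfg, k_inversions = 2, n_edit_sites = 4)
    .shared_sim_cache$cfg <- cfg
  }
  list(sim = .shared_sim_cache$sim, cfg = .shared_sim_cache$cfg)
}
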