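# Association statistics: Pearson correlation with t-based p-values,
# patristic distances, the per-species-pair table, and the headline
# rearrangement-vs-expression analysis. A Mantel permutation test is
# provided as a robustness companion for the pairwise-matrix correlations.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("undefined correlation: zero variance")
  }
  stats::cor(x, y, method = "pearson")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transformation: t = r * sqrt(n - 2) / sqrt(1 - r^2),
#' with n - 2 degrees of freedom.
#'
#' @param r correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value; for |r| = 1 returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(is.numeric(r), length(r) == 1L, n >= 3L)
  if (abs(r) > 1 + 1e-12) stopf("|r| > 1")
  if (abs(r) >= 1) {
    p <- 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Pearson correlation with its two-sided test
#'
#' @inheritParams pearson
#' @return list with `r`, `n`, `p`.
#' @export
cor_test <- function(x, y) {
  r <- pearson(x, y)
  list(r = r, n = length(x), p = pearson_pvalue(r, length(x)))
}

#' Patristic distance matrix from a phylogenetic tree
#'
#' The distance between two species is the sum of branch lengths
#' (substitutions/site) along the unique tip-to-tip path.
#'
#' @param tree an ape "phylo" object with branch lengths.
#' @param species optional character vector; all must be tips of the tree,
#'   and the returned matrix is restricted to them (in this order).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(d))
    if (length(miss)) stopf("species missing from tree: %s", paste(miss, collapse = ", "))
    d <- d[species, species, drop = FALSE]
  }
  d
}

#' Assemble the per-species-pair table
#'
#' One row per unordered species pair carrying the three pairwise
#' statistics of the study: ortholog expression correlation, rearrangement
#' count (PR) and genetic (patristic) distance.
#'
#' @param expr_corrs symmetric matrix of pairwise expression correlations.
#' @param rearr_matrix symmetric matrix of rearrangement counts.
#' @param dist_matrix symmetric matrix of genetic distances.
#' @return data.frame with columns `species_a`, `species_b`, `r_expr`,
#'   `pr`, `distance`; S*(S-1)/2 rows for S species.
#' @export
build_pair_table <- function(expr_corrs, rearr_matrix, dist_matrix) {
  sp <- rownames(expr_corrs)
  if (is.null(sp)) stopf("matrices must carry species names")
  for (m in list(rearr_matrix, dist_matrix)) {
    if (!identical(sort(rownames(m)), sort(sp))) stopf("species sets differ between matrices")
  }
  rearr_matrix <- rearr_matrix[sp, sp]
  dist_matrix <- dist_matrix[sp, sp]
  idx <- which(lower.tri(expr_corrs), arr.ind = TRUE)
  data.frame(
    species_a = sp[idx[, 2L]],
    species_b = sp[idx[, 1L]],
    r_expr = expr_corrs[idx],
    pr = rearr_matrix[idx],
    distance = dist_matrix[idx],
    stringsAsFactors = FALSE
  )
}

#' Headline association analysis
#'
#' The study's two summary tests over the pair table: Pearson correlation
#' of rearrangement count (PR) with genetic distance, and of PR with the
#' ortholog expression correlation. Note the S*(S-1)/2 pairwise values are
#' not independent; the plain Pearson test is reported as in the study, and
#' [mantel_test()] offers a permutation alternative.
#'
#' @param pair_table data.frame from [build_pair_table()].
#' @return list with elements `pr_vs_distance` and `pr_vs_expression`, each
#'   a list `(r, n, p)`.
#' @export
headline_analysis <- function(pair_table) {
  stopifnot(all(c("r_expr", "pr", "distance") %in% names(pair_table)))
  if (nrow(pair_table) < 3L) stopf("need at least 3 species pairs")
  list(
    pr_vs_distance = cor_test(pair_table$pr, pair_table$distance),
    pr_vs_expression = cor_test(pair_table$pr, pair_table$r_expr)
  )
}

#' Mantel permutation test between two pairwise matrices
#'
#' Pearson correlation of the vectorized off-diagonal entries, with
#' significance from joint row/column label permutations of the second
#' matrix and the add-one estimator p = (1 + #\{|r*| >= |r|\}) / (n_perm + 1).
#'
#' @param matA,matB symmetric matrices over the same species set.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `r`, `p_perm`, `n_perm`.
#' @export
mantel_test <- function(matA, matB, n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 99L)
  if (!isSymmetric(unname(matA)) || !isSymmetric(unname(matB))) {
    stopf("Mantel test requires symmetric matrices")
  }
  sp <- rownames(matA) %||% seq_len(nrow(matA))
  if (!is.null(rownames(matB))) matB <- matB[sp, sp]
  lt <- lower.tri(matA)
  r_obs <- pearson(matA[lt], matB[lt])
  n <- nrow(matA)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      repeat { # identity shuffles carry no information; redraw
        p <- sample.int(n)
        if (any(p != seq_len(n))) break
      }
      rp <- stats::cor(matA[lt], matB[p, p][lt])
      abs(rp) >= abs(r_obs) - 1e-12
    }, logical(1)))
  })
  list(r = r_obs, p_perm = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}
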