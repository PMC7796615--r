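test_that("pearson matches the closed form and flags degenerate input", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  y <- c(1, 3, 2, 5)
  expect_equal(pearson(x, y), oracle_pearson(x, y))
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("the t-based p-value behaves analytically", {
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_equal(pearson_pvalue(0.5, 20), pearson_pvalue(-0.5, 20))
  # strictly decreasing in |r| at fixed n, and in n at fixed r
  rs <- seq(0.05, 0.95, by = 0.1)
  ps <- vapply(rs, pearson_pvalue, numeric(1), n = 12)
  expect_true(all(diff(ps) < 0))
  ns <- c(5, 10, 20, 50, 100)
  pn <- vapply(ns, function(n) pearson_pvalue(0.4, n), numeric(1))
  expect_true(all(diff(pn) < 0))
  p1 <- pearson_pvalue(1, 10)
  expect_equal(as.numeric(p1), 0)
  expect_true(isTRUE(attr(p1, "degenerate")))
})

test_that("patristic distances sum branch lengths along tip paths", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,C:4);")
  d <- patristic_distances(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 8)
  expect_equal(d["B", "C"], 9)
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ds <- patristic_distances(star)
  expect_true(all(ds[upper.tri(ds)] == 2))
  expect_error(patristic_distances(tr, species = c("A", "Z")), "missing")
})

test_that("patristic matrices from random additive trees satisfy the four-point condition", {
  set.seed(11)
  for (i in 1:5) {
    tr <- ape::rtree(8)
    d <- patristic_distances(tr)
    tips <- rownames(d)
    for (j in 1:20) {
      q <- sample(tips, 4)
      sums <- c(d[q[1], q[2]] + d[q[3], q[4]],
                d[q[1], q[3]] + d[q[2], q[4]],
                d[q[1], q[4]] + d[q[2], q[3]])
      top2 <- sort(sums, decreasing = TRUE)[1:2]
      expect_equal(top2[1], top2[2], tolerance = 1e-8)
    }
  }
})

test_that("pair table assembly has one row per unordered pair", {
  sp <- paste0("s", 1:6)
  mk <- function(fill) {
    m <- matrix(fill, 6, 6, dimnames = list(sp, sp)); diag(m) <- 0; m
  }
  r <- mk(0.8); pr <- mk(4); dd <- mk(0.02)
  tab <- build_pair_table(r, pr, dd)
  expect_equal(nrow(tab), 15L)
  expect_true(all(tab$r_expr == 0.8 & tab$pr == 4 & tab$distance == 0.02))
  tab2 <- build_pair_table(r[1:2, 1:2], pr[1:2, 1:2], dd[1:2, 1:2])
  expect_equal(nrow(tab2), 1L)
  # values round-trip from the input matrices
  pr2 <- mk(0); pr2["s1", "s3"] <- pr2["s3", "s1"] <- 9
  tab3 <- build_pair_table(r, pr2, dd)
  expect_equal(tab3$pr[tab3$species_a == "s1" & tab3$species_b == "s3"], 9)
  expect_error(build_pair_table(r[1:3, 1:3], pr, dd), "differ")
})

test_that("headline analysis reports both tests with n = number of pairs", {
  st <- simulate_coupled_study(seed = 5)
  h <- st$headline
  expect_equal(h$pr_vs_expression$n, nrow(st$pair_table))
  expect_equal(h$pr_vs_distance$n, 15L)
  expect_equal(h$pr_vs_expression$r,
               oracle_pearson(st$pair_table$pr, st$pair_table$r_expr))
  expect_equal(h$pr_vs_expression$p,
               pearson_pvalue(h$pr_vs_expression$r, 15))
})

test_that("Mantel permutation p-values match exhaustive enumeration on 4 species", {
  set.seed(21)
  sp <- paste0("s", 1:4)
  mk_sym <- function() {
    m <- matrix(0, 4, 4, dimnames = list(sp, sp))
    v <- runif(6)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    m
  }
  a <- mk_sym(); b <- mk_sym()
  # identity comparison: nothing beats a perfect match
  self <- mantel_test(a, a, n_perm = 199, seed = 2)
  expect_equal(self$p_perm, 1 / 200)
  res <- mantel_test(a, b, n_perm = 999, seed = 3)
  expect_gte(res$p_perm, 1 / 1000)
  expect_lte(res$p_perm, 1)
  # exact hit rate over the 23 non-identity label permutations
  lt <- lower.tri(a)
  perms <- rbind(c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
                 c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
                 c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
                 c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  r_obs <- cor(a[lt], b[lt])
  r_perm <- apply(perms, 1, function(p) cor(a[lt], b[p, p][lt]))
  q_exact <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
  p_exact <- (1 + 999 * q_exact) / 1000
  se <- 999 * sqrt(q_exact * (1 - q_exact) / 999) / 1000
  expect_lte(abs(res$p_perm - p_exact), 3 * se + 2 / 1000)
  expect_error(mantel_test(matrix(1:16, 4, 4), a), "symmetric")
})
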