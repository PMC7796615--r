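test_that("genome building is deterministic and respects the requested structure", {
  cfg <- sim_config(n_genes = 4, n_operons = 2, seed = 3)
  b1 <- build_genome(cfg)
  b2 <- build_genome(cfg)
  expect_identical(b1, b2)
  f <- b1$genome$features
  expect_equal(nrow(f), 4L)
  expect_equal(length(unique(f$operon_id)), 2L)
  expect_equal(as.integer(table(f$operon_id)), c(2L, 2L))
  expect_true(all((f$end - f$start) %% 3L == 0L))
  # features never overlap (exhaustive pairwise check)
  f <- f[order(f$start), ]
  expect_true(all(f$start[-1L] >= f$end[-nrow(f)]))
  # operons are strand-coherent
  expect_true(all(tapply(f$strand, f$operon_id, function(x) length(unique(x))) == 1L))
})

test_that("inversions are involutive, spacer-bounded and produce the stated DCJ distance", {
  cfg <- sim_config(n_genes = 10, n_operons = 4, seed = 5)
  g0 <- build_genome(cfg)$genome
  expect_identical(apply_inversions(g0, 0L)$genome, g0)

  inv <- apply_inversions(g0, 1L, seed = 9)
  expect_equal(nrow(inv$log), 1L)
  sb <- find_synteny_blocks(list(a = gene_order(g0), b = gene_order(inv$genome)))
  d <- dcj_distance(sb$genomes$a, sb$genomes$b)
  expect_equal(d, 1L)
  # exhaustive BFS oracle agrees on this instance
  dm <- oracle_dcj_bfs_map(sb$genomes$a)
  expect_equal(oracle_dcj_lookup(dm, sb$genomes$b), 1L)

  # re-applying the logged inversions restores the original genome
  back <- apply_inversions(inv$genome, log = inv$log)
  expect_identical(back$genome$sequence, g0$sequence)
  expect_equal(back$genome$features[order(back$genome$features$gene_id), ],
               g0$features[order(g0$features$gene_id), ], ignore_attr = TRUE)

  expect_error(apply_inversions(g0, 50L), "spacers")
})

test_that("the transcript pool reflects operons, read-through and background", {
  cfg <- sim_config(n_genes = 6, n_operons = 3, readthrough_prob = 0,
                    antisense_rate = 0, seed = 1)
  built <- build_genome(cfg)
  pool <- simulate_transcripts(built$genome, built$model)
  ops <- built$model$operons
  expect_equal(nrow(pool), nrow(ops))
  expect_setequal(paste(pool$start, pool$end), paste(ops$start, ops$end))

  # pervasive background: combined-strand expected coverage support is the genome
  cfg2 <- sim_config(n_genes = 6, n_operons = 3, antisense_rate = 0.05, seed = 1)
  built2 <- build_genome(cfg2)
  pool2 <- simulate_transcripts(built2$genome, built2$model)
  expcov <- pool_expected_coverage(pool2, cfg2, built2$genome$length, n_pairs = 1)
  expect_true(all(expcov$plus > 0))
  expect_true(all(expcov$minus > 0))

  zero <- built$model
  zero$operons$rate <- 0
  expect_error(simulate_transcripts(built$genome, zero), "zero")
})

test_that("full read-through feeds the downstream operon at least its own rate", {
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  feats <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    start = c(100L, 500L, 1000L, 1400L), end = c(400L, 800L, 1300L, 1700L),
    strand = "+", phase = 0L, wraps_origin = FALSE,
    operon_id = c("op1", "op1", "op2", "op2"), stringsAsFactors = FALSE
  )
  g <- plastome("two_ops", s, feats)
  model <- structure(list(
    operons = data.frame(operon_id = c("op1", "op2"), strand = "+",
                         start = c(100L, 1000L), end = c(800L, 1700L),
                         rate = c(2, 1), stringsAsFactors = FALSE),
    readthrough_prob = 1, antisense_rate = 0), class = "operon_model")
  pool <- simulate_transcripts(g, model)
  ab <- gene_abundance(pool, g)
  # downstream genes see their own rate plus the full read-through of op1
  expect_gte(ab[["g3"]], 3 - 1e-9)
  expect_gte(ab[["g1"]], 2 - 1e-9)
})

test_that("edit injection validates targets and hits its efficiency", {
  ss <- shared_sim()
  g <- ss$sim$genome
  # a non-C target errors
  pos_a <- regexpr("A", g$sequence)[[1]] - 1L
  expect_error(
    inject_edits(ss$sim$pool, g,
                 data.frame(position = pos_a, strand = "+", efficiency = 0.5)),
    "not a C"
  )
  # efficiency 1 and 0 at error rate 0: all or none of the covering reads edited
  cfg <- sim_config(n_genes = 6, n_operons = 2, n_read_pairs = 8000,
                    base_error_rate = 0, antisense_rate = 0.05, seed = 8)
  built <- build_genome(cfg)
  gen <- built$genome
  model <- derive_operon_model(gen, built$model)
  pool <- simulate_transcripts(gen, model)
  # use the most abundantly transcribed gene so the site is well covered
  ab <- gene_abundance(pool, gen)
  f1 <- gen$features[gen$features$gene_id == names(which.max(ab)), ]
  st <- f1$strand
  ref_base <- if (st == "+") "C" else "G"   # C on the transcript strand
  alt_base <- if (st == "+") "T" else "A"
  mat <- if (st == "+") "plus" else "minus"
  span <- f1$start:(f1$end - 1L)
  cpos <- span[substring(gen$sequence, span + 1L, span + 1L) == ref_base][1:2]
  sites <- data.frame(position = cpos, strand = st, efficiency = c(1, 0))
  rec <- simulate_reads(inject_edits(pool, gen, sites), gen, cfg)$records
  pu <- build_pileup(rec, gen)
  expect_equal(unname(pu[[mat]][cpos[1L] + 1L, ref_base]), 0L)   # fully edited
  expect_gt(pu[[mat]][cpos[1L] + 1L, alt_base], 0L)
  expect_equal(unname(pu[[mat]][cpos[2L] + 1L, alt_base]), 0L)   # never edited
  # efficiency 0.4 lands inside the central 99% binomial band
  sites2 <- data.frame(position = cpos[1L], strand = st, efficiency = 0.4)
  rec2 <- simulate_reads(inject_edits(pool, gen, sites2), gen, cfg)$records
  pu2 <- build_pileup(rec2, gen)
  edited <- pu2[[mat]][cpos[1L] + 1L, alt_base]
  n <- edited + pu2[[mat]][cpos[1L] + 1L, ref_base]
  expect_gte(n, 100)
  expect_gte(edited, qbinom(0.005, n, 0.4))
  expect_lte(edited, qbinom(0.995, n, 0.4))
})

test_that("simulated reads are exact at zero error rate and strand-true", {
  cfg <- sim_config(n_genes = 6, n_operons = 2, n_read_pairs = 500,
                    base_error_rate = 0, seed = 4)
  built <- build_genome(cfg)
  model <- derive_operon_model(built$genome, built$model)
  pool <- simulate_transcripts(built$genome, model)
  sim <- simulate_reads(pool, built$genome, cfg)
  rec <- sim$records
  expect_equal(nrow(rec), 2L * cfg$n_read_pairs)
  ref <- substring(built$genome$sequence, rec$pos + 1L, rec$pos + cfg$read_length)
  expect_identical(rec$seq, ref)
  # determinism
  sim2 <- simulate_reads(pool, built$genome, cfg)
  expect_identical(sim$records, sim2$records)
})

test_that("per-gene read counts match the manifest expectation within 3 SE", {
  cfg <- sim_config(n_genes = 12, n_operons = 4, n_read_pairs = 100000, seed = 21)
  sp <- simulate_species(cfg)
  obs <- count_cds_reads(sp$records, sp$genome)
  exp_counts <- sp$manifest$expected_counts
  # per-pair contributions are bounded by 2 reads, so Var <= 2 * E
  tol <- 3 * sqrt(2 * pmax(exp_counts$expected_sense, 1))
  expect_true(all(abs(obs$sense_count - exp_counts$expected_sense) <= tol))
  tol_a <- 3 * sqrt(2 * pmax(exp_counts$expected_antisense, 1))
  expect_true(all(abs(obs$antisense_count - exp_counts$expected_antisense) <= tol_a))
})
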