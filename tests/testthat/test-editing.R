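test_that("pileup projects read bases per transcript strand", {
  g <- toy_plastome()
  rec <- toy_records(10L, "+", len = 12L, seq = "ATGACCTCAAAA")
  pu <- build_pileup(rec, g)
  expect_equal(unname(pu$plus[11L, "A"]), 1L)   # position 10 holds 'A' (ATG...)
  expect_equal(unname(pu$plus[16L, "C"]), 1L)   # position 15: 3rd-pos C of ACC
  expect_equal(sum(pu$minus), 0L)
  # mates/overlapping reads are counted independently
  rec2 <- rbind(rec, rec)
  pu2 <- build_pileup(rec2, g)
  expect_equal(unname(pu2$plus[16L, "C"]), 2L)
  # soft-clipped bases are excluded: only the 10 M bases enter the pileup,
  # aligned from position 10 (the two clipped G's never appear there)
  rec3 <- toy_records(10L, "+", len = 12L, seq = "GGATGACCTCAA")
  rec3$cigar <- "2S10M"
  pu3 <- build_pileup(rec3, g)
  expect_equal(sum(pu3$plus), 10L)
  expect_equal(unname(pu3$plus[11L, "A"]), 1L)
  expect_equal(unname(pu3$plus[11L, "G"]), 0L)
})

test_that("C-to-U calling applies the coverage, frequency and p-value thresholds", {
  g <- toy_plastome()
  cfg <- caller_config()
  # ref C with 60 C / 40 T: called at efficiency 0.40
  pu <- toy_pileup_site(100L, 15L, "+", ref_count = 60L, alt_count = 40L, g)
  sites <- call_c2u(pu, g, cfg)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 15L)
  expect_equal(sites$efficiency, 0.40)
  expect_lt(sites$p_value, 1e-6)
  # coverage 49 -> not called
  pu49 <- toy_pileup_site(100L, 15L, "+", 29L, 20L, g)
  expect_equal(nrow(call_c2u(pu49, g, cfg)), 0L)
  # frequency 0.05 at coverage 100 -> not called
  pu05 <- toy_pileup_site(100L, 15L, "+", 95L, 5L, g)
  expect_equal(nrow(call_c2u(pu05, g, cfg)), 0L)
  # passing coverage and frequency but failing the binomial test
  noisy <- caller_config(base_error_rate = 0.2)
  pu12 <- toy_pileup_site(100L, 15L, "+", 88L, 12L, g)
  expect_equal(nrow(call_c2u(pu12, g, noisy)), 0L)
  # minus-strand site: plus-strand G with A-carrying reads
  pum <- toy_pileup_site(100L, 35L, "-", ref_count = 50L, alt_count = 50L, g)
  sm <- call_c2u(pum, g, cfg)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$strand, "-")
  expect_equal(sm$efficiency, 0.5)
  # a site is never called where the transcript-strand base is not C:
  # same counts placed at a plus-strand 'A' position yield nothing
  puA <- toy_pileup_site(100L, 0L, "+", 60L, 40L, g)
  expect_equal(nrow(call_c2u(puA, g, cfg)), 0L)
})

test_that("site classification follows the genetic code and gene geometry", {
  g <- toy_plastome()
  sites <- data.frame(position = c(15L, 17L, 35L, 33L, 5L),
                      strand = c("+", "+", "-", "+", "+"),
                      edited_count = 40L, unedited_count = 60L,
                      efficiency = 0.4, edited_unedited_ratio = 40 / 60,
                      p_value = 1e-30, stringsAsFactors = FALSE)
  cl <- classify_sites(sites, g, g)
  expect_equal(cl$category, c("silent", "non_silent", "non_silent", "antisense", "noncoding"))
  expect_equal(cl$aa_change[1:3], c("T->T", "S->L", "H->Y"))
  expect_equal(cl$codon_position[1:3], c(3L, 2L, 1L))
  expect_equal(cl$gene_id[1:4], c("gA", "gA", "gB", "gB"))
})

test_that("codon-aware alignment maps positions and scores like the DP oracle", {
  # identical sequences: identity mapping
  seqs <- c(a = "ATGACCTCAAAA", b = "ATGACCTCAAAA")
  aln <- align_orthologs(seqs)
  expect_equal(aln$columns$a, 0:11)
  expect_equal(aln$columns$b, 0:11)
  # one extra codon: a single 3-column gap
  seqs2 <- c(long = "ATGGATACCTCAAAA", short = "ATGACCTCAAAA")
  aln2 <- align_orthologs(seqs2)
  expect_equal(aln2$center, "long")
  gap <- setdiff(0:14, aln2$columns$short)
  expect_length(gap, 3L)
  expect_equal(diff(gap), c(1L, 1L))
  # alignment scores equal brute-force affine DP on short toys
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  code11 <- Biostrings::getGeneticCode("11")
  set.seed(7)
  for (i in 1:5) {
    n1 <- sample(4:9, 1) * 3L
    n2 <- sample(4:9, 1) * 3L
    mk <- function(n) paste0("ATG", paste(sample(c("GCT", "TGC", "GAT", "GAA", "TTT",
                                                   "CAT", "AAA", "CTT", "ATG", "TCT"),
                                                 n / 3 - 1, replace = TRUE), collapse = ""))
    s1 <- mk(n1); s2 <- mk(n2)
    aa <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s),
                                                         genetic.code = code11))
    out <- align_orthologs(c(x = s1, y = s2))
    other <- setdiff(c("x", "y"), out$center)
    expected <- oracle_nw_affine(aa(get(ifelse(other == "x", "s1", "s2"))),
                                 aa(get(ifelse(out$center == "x", "s1", "s2"))),
                                 data_env$BLOSUM62)
    expect_equal(unname(out$scores[other]), expected)
  }
  # internal stop codons are excluded with a warning
  expect_warning(
    aln3 <- align_orthologs(c(a = "ATGTAAAAATTT", b = "ATGAAATTTCAT", c = "ATGAAATTTCAT")),
    "internal stop"
  )
  expect_equal(aln3$excluded, "a")
})

test_that("shared/specific labelling reproduces exhaustive set arithmetic", {
  # one shared gene, identical in three species; sites at columns a, b, c
  base <- toy_plastome()
  genomes <- list(sp1 = base, sp2 = base, sp3 = base)
  ortho <- data.frame(group = "og1", species = c("sp1", "sp2", "sp3"),
                      gene_id = "gA", stringsAsFactors = FALSE)
  mk_sites <- function(pos) {
    if (!length(pos)) return(data.frame())
    data.frame(position = pos, strand = "+", edited_count = 40L,
               unedited_count = 60L, efficiency = 0.4,
               edited_unedited_ratio = 2 / 3, p_value = 1e-30,
               category = "non_silent", gene_id = "gA",
               codon_position = 1L, aa_change = "X->Y",
               stringsAsFactors = FALSE)
  }
  # a = 13, b = 15, c = 17 (all inside gA): sets {a,b}, {b}, {b,c}
  res <- shared_specific(
    list(sp1 = mk_sites(c(13L, 15L)), sp2 = mk_sites(15L), sp3 = mk_sites(c(15L, 17L))),
    genomes, ortho
  )
  s <- res$sites
  expect_equal(s$sharing[s$position == 15L], rep("shared", 3))
  expect_equal(s$sharing[s$position != 15L], rep("specific", 2))
  ints <- res$intersections
  expect_equal(ints$count[ints$combo == "sp1"], 1L)
  expect_equal(ints$count[ints$combo == "sp3"], 1L)
  expect_equal(ints$count[ints$combo == "sp1&sp2&sp3"], 1L)
  # a site in a gene missing from the map stays specific, with a warning
  ortho2 <- ortho[ortho$species != "sp2", ]
  expect_warning(
    res2 <- shared_specific(list(sp1 = mk_sites(15L), sp2 = mk_sites(15L)),
                            genomes[1:2], ortho2),
    "absent"
  )
  expect_true(all(res2$sites$sharing == "specific"))
})

test_that("editing summary aggregates categories and efficiencies", {
  sites <- data.frame(
    position = 1:10, strand = "+", edited_count = 10L, unedited_count = 10L,
    efficiency = c(seq(0.1, 0.4, length.out = 2), seq(0.5, 0.9, length.out = 8)),
    edited_unedited_ratio = 1, p_value = 1e-30,
    category = c(rep("silent", 2), rep("non_silent", 8)),
    stringsAsFactors = FALSE
  )
  sm <- editing_summary(sites)
  expect_equal(sm$n_sites, 10L)
  expect_equal(unname(sm$category_proportions["non_silent"]), 0.8)
  expect_equal(unname(sm$category_counts["antisense"]), 0L)
  empty <- editing_summary(sites[0L, ])
  expect_equal(empty$n_sites, 0L)
  expect_true(all(empty$category_counts == 0L))
})

test_that("pileup of error-free simulated reads matches the edited-transcript truth", {
  cfg <- sim_config(n_genes = 8, n_operons = 3, n_read_pairs = 6000,
                    base_error_rate = 0, seed = 31)
  sp <- simulate_species(cfg, n_edit_sites = 3)
  pu <- build_pileup(sp$records, sp$genome)
  ref <- strsplit(sp$genome$sequence, "")[[1]]
  edits <- sp$manifest$edits
  # away from edit sites every plus-pileup base equals the reference base
  for (strand in c("plus", "minus")) {
    mat <- pu[[strand]]
    covered <- which(rowSums(mat) > 0)
    covered <- setdiff(covered, edits$position + 1L)
    mism <- vapply(covered, function(i) sum(mat[i, ]) - mat[i, ref[i]], numeric(1))
    expect_true(all(mism == 0))
  }
  # at each edit site, edited + unedited reads account for all coverage
  for (k in seq_len(nrow(edits))) {
    key <- if (edits$strand[k] == "+") "plus" else "minus"
    row <- pu[[key]][edits$position[k] + 1L, ]
    bases <- if (edits$strand[k] == "+") c("C", "T") else c("G", "A")
    expect_equal(sum(row), sum(row[bases]))
  }
})
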