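test_that("FASTA round-trips and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">x", con = f)
  cat("ACGT", file = f, append = TRUE, sep = "\n")
  expect_identical(read_fasta(f), c(x = "ACGT"))

  seqs <- c(a = paste(rep("ACGT", 60), collapse = ""), b = "TTTT")
  write_fasta(seqs, f, width = 70)
  expect_identical(read_fasta(f), seqs)

  writeLines(character(), f)
  expect_length(read_fasta(f), 0L)

  writeLines(c(">x", "ACGJ"), f)
  expect_error(read_fasta(f), "line 2")
})

test_that("GFF3 coordinates shift to 0-based half-open and wrap dialect is flagged", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t1\t300\t.\t+\t0\tID=gene1",
    "chr\tsrc\tCDS\t950\t1050\t.\t-\t0\tID=gene2",
    "chr\tsrc\tCDS\t1\t300\t.\t+\t0\tID=gene1"
  ), f)
  expect_warning(feats <- read_gff3(f, genome_length = 1000), "duplicate")
  expect_equal(nrow(feats), 2L)
  g1 <- feats[feats$gene_id == "gene1", ]
  expect_equal(c(g1$start, g1$end), c(0L, 300L))
  expect_false(g1$wraps_origin)
  g2 <- feats[feats$gene_id == "gene2", ]
  expect_true(g2$wraps_origin)
  expect_equal(c(g2$start, g2$end), c(949L, 1050L))

  writeLines(c("chr\tsrc\tCDS\t300\t100\t.\t+\t0\tID=bad"), f)
  expect_error(read_gff3(f, genome_length = 1000), "end < start")
  writeLines(c("chr\tsrc\tCDS\t1\t30\t.\t?\t0\tID=bad"), f)
  expect_error(read_gff3(f, genome_length = 1000), "strand")
})

test_that("GFF3 write/read is an involution on internal coordinates", {
  g <- toy_plastome()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, f)
  back <- read_gff3(f, genome_length = g$length)
  expect_equal(back$start, g$features$start)
  expect_equal(back$end, g$features$end)
  expect_equal(back$strand, g$features$strand)
  expect_equal(back$gene_id, g$features$gene_id)
  expect_equal(back$operon_id, g$features$operon_id)
})

test_that("SAM transcript-strand assignment follows the dUTP convention", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:toy\tLN:100",
    # R1 mapped to the minus strand -> transcript '+'
    "p1\t83\ttoy\t1\t60\t10M\t=\t71\t80\tACGTACGTAC\t*",
    "p1\t163\ttoy\t71\t60\t10M\t=\t1\t-80\tACGTACGTAC\t*",
    # R2 mapped to the minus strand -> transcript '-'
    "p2\t99\ttoy\t1\t60\t10M\t=\t71\t80\tACGTACGTAC\t*",
    "p2\t147\ttoy\t71\t60\t10M\t=\t1\t-80\tACGTACGTAC\t*",
    # unmapped and secondary records are dropped
    "p3\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",
    "p4\t339\ttoy\t5\t60\t10M\t=\t1\t0\tACGTACGTAC\t*"
  ), f)
  rec <- read_sam(f, "fr-firststrand")
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$transcript_strand[rec$read_id == "p1"], c("+", "+"))
  expect_equal(rec$transcript_strand[rec$read_id == "p2"], c("-", "-"))
  # mates of a proper pair always agree
  agree <- tapply(rec$transcript_strand, rec$read_id, function(x) length(unique(x)) == 1L)
  expect_true(all(agree))
})

test_that("single-end 'reverse' convention and SAM error paths", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:toy\tLN:100",
    "s1\t16\ttoy\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "s2\t0\ttoy\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"
  ), f)
  rec <- read_sam(f, "reverse")
  expect_equal(rec$transcript_strand, c("+", "-"))

  writeLines(c("@SQ\tSN:other\tLN:50",
               "s1\t0\ttoy\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"), f)
  expect_error(read_sam(f), "no @SQ header")
  writeLines(c("@SQ\tSN:toy\tLN:100",
               "s1\t0\ttoy\t1\t60\t5M20N5M\t*\t0\t0\tACGTACGTAC\t*"), f)
  expect_error(read_sam(f), "unsupported CIGAR")
})

test_that("simulated SAM survives a write/read round trip with strands intact", {
  ss <- shared_sim()
  f <- withr::local_tempfile(fileext = ".sam")
  refs <- stats::setNames(ss$sim$genome$length, ss$sim$genome$id)
  write_sam(ss$sim$records, refs, f)
  back <- read_sam(f, "fr-firststrand")
  expect_equal(nrow(back), nrow(ss$sim$records))
  ord <- order(back$read_id, back$is_first)
  ord0 <- order(ss$sim$records$read_id, ss$sim$records$is_first)
  expect_equal(back$transcript_strand[ord], ss$sim$records$transcript_strand[ord0])
  expect_equal(back$pos[ord], ss$sim$records$pos[ord0])
})

test_that("newick parsing preserves topology and branch lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):3,C:4);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), c(1, 2, 3, 4))
  # parse-print round trip
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f2)
  expect_equal(stats::cophenetic(read_newick(f2)), stats::cophenetic(tr))

  writeLines("((A,B),C);", f)
  expect_warning(tr2 <- read_newick(f), "branch")
  expect_true(all(tr2$edge.length == 0))
})

test_that("plastome invariants are enforced", {
  g <- toy_plastome()
  expect_true(validate_genome(g))
  expect_error(plastome("bad", "ACGU"), "A/C/G/T/N")
  bad_feats <- data.frame(gene_id = "x", start = 10L, end = 5L, strand = "+")
  expect_error(plastome("bad", paste(rep("A", 20), collapse = ""), bad_feats),
               "start >= end")
})
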