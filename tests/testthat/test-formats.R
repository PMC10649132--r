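test_that("FASTA reading canonicalizes, concatenates and validates", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGT"), f)
  expect_identical(read_fasta(f), c(t1 = "ACGT"))

  writeLines(c(">t1", "acg", "tac"), f)
  expect_identical(read_fasta(f), c(t1 = "ACGTAC"))

  writeLines(c(">t1", "ACGT", ">t1", "GGGG"), f)
  expect_error(read_fasta(f), "t1")

  writeLines(c(">t1", "AC-GT"), f)
  expect_error(read_fasta(f), "position 3")

  writeLines(c(">t1", "ACGT", ">t2", ""), f)
  expect_error(read_fasta(f), "empty sequence")
})

test_that("FASTA writing wraps at line_width and round-trips", {
  f <- tempfile(fileext = ".fa")
  write_fasta(c(t1 = "ACGT"), f)
  expect_identical(readLines(f), c(">t1", "ACGT"))

  long <- paste(rep("ACGT", 33), collapse = "")  # 132 nt
  write_fasta(c(tl = substr(long, 1, 130)), f)
  lines <- readLines(f)
  expect_identical(nchar(lines[-1]), c(60L, 60L, 10L))

  set.seed(1)
  recs <- vapply(1:100, function(i) random_seq(sample(10:400, 1)), character(1))
  names(recs) <- sprintf("rec%03d", 1:100)
  write_fasta(recs, f)
  expect_identical(read_fasta(f), recs)
})

test_that("GTF reading groups exons, reads biotypes and validates geometry", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";',
    'chr1\tx\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'
  ), f)
  m <- read_gtf(f)
  expect_equal(nrow(m), 2L)
  expect_equal(unname(transcript_lengths(m)["t1"]), 202L)
  expect_identical(m$biotype, rep("protein_coding", 2))

  writeLines('chr1\tx\texon\t0\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";', f)
  expect_error(read_gtf(f), "1-based")

  writeLines(c(
    'chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t300\t400\t.\t-\t.\tgene_id "g"; transcript_id "t";'
  ), f)
  expect_error(read_gtf(f), "strand")

  writeLines('chr1\tx\texon\t60\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";', f)
  expect_error(read_gtf(f))

  # unknown biotype collapses to "other"
  writeLines('chr1\tx\texon\t10\t50\t.\t+\t.\tgene_id "g"; transcript_id "t"; gene_biotype "snoRNA";', f)
  expect_identical(read_gtf(f)$biotype, "other")
})

test_that("GTF round-trip reproduces the simulated annotation exactly", {
  cfg <- sim_config(seed = 3, n_coding_genes = 25, n_lnc_genes = 10,
                    n_cis_pairs = 3)
  ref <- simulate_reference(cfg, genome = FALSE)
  f <- tempfile(fileext = ".gtf")
  write_gtf(ref$models, f)
  back <- read_gtf(f)
  ord <- function(d) {
    d <- d[order(d$transcript_id, d$start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back), ord(ref$models))
})

test_that("count tables validate cells and group coverage", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t0\t5\t9"), f)
  gm <- c(s1 = "control", s2 = "control", s3 = "treated")
  cm <- read_count_table(f, gm)
  expect_identical(dim(cm$counts), c(2L, 3L))
  expect_identical(cm$counts["g2", "s3"], 9L)

  writeLines(c("feature_id\ts1\ts2\ts3", "g1\t1\t-1\t3"), f)
  expect_error(read_count_table(f, gm), "negative")
  writeLines(c("feature_id\ts1\ts2\ts3", "g1\t1\t3.7\t3"), f)
  expect_error(read_count_table(f, gm), "non-integer")
  writeLines(c("feature_id\ts1\ts2\ts3", "g1\t1\t2\t3"), f)
  expect_error(read_count_table(f, gm[1:2]), "s3")

  # write/read round-trip
  writeLines(c("feature_id\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t0\t5\t9"), f)
  cm <- read_count_table(f, gm)
  f2 <- tempfile(fileext = ".tsv")
  write_count_table(cm, f2)
  expect_identical(read_count_table(f2, gm)$counts, cm$counts)
})

test_that("BLAST tabular hit tables parse and classify subjects", {
  f <- tempfile(fileext = ".tsv")
  row <- function(q, s, e) paste(q, s, "98.0", "100", "1", "0", "1", "100",
                                 "1", "100", e, "180", sep = "\t")
  writeLines(c(row("c1", "known_lnc", "1e-20"), row("c2", "mystery", "0.001")), f)
  h <- read_hit_table(f, c(known_lnc = "lncRNA"))
  expect_identical(h$subject_class, c("lncRNA", "coding_or_other"))
  expect_equal(h$evalue, c(1e-20, 1e-3))

  file.create(f2 <- tempfile())
  expect_identical(nrow(read_hit_table(f2)), 0L)

  writeLines(paste(rep("a", 11), collapse = "\t"), f)
  expect_error(read_hit_table(f), "12 columns")
})
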