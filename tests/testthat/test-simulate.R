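small_cfg <- function(seed = 17, ...) {
  sim_config(seed = seed, n_coding_genes = 80, n_lnc_genes = 40,
             n_cis_pairs = 5,
             assembly_counts = c("=" = 10, "j" = 6, "o" = 6, "x" = 6,
                                 "i" = 6, "u" = 12),
             n_duplicates = 3, ...)
}

test_that("the reference layout is deterministic and honours cis distances", {
  cfg <- small_cfg()
  r1 <- simulate_reference(cfg, genome = FALSE)
  r2 <- simulate_reference(cfg, genome = FALSE)
  expect_identical(r1$models, r2$models)
  expect_identical(r1$cis_pairs, r2$cis_pairs)

  expect_equal(nrow(r1$genes), 120)
  expect_equal(nrow(r1$cis_pairs), 5)
  expect_true(all(r1$cis_pairs$distance_bp >= 0 &
                  r1$cis_pairs$distance_bp < 20000))
  # recorded distance equals the realized gene-body gap
  g <- r1$genes
  for (k in seq_len(nrow(r1$cis_pairs))) {
    a <- g[g$gene_id == r1$cis_pairs$lnc_gene[k], ]
    b <- g[g$gene_id == r1$cis_pairs$target_gene[k], ]
    gap <- max(a$start - b$end - 1L, b$start - a$end - 1L, 0L)
    expect_identical(gap, r1$cis_pairs$distance_bp[k])
  }
  # gene loci never overlap
  g <- g[order(g$chrom, g$start), ]
  same <- g$chrom[-1] == g$chrom[-nrow(g)]
  expect_true(all(g$start[-1][same] > g$end[-nrow(g)][same]))

  # byte-identical GTF on rerun
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(r1$models, f1); write_gtf(r2$models, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_error(simulate_reference(sim_config(seed = 1, n_chromosomes = 1,
                                             chrom_length_bp = 50000)),
               "too short")
})

test_that("sequences satisfy the planted ORF constraints and hexamer bias", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg, genome = FALSE)
  sq <- simulate_sequences(ref, cfg)
  lens <- transcript_lengths(ref$models)
  expect_identical(unname(nchar(sq$sequences)), unname(as.integer(lens[names(sq$sequences)])))

  orf <- longest_orf_lengths(sq$sequences)
  expect_true(all(orf[sq$label == "coding"] >= 300))
  expect_true(all(orf[sq$label == "noncoding"] < 300))

  tab <- build_hexamer_table(sq$sequences[sq$label == "coding"],
                             sq$sequences[sq$label == "noncoding"])
  sc <- vapply(sq$sequences, hexamer_score, numeric(1), table = tab)
  expect_gt(mean(sc[sq$label == "coding"]), mean(sc[sq$label == "noncoding"]))
})

test_that("the assembly covers every planted code with ground truth for all", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg, genome = FALSE)
  sq <- simulate_sequences(ref, cfg)
  asm <- simulate_assembly(ref, sq, cfg)
  expect_setequal(unique(asm$truth$planted_code), c("=", "j", "o", "x", "i", "u"))
  # every emitted transcript is labelled exactly once
  ids <- unique(asm$models$transcript_id)
  expect_setequal(asm$truth$transcript_id, ids)
  expect_identical(anyDuplicated(asm$truth$transcript_id), 0L)
  expect_setequal(names(asm$sequences), ids)
  # duplicates share sequence with their source
  dups <- asm$truth$transcript_id[asm$truth$is_duplicate]
  expect_length(dups, 3L)
  for (d in dups) {
    expect_identical(asm$sequences[[d]], asm$sequences[[sub("\\.dup$", "", d)]])
  }
})

test_that("counts carry planted effects, cis correlation and determinism", {
  cfg <- small_cfg(frac_de = 0)
  sim <- simulate_counts(sprintf("f%d", 1:800), cfg)
  cm <- sim$counts$counts
  expect_true(all(sim$truth$true_lfc == 0))
  lfc <- log2((rowMeans(cm[, 5:7]) + 1) / (rowMeans(cm[, 1:4]) + 1))
  expect_lt(abs(mean(lfc)), 0.05)

  sim2 <- simulate_counts(sprintf("f%d", 1:800), cfg)
  expect_identical(cm, sim2$counts$counts)

  # planted cis pairs correlate above random pairs
  cfg2 <- small_cfg(seed = 23)
  ref <- simulate_reference(cfg2, genome = FALSE)
  sim3 <- simulate_counts(ref$genes$gene_id, cfg2, cis_pairs = ref$cis_pairs)
  x <- log2(sim3$counts$counts + 1)
  cp <- ref$cis_pairs
  r_cis <- mapply(function(a, b) cor(x[a, ], x[b, ]), cp$lnc_gene, cp$target_gene)
  set.seed(1)
  others <- setdiff(rownames(x), c(cp$lnc_gene, cp$target_gene))
  r_rand <- replicate(200, cor(x[sample(others, 1), ], x[sample(others, 1), ]))
  expect_gt(mean(r_cis), mean(r_rand, na.rm = TRUE) + 0.3)

  # group sizes mirror the study design
  expect_identical(as.vector(table(sim$counts$groups)[c("control", "treated")]),
                   c(4L, 3L))
})

test_that("written simulation files round-trip through the format readers", {
  cfg <- small_cfg(seed = 29)
  study <- simulate_study(cfg, genome = FALSE)
  d <- tempfile("simdir")
  write_simulation(study, d)
  expect_identical(read_gtf(file.path(d, "reference.gtf")),
                   study$reference$models)
  expect_identical(read_fasta(file.path(d, "assembled.fa")),
                   study$assembly$sequences)
  gm <- study$expression$counts$groups
  back <- read_count_table(file.path(d, "counts.tsv"), gm)
  expect_identical(back$counts, study$expression$counts$counts)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_setequal(unlist(gt$novel_lncRNA_ids), study$assembly$novel_lncRNA_ids)
})
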