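test_that("Pearson r and p match closed forms and the t reference", {
  res <- pearson_with_p(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$r, 1)

  # at the study's n = 7, r = 0.90 is comfortably below p = 0.05
  p90 <- lncpipe:::cor_p(0.90, 7)
  expect_equal(p90, 2 * pt(-0.9 * sqrt(5 / (1 - 0.81)), df = 5))
  expect_lt(p90, 0.05)
  expect_equal(p90, 0.005752, tolerance = 1e-4)

  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- pearson_with_p(x, y)
    r_bf <- (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    expect_equal(res$r, r_bf, tolerance = 1e-10)
    ct <- cor.test(x, y)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("cis screening uses strict gene-body distance on one chromosome", {
  mk <- function(id, chrom, start, end, biotype) {
    data.frame(transcript_id = paste0(id, ".t"), gene_id = id, chrom = chrom,
               strand = "+", start = start, end = end, biotype = biotype,
               stringsAsFactors = FALSE)
  }
  ann <- rbind(mk("L1", "chr1", 1000L, 2000L, "lncRNA"),
               mk("G1", "chr1", 22000L, 23000L, "protein_coding"),   # gap 19999
               mk("G2", "chr1", 22001L, 23001L, "protein_coding"),   # gap 20000
               mk("G3", "chr2", 3000L, 4000L, "protein_coding"),
               mk("G4", "chr1", 1500L, 2500L, "protein_coding"))     # overlap
  cis <- cis_candidates("L1", c("G1", "G2", "G3", "G4"), ann)
  expect_identical(sort(cis$deg_id), c("G1", "G4"))
  expect_identical(cis$distance_bp[cis$deg_id == "G1"], 19999L)
  expect_identical(cis$distance_bp[cis$deg_id == "G4"], 0L)
  expect_warning(cis_candidates("L1", "missing_gene", ann), "missing")
})

test_that("the emitted network equals a brute-force threshold filter", {
  cfg <- sim_config(seed = 55)
  ref <- simulate_reference(cfg, genome = FALSE)
  sim <- simulate_counts(ref$genes$gene_id, cfg, cis_pairs = ref$cis_pairs)
  cnt <- sim$counts$counts
  expr <- log2(sweep(cnt, 2, size_factors(cnt), "/") + 1)
  dels <- ref$genes$gene_id[ref$genes$biotype == "lncRNA"][1:30]
  degs <- ref$genes$gene_id[ref$genes$biotype == "protein_coding"][1:50]
  cis <- cis_candidates(dels, degs, ref$models)
  net <- build_target_network(expr[dels, ], expr[degs, ], cis = cis)

  brute <- list()
  for (a in dels) for (b in degs) {
    res <- pearson_with_p(expr[a, ], expr[b, ])
    if (abs(res$r) >= 0.90 && res$p <= 0.05) {
      brute[[length(brute) + 1L]] <- data.frame(del_id = a, deg_id = b,
                                                r = res$r, stringsAsFactors = FALSE)
    }
  }
  brute <- do.call(rbind, brute)
  expect_identical(paste(net$del_id, net$deg_id),
                   paste(brute$del_id, brute$deg_id)[order(brute$del_id, brute$deg_id)])
  expect_equal(net$r, brute$r[order(brute$del_id, brute$deg_id)], tolerance = 1e-12)

  # threshold monotonicity: tightening either threshold never adds an edge
  tighter <- build_target_network(expr[dels, ], expr[degs, ], cis = cis, r_min = 0.95)
  expect_true(all(paste(tighter$del_id, tighter$deg_id) %in%
                  paste(net$del_id, net$deg_id)))
  stricter <- build_target_network(expr[dels, ], expr[degs, ], cis = cis, alpha = 0.01)
  expect_true(all(paste(stricter$del_id, stricter$deg_id) %in%
                  paste(net$del_id, net$deg_id)))

  # cis/trans partition with bounded distances; signs follow r
  expect_true(all(net$mode %in% c("cis", "trans")))
  expect_true(all(net$distance_bp[net$mode == "cis"] < 20000))
  expect_true(all(is.na(net$distance_bp[net$mode == "trans"])))
  expect_identical(net$sign, ifelse(net$r > 0, "positive", "negative"))
})

test_that("identical profiles give a sign-positive unit edge", {
  expr <- matrix(c(1, 3, 2, 5, 4, 7, 6), 1, dimnames = list("L1", sprintf("s%d", 1:7)))
  deg <- expr * 2; rownames(deg) <- "G1"
  net <- build_target_network(expr, deg)
  expect_equal(net$r, 1)
  expect_identical(net$sign, "positive")
  expect_identical(net$mode, "trans")
  expect_error(build_target_network(expr, deg[, 7:1]), "same samples")
})

test_that("hypergeometric ORA matches closed form and exhaustive enumeration", {
  universe <- sprintf("g%02d", 1:20)
  terms <- list(all = universe, five = universe[1:5])
  res <- ora_enrichment(universe[1:5], universe, terms)
  expect_equal(res$p[res$term == "all"], 1)
  expect_equal(res$p[res$term == "five"], 1 / choose(20, 5), tolerance = 1e-12)

  # exhaustive check on N <= 12
  uni <- letters[1:10]
  term <- letters[1:4]
  hits <- c("a", "b", "e")
  res <- ora_enrichment(hits, uni, list(t = term))
  expect_equal(res$p, oracle_hyper_enum(uni, term, length(hits), 2))
  expect_error(ora_enrichment(c("a", "zz"), uni, list(t = term)), "outside")
})

test_that("structure summary reproduces planted lncRNA/mRNA differences", {
  cfg <- sim_config(seed = 61, n_coding_genes = 150, n_lnc_genes = 80,
                    n_cis_pairs = 5)
  ref <- simulate_reference(cfg, genome = FALSE)
  lnc <- ref$models[ref$models$biotype == "lncRNA", ]
  cod <- ref$models[ref$models$biotype == "protein_coding", ]
  s <- structure_summary(lnc, cod)
  st <- s$stats
  expect_lt(st$lnc_mean[st$metric == "transcript_length"],
            st$mrna_mean[st$metric == "transcript_length"])
  expect_lt(st$lnc_mean[st$metric == "exon_count"],
            st$mrna_mean[st$metric == "exon_count"])
  expect_gt(st$lnc_mean[st$metric == "exon_length"],
            st$mrna_mean[st$metric == "exon_length"])
  expect_true(all(s$tests < 0.05))
  # histogram masses equal class sizes
  expect_equal(sum(s$histograms$transcript_length$lnc), 80)
  expect_equal(sum(s$histograms$exon_count$mrna), 150)

  ident <- structure_summary(lnc, lnc)
  expect_equal(ident$stats$lnc_mean, ident$stats$mrna_mean)
  expect_true(all(ident$tests > 0.9))

  # Mann-Whitney U agrees with the brute-force pairwise count
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  W <- suppressWarnings(wilcox.test(x, y)$statistic)
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(W), U)
})
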