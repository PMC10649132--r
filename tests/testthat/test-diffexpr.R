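toy_groups <- c(s1 = "control", s2 = "control", s3 = "treated", s4 = "treated")

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  f <- size_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))  # ratio 1:2, geomean 1

  m2 <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(m2) <- c("s1", "s2", "s3")
  expect_equal(unname(size_factors(m2)), rep(1, 3))

  # 5x3 hand computation (zero-containing feature excluded from the reference)
  m3 <- matrix(c(100L, 50L, 10L, 80L, 0L,
                 200L, 60L, 30L, 90L, 5L,
                 150L, 55L, 20L, 85L, 2L), ncol = 3,
               dimnames = list(sprintf("g%d", 1:5), c("s1", "s2", "s3")))
  keep <- m3[rowSums(m3 == 0) == 0, ]
  geo <- exp(rowMeans(log(keep)))
  raw <- apply(keep, 2, function(col) median(col / geo))
  expect_equal(unname(size_factors(m3)), unname(raw / exp(mean(log(raw)))))

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "nonzero")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  set.seed(31)
  pois <- matrix(rpois(1500 * 4, 150), 1500, 4,
                 dimnames = list(sprintf("p%d", 1:1500), names(toy_groups)))
  d <- estimate_dispersion(pois, size_factors(pois), toy_groups)
  expect_lt(median(d), 0.02)

  cfg <- sim_config(seed = 31, frac_de = 0, n_cis_pairs = 0)
  sim <- simulate_counts(sprintf("f%d", 1:2000), cfg)
  cm <- sim$counts
  d <- estimate_dispersion(cm$counts, size_factors(cm$counts), cm$groups)
  expect_gt(median(d), 0.05)
  expect_lt(median(d), 0.2)

  # constant feature: raw moment estimate is floored
  const <- matrix(5L, 3, 4, dimnames = list(c("a", "b", "c"), names(toy_groups)))
  const[2, ] <- c(5L, 6L, 4L, 5L)
  const[3, ] <- c(9L, 2L, 7L, 4L)
  d <- estimate_dispersion(const, rep(1, 4), toy_groups, shrink = FALSE)
  expect_equal(unname(d["a"]), 1e-8)
})

test_that("Wald test is null-centred for identical groups", {
  m <- matrix(rep(c(40L, 400L, 4000L), 4), ncol = 4,
              dimnames = list(c("g1", "g2", "g3"), names(toy_groups)))
  res <- wald_test(m, toy_groups, rep(1, 4), rep(0.1, 3))
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$p > 0.999))
})

test_that("rescaling one sample moves only its size factor, not fold changes", {
  set.seed(8)
  m <- matrix(rnbinom(500 * 7, size = 10, mu = 200), 500, 7)
  dimnames(m) <- list(sprintf("g%d", 1:500),
                      c(sprintf("CT%d", 1:4), sprintf("TAM%d", 1:3)))
  m[m == 0] <- 1L
  groups <- stats::setNames(rep(c("control", "treated"), c(4, 3)), colnames(m))
  m2 <- m; m2[, "CT1"] <- m2[, "CT1"] * 3L
  f1 <- size_factors(m); f2 <- size_factors(m2)
  expect_equal(f2[["CT1"]] / f1[["CT1"]] * (f2[["CT2"]] / f1[["CT2"]])^-1, 3,
               tolerance = 1e-12)
  d <- rep(0.1, 500)
  # exact invariance on the unmoderated ratio; the moderating constant adds
  # only a vanishing scale dependence
  r1 <- wald_test(m, groups, f1, d, moderation = 0)
  r2 <- wald_test(m2, groups, f2, d, moderation = 0)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-12)
  r1m <- wald_test(m, groups, f1, d)
  r2m <- wald_test(m2, groups, f2, d)
  expect_equal(r1m$log2fc, r2m$log2fc, tolerance = 0.01)
})

test_that("BH adjustment matches the examples and stays bounded", {
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("DE calls honour the boundary thresholds", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    base_mean = 100, log2fc = c(1.0, 0.9, -1.2),
                    se = 0.1, wald = 1,
                    p = c(0.05, 0.04, 0.04), stringsAsFactors = FALSE)
  # single-feature families keep padj = p
  out <- do.call(rbind, lapply(seq_len(3), function(i) call_de(res[i, ])))
  expect_identical(out$call, c("up", "ns", "down"))
})

test_that("sample QC flags the planted outlier and nothing else", {
  cfg <- sim_config(seed = 13, outlier_sample = TRUE)
  ref <- simulate_reference(cfg, genome = FALSE)
  sim <- simulate_counts(ref$genes$gene_id, cfg, cis_pairs = ref$cis_pairs)
  qc <- sample_qc(sim$counts)
  expect_identical(qc$flagged, sim$outlier_sample)
  expect_true(isSymmetric(qc$distances))
  expect_equal(unname(diag(qc$distances)), rep(0, 7))

  # duplicated sample has distance zero
  m <- sim$counts$counts
  m[, "CT2"] <- m[, "CT1"]
  qc2 <- sample_qc(count_matrix(m, sim$counts$groups))
  expect_equal(qc2$distances["CT1", "CT2"], 0)

  # exclusion is an explicit action: run_de drops the named sample
  de <- run_de(sim$counts, exclude = qc$flagged)
  expect_s3_class(de, "data.frame")
  expect_true(all(c("padj", "call") %in% colnames(de)))
})
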