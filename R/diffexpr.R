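#' Median-of-ratios size factors
#'
#' Per-feature geometric means over samples are computed on features without
#' zeros; each sample's factor is the median ratio of its counts to those
#' geometric means, rescaled so the factors have geometric mean 1.
#'
#' @param counts Non-negative count matrix (features x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) stop("no feature has nonzero counts in all samples")
  x <- counts[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(x)))
  f <- apply(x, 2, function(col) stats::median(col / geo))
  f / exp(mean(log(f)))
}

normalize_counts <- function(counts, factors) {
  sweep(counts, 2, factors, "/")
}

#' Method-of-moments per-feature NB dispersion
#'
#' On normalized counts, the within-group pooled variance and mean give the
#' moment estimate `alpha = (s^2 - mu) / mu^2`, floored at zero (and then at
#' 1e-8). With `shrink = TRUE`, per-feature estimates falling below the
#' 10%-trimmed mean of all estimates are raised to that common value while
#' larger estimates are kept: with only a handful of samples the moment
#' estimator is very noisy and chance underestimates would otherwise
#' understate the Wald standard error and inflate the false-positive rate,
#' so shrinkage is applied asymmetrically, never below the common
#' dispersion.
#'
#' @param counts Count matrix.
#' @param factors Size factors from [size_factors()].
#' @param groups Named group vector (`control`/`treated`) for the columns.
#' @param shrink Shrink toward the trimmed mean? (default `TRUE`)
#' @return Named non-negative numeric vector, one dispersion per feature.
#' @export
estimate_dispersion <- function(counts, factors, groups, shrink = TRUE) {
  x <- normalize_counts(counts, factors)
  gs <- split(seq_len(ncol(x)), groups[colnames(x)])
  ss <- 0; df <- 0
  mu <- rowMeans(x)
  for (idx in gs) {
    if (length(idx) < 2L) next
    gm <- rowMeans(x[, idx, drop = FALSE])
    ss <- ss + rowSums((x[, idx, drop = FALSE] - gm)^2)
    df <- df + length(idx) - 1L
  }
  if (df == 0L) stop("need at least one group with >= 2 samples")
  s2 <- ss / df
  alpha <- pmax((s2 - mu) / mu^2, 0)
  if (shrink) {
    alpha <- pmax(alpha, mean(alpha, trim = 0.1))
  }
  pmax(alpha, 1e-8)
}

#' Negative-binomial Wald test for two groups
#'
#' Group means are taken on normalized counts; the log2 fold change uses a
#' moderating constant `c` on both means, its standard error follows from
#' the NB variance `mu + alpha * mu^2` by the delta method, and the Wald
#' statistic is referred to a standard normal.
#'
#' @param counts Count matrix (features x samples).
#' @param groups Named group vector (`control`/`treated`).
#' @param factors Size factors.
#' @param dispersions Per-feature dispersions.
#' @param moderation Moderating constant added to both group means on the
#'   normalized-count scale (default 0.5).
#' @return `data.frame` with `feature_id`, `base_mean`, `log2fc`
#'   (treated vs control), `se`, `wald`, `p`.
#' @export
wald_test <- function(counts, groups, factors, dispersions, moderation = 0.5) {
  groups <- groups[colnames(counts)]
  ic <- which(groups == "control"); it <- which(groups == "treated")
  if (length(ic) < 2L || length(it) < 2L) stop("each group needs >= 2 samples")
  x <- normalize_counts(counts, factors)
  mu_c <- rowMeans(x[, ic, drop = FALSE])
  mu_t <- rowMeans(x[, it, drop = FALSE])
  c0 <- moderation
  lfc <- log2((mu_t + c0) / (mu_c + c0))
  # variance of a group mean of normalized NB counts
  var_mean <- function(mu, idx) {
    v <- outer(mu, 1 / factors[idx]) + dispersions * mu^2
    rowSums(v) / length(idx)^2
  }
  se2 <- var_mean(mu_t, it) / ((mu_t + c0)^2 * log(2)^2) +
         var_mean(mu_c, ic) / ((mu_c + c0)^2 * log(2)^2)
  se <- sqrt(pmax(se2, 1e-16))
  wald <- lfc / se
  p <- 2 * stats::pnorm(-abs(wald))
  data.frame(feature_id = rownames(counts),
             base_mean = rowMeans(x), log2fc = lfc, se = se,
             wald = wald, p = p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving.
#'
#' @param pvals Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Apply significance and fold-change thresholds to test results
#'
#' A feature is called `up` when `padj <= alpha` and `log2fc >= lfc`, `down`
#' when `padj <= alpha` and `log2fc <= -lfc`, otherwise `ns`. Boundary
#' values are significant.
#'
#' @param results `data.frame` from [wald_test()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc Absolute log2-fold-change threshold (default 1.0).
#' @return `results` with added `padj` and `call` columns.
#' @export
call_de <- function(results, alpha = 0.05, lfc = 1.0) {
  results$padj <- bh_adjust(results$p)
  results$call <- ifelse(results$padj <= alpha & results$log2fc >= lfc, "up",
                  ifelse(results$padj <= alpha & results$log2fc <= -lfc, "down", "ns"))
  results
}

#' Run the two-group NB differential-expression pipeline
#'
#' @param cm [count_matrix()] object.
#' @param alpha,lfc Calling thresholds (defaults 0.05 and 1.0).
#' @param exclude Optional sample ids dropped before testing (e.g. an
#'   outlier flagged by [sample_qc()]).
#' @return `data.frame` of per-feature results with `padj` and `call`.
#' @export
run_de <- function(cm, alpha = 0.05, lfc = 1.0, exclude = NULL) {
  counts <- cm$counts; groups <- cm$groups
  if (!is.null(exclude)) {
    keep <- setdiff(colnames(counts), exclude)
    counts <- counts[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  f <- size_factors(counts)
  disp <- estimate_dispersion(counts, f, groups)
  res <- wald_test(counts, groups, f, disp)
  call_de(res, alpha = alpha, lfc = lfc)
}

#' Sample quality control: PCA, distances and outlier flags
#'
#' Runs PCA on log2(normalized count + 1) (features centered), computes the
#' Euclidean sample distance matrix, and flags a sample when its median
#' distance to same-group samples exceeds the group median of those medians
#' by more than `z_cut` MADs. Flags are advisory; exclusion is an explicit
#' user action.
#'
#' @param cm [count_matrix()] object (>= 3 samples).
#' @param z_cut Robust z threshold (default 3).
#' @return List of class `qc_report`: `pca` (`data.frame` with PC1/PC2 and
#'   group), `distances` (matrix), `flagged` (sample ids).
#' @export
sample_qc <- function(cm, z_cut = 3) {
  counts <- cm$counts
  if (ncol(counts) < 3L) stop("sample QC needs >= 3 samples")
  f <- size_factors(counts)
  lx <- log2(normalize_counts(counts, f) + 1)
  pca <- stats::prcomp(t(lx), center = TRUE, scale. = FALSE)
  d <- as.matrix(stats::dist(t(lx)))
  flagged <- character(0)
  for (g in unique(cm$groups)) {
    ids <- names(cm$groups)[cm$groups == g]
    if (length(ids) < 3L) next
    med <- vapply(ids, function(s) stats::median(d[s, setdiff(ids, s)]), numeric(1))
    cut <- stats::median(med) + z_cut * stats::mad(med)
    flagged <- c(flagged, ids[med > cut])
  }
  structure(list(
    pca = data.frame(sample_id = colnames(counts),
                     PC1 = pca$x[, 1], PC2 = pca$x[, 2],
                     group = unname(cm$groups[colnames(counts)]),
                     row.names = NULL, stringsAsFactors = FALSE),
    distances = d,
    flagged = flagged
  ), class = "qc_report")
}
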