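#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return List with `r` and `p` (`t = r * sqrt((n-2)/(1-r^2))` referred to
#'   Student t with n-2 df, two-sided).
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  list(r = r, p = cor_p(r, n))
}

cor_p <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-15)
  t <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(-t, df = n - 2)
}

#' Screen DEL-DEG pairs within the genomic cis window
#'
#' The distance between two genes is the minimal gap between their gene
#' bodies (union of transcript spans) on the same chromosome; overlapping
#' bodies have distance 0. Pairs on the same chromosome with distance
#' strictly below `window` are cis candidates; strand is ignored.
#'
#' @param del_genes,deg_genes Character vectors of gene ids.
#' @param annotation Transcript-model table containing both sets.
#' @param window Cis window in bp (default 20000).
#' @return `data.frame` with `del_id`, `deg_id`, `distance_bp`.
#' @export
cis_candidates <- function(del_genes, deg_genes, annotation, window = 20000) {
  spans <- transcript_spans(annotation)
  body <- do.call(rbind, lapply(split(spans, spans$gene_id), function(s) {
    data.frame(gene_id = s$gene_id[1], chrom = s$chrom[1],
               start = min(s$start), end = max(s$end), stringsAsFactors = FALSE)
  }))
  lookup <- function(ids, what) {
    miss <- setdiff(ids, body$gene_id)
    if (length(miss) > 0L) {
      warning("skipping ", what, " gene(s) missing from annotation: ",
              paste(utils::head(miss, 5), collapse = ", "))
      ids <- setdiff(ids, miss)
    }
    body[match(ids, body$gene_id), , drop = FALSE]
  }
  dels <- lookup(del_genes, "DEL"); degs <- lookup(deg_genes, "DEG")
  out <- list()
  for (i in seq_len(nrow(dels))) {
    same <- degs$chrom == dels$chrom[i] & degs$gene_id != dels$gene_id[i]
    if (!any(same)) next
    dg <- degs[same, , drop = FALSE]
    gap <- pmax(dg$start - dels$end[i] - 1L, dels$start[i] - dg$end - 1L, 0L)
    hit <- gap < window
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        del_id = dels$gene_id[i], deg_id = dg$gene_id[hit],
        distance_bp = as.integer(gap[hit]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(del_id = character(), deg_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build the DEL-DEG co-expression target network
#'
#' Every DEL x DEG pair is tested by Pearson correlation across samples;
#' pairs passing `|r| >= r_min` and `p <= alpha` become edges. Pairs present
#' in the cis candidate list get `mode = "cis"` (with their genomic
#' distance), all others `trans`. No multiple-testing correction is applied
#' across the correlation family (raw p, mirroring the thresholding this
#' network is defined by).
#'
#' @param del_expr,deg_expr Expression matrices (features x samples, same
#'   samples in the same order), e.g. log2(normalized count + 1).
#' @param cis Cis candidate table from [cis_candidates()] (may be empty).
#' @param r_min Minimum |Pearson r| (default 0.90).
#' @param alpha Maximum p-value (default 0.05).
#' @return `data.frame` of class `correlation_edges`: `del_id`, `deg_id`,
#'   `r`, `p`, `mode`, `sign`, `distance_bp`.
#' @export
build_target_network <- function(del_expr, deg_expr,
                                 cis = NULL, r_min = 0.90, alpha = 0.05) {
  if (!identical(colnames(del_expr), colnames(deg_expr))) {
    stop("DEL and DEG expression matrices must share the same samples")
  }
  n <- ncol(del_expr)
  if (n < 3L) stop("need >= 3 samples for correlation")
  empty <- data.frame(del_id = character(), deg_id = character(),
                      r = numeric(), p = numeric(), mode = character(),
                      sign = character(), distance_bp = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("correlation_edges", "data.frame")
  if (nrow(del_expr) == 0L || nrow(deg_expr) == 0L) return(empty)
  const_del <- apply(del_expr, 1, stats::sd) == 0
  const_deg <- apply(deg_expr, 1, stats::sd) == 0
  if (any(const_del) || any(const_deg)) {
    warning("skipping constant expression profile(s): ",
            paste(utils::head(c(rownames(del_expr)[const_del],
                                rownames(deg_expr)[const_deg]), 5), collapse = ", "))
    del_expr <- del_expr[!const_del, , drop = FALSE]
    deg_expr <- deg_expr[!const_deg, , drop = FALSE]
  }
  r <- stats::cor(t(del_expr), t(deg_expr))
  p <- cor_p(r, n)
  pass <- abs(r) >= r_min & p <= alpha
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(
    del_id = rownames(del_expr)[idx[, 1]],
    deg_id = rownames(deg_expr)[idx[, 2]],
    r = r[idx], p = p[idx],
    mode = "trans",
    sign = ifelse(r[idx] > 0, "positive", "negative"),
    distance_bp = NA_integer_,
    stringsAsFactors = FALSE)
  edges <- edges[edges$del_id != edges$deg_id, , drop = FALSE]
  if (!is.null(cis) && nrow(cis) > 0L) {
    key <- paste(edges$del_id, edges$deg_id)
    ckey <- paste(cis$del_id, cis$deg_id)
    hit <- match(key, ckey)
    edges$mode[!is.na(hit)] <- "cis"
    edges$distance_bp[!is.na(hit)] <- cis$distance_bp[hit[!is.na(hit)]]
  }
  edges <- edges[order(edges$del_id, edges$deg_id), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("correlation_edges", "data.frame")
  edges
}

#' Hypergeometric over-representation test
#'
#' For each term, with N = |universe|, K = term genes in the universe,
#' n = |hits| and k = term genes among the hits, the upper-tail probability
#' P(X >= k) is computed, BH-adjusted across terms.
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param universe Character vector of all testable genes.
#' @param term_map Named list: term id -> character vector of member genes.
#' @return `data.frame` with `term`, `k`, `K`, `n`, `N`, `enrichment`
#'   (ratio (k/n)/(K/N)), `p`, `padj`.
#' @export
ora_enrichment <- function(hits, universe, term_map) {
  stopifnot(length(hits) > 0L, length(universe) > 0L, length(term_map) > 0L)
  universe <- unique(universe)
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L) {
    stop("hit(s) outside the universe: ", paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(term_map), function(term) {
    members <- intersect(term_map[[term]], universe)
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               enrichment = if (K > 0) (k / n) / (K / N) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out
}

#' Structural comparison of lncRNA and mRNA transcript models
#'
#' Summarises transcript length, exon length and exon count per class
#' (mean, sd), tests each metric between classes with a two-sided
#' Mann-Whitney U test, and bins lengths and exon counts into histograms.
#'
#' @param lnc_models,mrna_models Transcript-model tables.
#' @param length_breaks Transcript-length bin edges (bp).
#' @param exon_length_breaks Exon-length bin edges (bp).
#' @param max_exons Exon-count bins run 1..`max_exons` with a final
#'   overflow bin.
#' @return List of class `structure_summary` with `stats` (per class and
#'   metric), `tests` (p-value per metric) and `histograms`.
#' @export
structure_summary <- function(lnc_models, mrna_models,
                              length_breaks = c(seq(0, 5000, by = 500), Inf),
                              exon_length_breaks = c(0, 50, 100, 200, 500, 1000, Inf),
                              max_exons = 10) {
  metrics <- function(models) {
    list(transcript_length = as.numeric(transcript_lengths(models)),
         exon_length = as.numeric(models$end - models$start + 1),
         exon_count = as.numeric(exon_counts(models)))
  }
  a <- metrics(lnc_models); b <- metrics(mrna_models)
  stats_tab <- do.call(rbind, lapply(names(a), function(m) {
    data.frame(metric = m,
               lnc_mean = mean(a[[m]]), lnc_sd = stats::sd(a[[m]]),
               mrna_mean = mean(b[[m]]), mrna_sd = stats::sd(b[[m]]),
               stringsAsFactors = FALSE)
  }))
  tests <- vapply(names(a), function(m) {
    stats::wilcox.test(a[[m]], b[[m]], exact = FALSE)$p.value
  }, numeric(1))
  hist_of <- function(x, breaks) table(cut(x, breaks = breaks, include.lowest = TRUE))
  exon_breaks <- c(seq(0.5, max_exons + 0.5, by = 1), Inf)
  histograms <- list(
    transcript_length = list(lnc = hist_of(a$transcript_length, length_breaks),
                             mrna = hist_of(b$transcript_length, length_breaks)),
    exon_length = list(lnc = hist_of(a$exon_length, exon_length_breaks),
                       mrna = hist_of(b$exon_length, exon_length_breaks)),
    exon_count = list(lnc = hist_of(a$exon_count, exon_breaks),
                      mrna = hist_of(b$exon_count, exon_breaks))
  )
  structure(list(stats = stats_tab, tests = tests, histograms = histograms),
            class = "structure_summary")
}
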