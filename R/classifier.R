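#' Train a cross-validated random-forest coding-potential classifier
#'
#' A stratified hold-out test set is reserved first; hyperparameters are then
#' chosen on the remaining training data by stratified k-fold
#' cross-validation, by mean F1 for the noncoding class; the winning
#' configuration is refit on all training data. Metadata records per-fold
#' precision/recall/F1 and held-out performance.
#'
#' @param features `data.frame` from [feature_matrix()].
#' @param labels Character vector (`coding`/`noncoding`), aligned to rows.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling the split, folds and forests.
#' @param grid `data.frame` of hyperparameter combinations with columns
#'   `ntree` and `nodesize`.
#' @param test_fraction Fraction held out before CV (default 0.2).
#' @return Object of class `coding_classifier`: list with `forest`,
#'   `feature_names`, `metadata`.
#' @export
train_classifier <- function(features, labels,
                             n_folds = 10, seed = 1,
                             grid = expand.grid(ntree = c(100L, 300L),
                                                nodesize = c(1L, 5L)),
                             test_fraction = 0.2) {
  stopifnot(nrow(features) == length(labels))
  labels <- factor(labels, levels = c("coding", "noncoding"))
  if (any(is.na(labels))) stop("labels must be 'coding' or 'noncoding'")
  if (nlevels(droplevels(labels)) < 2L) stop("both classes must be present")
  if (min(table(labels)) < n_folds) stop("n_folds exceeds smallest class size")
  features <- features[, FEATURE_NAMES, drop = FALSE]

  set.seed(seed)
  # stratified hold-out
  test_idx <- unlist(lapply(levels(labels), function(cl) {
    i <- which(labels == cl)
    sample(i, max(1L, round(test_fraction * length(i))))
  }))
  train_idx <- setdiff(seq_along(labels), test_idx)
  xtr <- features[train_idx, , drop = FALSE]; ytr <- droplevels(labels[train_idx])
  xte <- features[test_idx, , drop = FALSE]; yte <- labels[test_idx]

  # stratified fold assignment
  fold <- integer(length(ytr))
  for (cl in levels(ytr)) {
    i <- which(ytr == cl)
    fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  classwt <- rev(as.numeric(table(ytr))) / length(ytr)  # balance classes
  names(classwt) <- levels(ytr)

  fit_rf <- function(x, y, ntree, nodesize) {
    randomForest::randomForest(x = x, y = y, ntree = ntree,
                               nodesize = nodesize, classwt = classwt)
  }
  cv <- lapply(seq_len(nrow(grid)), function(g) {
    per_fold <- lapply(seq_len(n_folds), function(k) {
      rf <- fit_rf(xtr[fold != k, , drop = FALSE], ytr[fold != k],
                   grid$ntree[g], grid$nodesize[g])
      pred <- stats::predict(rf, xtr[fold == k, , drop = FALSE])
      prf(ytr[fold == k], pred, positive = "noncoding")
    })
    do.call(rbind, per_fold)
  })
  mean_f1 <- vapply(cv, function(m) mean(m[, "f1"]), numeric(1))
  best <- which.max(mean_f1)

  final <- fit_rf(xtr, ytr, grid$ntree[best], grid$nodesize[best])
  held_out <- prf(yte, stats::predict(final, xte), positive = "noncoding")

  structure(list(
    forest = final,
    feature_names = FEATURE_NAMES,
    metadata = list(
      seed = seed, n_folds = n_folds, grid = grid,
      best_hyperparameters = as.list(grid[best, , drop = FALSE]),
      cv_mean_f1 = mean_f1,
      cv_per_fold = cv[[best]],
      held_out = held_out,
      n_train = length(train_idx), n_test = length(test_idx)
    )
  ), class = "coding_classifier")
}

# precision/recall/F1 for one positive class
prf <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1,
    accuracy = mean(pred == truth))
}

#' Predict coding status and remove predicted mRNAs
#'
#' @param model `coding_classifier` from [train_classifier()].
#' @param features `data.frame` with the model's feature columns; rownames
#'   are transcript ids.
#' @param threshold Coding-probability cut: transcripts with
#'   `P(coding) >= threshold` are removed (default 0.5).
#' @return List with `retained` ids, `removal_log`, and `predictions`
#'   (`data.frame`: `transcript_id`, `prob_coding`, `predicted`).
#' @export
predict_noncoding <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "coding_classifier"))
  if (nrow(features) == 0L) {
    return(list(retained = character(),
                removal_log = removal_log_entries(character(), "classifier", character()),
                predictions = data.frame(transcript_id = character(),
                                         prob_coding = numeric(),
                                         predicted = character())))
  }
  if (!identical(colnames(features)[seq_along(model$feature_names)], model$feature_names)) {
    stop("feature columns do not match the training feature order")
  }
  prob <- stats::predict(model$forest, features[, model$feature_names, drop = FALSE],
                         type = "prob")
  p_coding <- if ("coding" %in% colnames(prob)) prob[, "coding"] else 1 - prob[, "noncoding"]
  coding_call <- p_coding >= threshold
  ids <- rownames(features)
  list(
    retained = ids[!coding_call],
    removal_log = removal_log_entries(ids[coding_call], "classifier", "predicted_mRNA"),
    predictions = data.frame(transcript_id = ids, prob_coding = unname(p_coding),
                             predicted = ifelse(coding_call, "coding", "noncoding"),
                             stringsAsFactors = FALSE)
  )
}

#' Triage lncRNA candidates by homology search results
#'
#' Candidates are split into three groups using their significant hits
#' (`evalue <= evalue_threshold`): group 1 (any significant hit to a coding
#' or other non-lncRNA subject; removed), group 2 (significant hits only to
#' lncRNA subjects; retained) and group 3 (no significant hit; retained).
#'
#' @param candidates Character vector of candidate transcript ids.
#' @param hits Hit table from [read_hit_table()].
#' @param evalue_threshold Significance cut for hits (default 1e-5).
#' @return List with `retained`, `removal_log` and `groups` (`data.frame`:
#'   `transcript_id`, `group`).
#' @export
triage_by_homology <- function(candidates, hits, evalue_threshold = 1e-5) {
  unknown <- setdiff(unique(hits$query_id), candidates)
  if (length(unknown) > 0L) {
    warning("ignoring hits for unknown candidate id(s): ",
            paste(utils::head(unknown, 5), collapse = ", "))
    hits <- hits[hits$query_id %in% candidates, , drop = FALSE]
  }
  sig <- hits[hits$evalue <= evalue_threshold, , drop = FALSE]
  group <- vapply(candidates, function(id) {
    h <- sig[sig$query_id == id, , drop = FALSE]
    if (nrow(h) == 0L) 3L
    else if (any(h$subject_class == "coding_or_other")) 1L
    else 2L
  }, integer(1))
  list(
    retained = candidates[group != 1L],
    removal_log = removal_log_entries(candidates[group == 1L], "homology",
                                      "significant_coding_match"),
    groups = data.frame(transcript_id = candidates, group = unname(group),
                        stringsAsFactors = FALSE)
  )
}
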