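#' Pipeline configuration
#'
#' Collects every stage threshold in one place. Defaults are the pipeline's
#' canonical operating point: novel candidates keep class codes x/o/i/u/j,
#' structural filter at 200 nt and 2 exons, ORF removal at 300 nt, homology
#' significance at E <= 1e-5, DE calling at adjusted p <= 0.05 with
#' |log2FC| >= 1, and target edges at |r| >= 0.90 with p <= 0.05 within a
#' 20 kb cis window.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param min_length,min_exons Structural filter thresholds.
#' @param orf_threshold ORF-removal threshold in nt.
#' @param evalue Homology significance threshold.
#' @param n_folds Classifier cross-validation folds.
#' @param alpha,lfc DE calling thresholds.
#' @param r_min,cor_alpha Correlation-edge thresholds.
#' @param window Cis window in bp.
#' @param exclude Sample ids to drop before DE (manual outlier exclusion).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, min_length = 200, min_exons = 2,
                            orf_threshold = 300, evalue = 1e-5, n_folds = 10,
                            alpha = 0.05, lfc = 1.0, r_min = 0.90,
                            cor_alpha = 0.05, window = 20000,
                            exclude = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_length > 0, cfg$min_exons > 0, cfg$orf_threshold > 0,
            cfg$evalue > 0, cfg$alpha > 0, cfg$lfc > 0, cfg$r_min > 0,
            cfg$window > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full discovery pipeline on a directory of input files
#'
#' Stages, in order: candidate filtering (class codes, annotated split,
#' structural filter, deduplication), ORF filter, feature extraction and
#' classifier training, coding-potential classification, homology triage
#' (skipped when no hit table is present), differential expression of genes
#' and lncRNAs (separate BH families), sample QC, and cis/trans target
#' inference. Every stage writes its outputs under `outdir`; a manifest
#' with per-file checksums makes reruns verifiable: the same inputs, config
#' and seed give byte-identical outputs.
#'
#' @param indir Directory holding `reference.gtf`, `assembled.gtf`,
#'   `assembled.fa`, `coding_train.fa`, `noncoding_train.fa`, `counts.tsv`,
#'   `groups.tsv` and optionally `hits.tsv` (as written by
#'   [write_simulation()]).
#' @param outdir Output directory (created; must be empty or absent).
#' @param config [pipeline_config()] object.
#' @return Invisible list with the in-memory results of every stage.
#' @export
run_pipeline <- function(indir, outdir, config = pipeline_config()) {
  need <- c("reference.gtf", "assembled.gtf", "assembled.fa",
            "coding_train.fa", "noncoding_train.fa", "counts.tsv", "groups.tsv")
  paths <- file.path(indir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("missing input file(s) in ", indir, ": ", paste(missing, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  tsv <- function(x, f) data.table::fwrite(x, p(f), sep = "\t", eol = "\n")

  reference <- read_gtf(file.path(indir, "reference.gtf"))
  assembled <- read_gtf(file.path(indir, "assembled.gtf"))
  assembled_seqs <- read_fasta(file.path(indir, "assembled.fa"))
  coding_train <- read_fasta(file.path(indir, "coding_train.fa"))
  noncoding_train <- read_fasta(file.path(indir, "noncoding_train.fa"))
  groups_df <- utils::read.delim(file.path(indir, "groups.tsv"),
                                 stringsAsFactors = FALSE)
  group_map <- stats::setNames(groups_df$group, groups_df$sample_id)
  cm <- read_count_table(file.path(indir, "counts.tsv"), group_map)

  # stage 1: retention cascade
  cascade <- filter_cascade(assembled, assembled_seqs, reference,
                            min_length = config$min_length,
                            min_exons = config$min_exons)
  tsv(cascade$codes, "class_codes.tsv")
  writeLines(cascade$novel_candidates, p("novel_candidates.txt"))
  writeLines(cascade$annotated_lncRNAs, p("annotated_lncRNAs.txt"))

  # stage 2: ORF filter
  orf <- orf_filter(assembled_seqs[cascade$novel_candidates],
                    threshold = config$orf_threshold)

  # stage 3: features and classifier
  hex <- build_hexamer_table(coding_train, noncoding_train)
  train_feats <- feature_matrix(c(coding_train, noncoding_train), hex)
  train_labels <- rep(c("coding", "noncoding"),
                      c(length(coding_train), length(noncoding_train)))
  model <- train_classifier(train_feats, train_labels,
                            n_folds = config$n_folds, seed = config$seed)
  cand_feats <- feature_matrix(assembled_seqs[orf$retained], hex)
  tsv(cbind(transcript_id = rownames(cand_feats), cand_feats), "features.tsv")
  jsonlite::write_json(model$metadata[c("seed", "n_folds",
                                        "best_hyperparameters", "cv_mean_f1")],
                       p("model_metadata.json"), auto_unbox = TRUE, digits = NA)

  # stage 4: classification + homology triage
  cls <- predict_noncoding(model, cand_feats)
  tsv(cls$predictions, "predictions.tsv")
  hits_path <- file.path(indir, "hits.tsv")
  if (file.exists(hits_path)) {
    hits <- read_hit_table(hits_path)
  } else {
    hits <- read_hit_table(tempfile_empty())
  }
  triage <- triage_by_homology(cls$retained, hits, evalue_threshold = config$evalue)
  novel_lnc <- triage$retained
  writeLines(novel_lnc, p("novel_lncRNAs.txt"))
  removal_log <- rbind(cascade$removal_log, orf$removal_log,
                       cls$removal_log, triage$removal_log)
  tsv(removal_log, "removal_log.tsv")

  # stage 5: QC + differential expression, genes and lncRNAs separately
  qc <- sample_qc(cm)
  jsonlite::write_json(list(pca = qc$pca, flagged = qc$flagged),
                       p("qc.json"), auto_unbox = TRUE, digits = NA)
  spans <- transcript_spans(reference)
  gene_biotype <- stats::setNames(spans$biotype, spans$gene_id)
  feat_bio <- gene_biotype[rownames(cm$counts)]
  de_sub <- function(biotype) {
    sub <- count_matrix(cm$counts[which(feat_bio == biotype), , drop = FALSE],
                        cm$groups)
    run_de(sub, alpha = config$alpha, lfc = config$lfc, exclude = config$exclude)
  }
  deg <- de_sub("protein_coding")
  del <- de_sub("lncRNA")
  tsv(deg, "de_genes.tsv")
  tsv(del, "de_lncRNAs.tsv")

  # stage 6: cis/trans target inference + structure summary
  keep <- setdiff(colnames(cm$counts), config$exclude)
  counts <- cm$counts[, keep, drop = FALSE]
  expr <- log2(normalize_counts(counts, size_factors(counts)) + 1)
  del_ids <- del$feature_id[del$call != "ns"]
  deg_ids <- deg$feature_id[deg$call != "ns"]
  cis <- cis_candidates(del_ids, deg_ids, reference, window = config$window)
  tsv(cis, "cis_candidates.tsv")
  edges <- build_target_network(expr[del_ids, , drop = FALSE],
                                expr[deg_ids, , drop = FALSE],
                                cis = cis, r_min = config$r_min,
                                alpha = config$cor_alpha)
  tsv(as.data.frame(edges), "edges.tsv")
  summ <- structure_summary(reference[reference$biotype == "lncRNA", , drop = FALSE],
                            reference[reference$biotype == "protein_coding", , drop = FALSE])
  jsonlite::write_json(list(stats = summ$stats, tests = as.list(summ$tests)),
                       p("structure_summary.json"), auto_unbox = TRUE, digits = NA)

  # manifest with per-file checksums
  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package = "lncpipe",
    version = as.character(utils::packageVersion("lncpipe")),
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cascade = cascade, orf = orf, model = model,
                 predictions = cls, triage = triage,
                 novel_lncRNAs = novel_lnc, qc = qc, deg = deg, del = del,
                 cis = cis, edges = edges, structure = summ,
                 manifest = manifest))
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}

#' Simulate a study and run the pipeline on it
#'
#' Convenience wrapper: writes a synthetic study to `file.path(outdir,
#' "inputs")` and runs [run_pipeline()] on it, seeding the simulation from
#' the pipeline seed.
#'
#' @param outdir Run directory.
#' @param config [pipeline_config()] object.
#' @param sim [sim_config()] object; its seed is overridden by
#'   `config$seed`.
#' @return Invisible result of [run_pipeline()], plus `study`.
#' @export
run_simulated_pipeline <- function(outdir, config = pipeline_config(),
                                   sim = sim_config()) {
  sim$seed <- config$seed
  study <- simulate_study(sim, genome = FALSE)
  indir <- file.path(outdir, "inputs")
  write_simulation(study, indir)
  res <- run_pipeline(indir, file.path(outdir, "results"), config)
  res$study <- study
  invisible(res)
}
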