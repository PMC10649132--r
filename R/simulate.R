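#' Configuration for the synthetic study generator
#'
#' Defaults mirror the emulated study design: four control vs three treated
#' samples, a 20 kb cis window, and a desk-scale reference (300 coding and
#' 120 lncRNA genes) whose planted effects (log2FC 2, NB dispersion 0.1,
#' baseline means 20-2000) are resolvable at n = 4 vs 3.
#'
#' @param seed Integer master seed; all sub-stage streams derive from it.
#' @param n_chromosomes,chrom_length_bp Genome layout.
#' @param n_coding_genes,n_lnc_genes Reference gene counts by biotype.
#' @param n_control,n_treated Samples per group.
#' @param frac_de Fraction of features with a planted effect.
#' @param planted_lfc Planted |log2 fold change| (sign equiprobable).
#' @param nb_dispersion Negative-binomial dispersion alpha.
#' @param mean_count_log_range Baseline means drawn log-uniformly over this
#'   (natural-log) range.
#' @param n_cis_pairs Number of lncRNA genes planted within the cis window
#'   of a coding gene, with correlated expression.
#' @param cis_max_distance_bp Cis window (default 20000).
#' @param cis_latent_sdlog Log-sd of the shared lognormal latent factor that
#'   correlates planted cis pairs.
#' @param outlier_sample Plant one treated sample drawn from an unrelated
#'   baseline?
#' @param coding_bias_strength Codon-usage bias of coding sequences, in
#'   \[0,1\].
#' @param assembly_counts Named vector: assembled transcripts to plant per
#'   class code.
#' @param frac_coding_contaminant Fraction of planted novel candidates given
#'   a coding sequence.
#' @param n_duplicates Exact-duplicate transcripts planted for the
#'   deduplication stage.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 4, chrom_length_bp = 4000000,
                       n_coding_genes = 300, n_lnc_genes = 120,
                       n_control = 4, n_treated = 3,
                       frac_de = 0.1, planted_lfc = 2.0,
                       nb_dispersion = 0.1,
                       mean_count_log_range = c(log(20), log(2000)),
                       n_cis_pairs = 10, cis_max_distance_bp = 20000,
                       cis_latent_sdlog = 1.5,
                       outlier_sample = FALSE,
                       coding_bias_strength = 0.8,
                       assembly_counts = c("=" = 30, "j" = 15, "o" = 15,
                                           "x" = 15, "i" = 15, "u" = 30),
                       frac_coding_contaminant = 0.3,
                       n_duplicates = 5) {
  cfg <- as.list(environment())
  stopifnot(cfg$frac_de >= 0, cfg$frac_de <= 1,
            cfg$nb_dispersion > 0,
            cfg$n_control >= 2, cfg$n_treated >= 2,
            cfg$n_cis_pairs >= 0, cfg$n_cis_pairs <= min(cfg$n_coding_genes, cfg$n_lnc_genes),
            cfg$coding_bias_strength >= 0, cfg$coding_bias_strength <= 1,
            cfg$cis_max_distance_bp >= 1)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

ALL_CODONS <- as.vector(outer(outer(c("T","C","A","G"), c("T","C","A","G"), paste0),
                              c("T","C","A","G"), paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# codon probabilities under a positional-composition bias: GC-ending and
# purine-leading codons preferred, mixed with uniform by bias strength
codon_probs <- function(bias) {
  w <- exp(1.2 * (substr(NONSTOP_CODONS, 3, 3) %in% c("G", "C")) +
           0.8 * (substr(NONSTOP_CODONS, 1, 1) %in% c("A", "G")))
  p <- (1 - bias) / length(w) + bias * w / sum(w)
  p / sum(p)
}

make_coding_seq <- function(len, bias) {
  if (len < 312) stop("coding transcript too short for a 300 nt ORF plus UTRs")
  orf_max <- 3L * ((len - 6L) %/% 3L)
  choices <- seq.int(300L, orf_max, by = 3L)
  orf_nt <- choices[sample.int(length(choices), 1L)]
  inner <- orf_nt / 3L - 2L
  body <- paste0("ATG",
                 paste(sample(NONSTOP_CODONS, inner, replace = TRUE,
                              prob = codon_probs(bias)), collapse = ""),
                 sample(STOP_CODONS, 1L))
  utr5 <- sample.int(len - orf_nt + 1L, 1L) - 1L
  paste0(if (utr5 > 0) random_dna(utr5) else "",
         body,
         if (len - orf_nt - utr5 > 0) random_dna(len - orf_nt - utr5) else "")
}

make_noncoding_seq <- function(len, max_attempts = 50) {
  for (i in seq_len(max_attempts)) {
    s <- random_dna(len)
    orf <- find_longest_orf(s)
    if (is.null(orf) || orf$length < 300) return(s)
  }
  stop("rejection sampling failed: no ORF-free sequence of length ", len,
       " after ", max_attempts, " attempts")
}

# exon/intron skeleton of one gene
gene_skeleton <- function(biotype) {
  if (biotype == "protein_coding") {
    n_ex <- sample(3:12, 1L)
    ex <- sample(120:300, n_ex, replace = TRUE)
  } else {
    n_ex <- sample(1:5, 1L)
    ex <- sample(100:600, n_ex, replace = TRUE)
  }
  list(exons = ex,
       introns = if (n_ex > 1L) sample(200:1500, n_ex - 1L, replace = TRUE) else integer(0))
}

#' Simulate a reference genome and annotation
#'
#' Places non-overlapping single-transcript genes on random chromosomes.
#' `n_cis_pairs` lncRNA genes are planted with a gene-body gap to a coding
#' gene drawn uniformly in `[0, cis_max_distance_bp)`; all other adjacent
#' genes are separated by more than the cis window.
#'
#' @param config [sim_config()] object.
#' @param genome Generate chromosome sequences? (`FALSE` skips them when
#'   only coordinates are needed.)
#' @return List of class `sim_reference`: `models` (exon table), `genes`
#'   (per-gene span table with upstream clearance), `genome` (named
#'   character vector or `NULL`), `cis_pairs`, `config`.
#' @export
simulate_reference <- function(config, genome = TRUE) {
  set.seed(config$seed)
  n_cod <- config$n_coding_genes; n_lnc <- config$n_lnc_genes
  ids_cod <- sprintf("GCOD%04d", seq_len(n_cod))
  ids_lnc <- sprintf("GLNC%04d", seq_len(n_lnc))
  skel <- c(stats::setNames(lapply(ids_cod, function(i) gene_skeleton("protein_coding")), ids_cod),
            stats::setNames(lapply(ids_lnc, function(i) gene_skeleton("lncRNA")), ids_lnc))
  biotype <- stats::setNames(rep(c("protein_coding", "lncRNA"), c(n_cod, n_lnc)),
                             c(ids_cod, ids_lnc))

  npair <- config$n_cis_pairs
  cis_cod <- ids_cod[seq_len(npair)]
  cis_lnc <- ids_lnc[seq_len(npair)]
  cis_gap <- if (npair > 0) sample.int(config$cis_max_distance_bp, npair) - 1L else integer(0)
  units <- c(
    lapply(seq_len(npair), function(k) list(genes = c(cis_cod[k], cis_lnc[k]),
                                            gap = cis_gap[k])),
    lapply(setdiff(c(ids_cod, ids_lnc), c(cis_cod, cis_lnc)),
           function(g) list(genes = g, gap = NA))
  )
  units <- units[sample.int(length(units))]

  span_of <- function(g) sum(skel[[g]]$exons) + sum(skel[[g]]$introns)
  rows <- vector("list", length(skel))
  gene_rows <- vector("list", length(skel))
  ri <- 0L
  chrom <- 1L
  cursor <- sample(5000:10000, 1L)
  for (u in units) {
    gap_before <- sample(21000:30000, 1L)
    total <- sum(vapply(u$genes, span_of, numeric(1))) +
      (if (length(u$genes) == 2L) u$gap + 1L else 0L)
    if (cursor + gap_before + total > config$chrom_length_bp) {
      chrom <- chrom + 1L
      if (chrom > config$n_chromosomes) {
        stop("chromosomes too short to place the requested genes without overlap")
      }
      cursor <- sample(5000:10000, 1L)
    }
    pos <- cursor + gap_before
    for (gi in seq_along(u$genes)) {
      g <- u$genes[gi]
      sk <- skel[[g]]
      starts <- pos + c(0L, cumsum(sk$exons[-length(sk$exons)] + sk$introns))
      ends <- starts + sk$exons - 1L
      strand <- sample(c("+", "-"), 1L)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        transcript_id = paste0(g, ".t1"), gene_id = g,
        chrom = paste0("chr", chrom), strand = strand,
        start = starts, end = ends, biotype = biotype[[g]],
        stringsAsFactors = FALSE)
      gene_rows[[ri]] <- data.frame(
        gene_id = g, transcript_id = paste0(g, ".t1"),
        chrom = paste0("chr", chrom), strand = strand,
        start = starts[1L], end = ends[length(ends)],
        biotype = biotype[[g]], stringsAsFactors = FALSE)
      pos <- ends[length(ends)] + 1L + (if (gi < length(u$genes)) u$gap else 0L)
    }
    cursor <- pos
  }
  models <- do.call(rbind, rows[seq_len(ri)])
  genes <- do.call(rbind, gene_rows[seq_len(ri)])
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  prev_end <- c(NA, genes$end[-nrow(genes)])
  same_chrom <- c(FALSE, genes$chrom[-1] == genes$chrom[-nrow(genes)])
  genes$upstream_gap <- ifelse(same_chrom, genes$start - prev_end - 1L, genes$start - 1L)
  rownames(genes) <- NULL

  cis_pairs <- data.frame(lnc_gene = cis_lnc, target_gene = cis_cod,
                          distance_bp = cis_gap, stringsAsFactors = FALSE)
  genome_seqs <- NULL
  if (genome) {
    genome_seqs <- stats::setNames(
      vapply(seq_len(config$n_chromosomes),
             function(i) random_dna(config$chrom_length_bp), character(1)),
      paste0("chr", seq_len(config$n_chromosomes)))
  }
  structure(list(models = validate_models(models), genes = genes,
                 genome = genome_seqs, cis_pairs = cis_pairs, config = config),
            class = "sim_reference")
}

#' Simulate labeled transcript sequences for the reference
#'
#' Coding transcripts carry one sense-strand ORF of at least 300 nt built
#' from a biased codon model and flanked by background UTRs; noncoding
#' transcripts are background sequence rejection-sampled until the longest
#' sense ORF is under 300 nt. Lengths follow the reference exon structure.
#'
#' @param reference `sim_reference` object.
#' @param config [sim_config()] object.
#' @return List with `sequences` (named character vector, one per reference
#'   transcript) and `label` (named vector, `coding`/`noncoding`).
#' @export
simulate_sequences <- function(reference, config) {
  set.seed(config$seed + 1000L)
  lens <- transcript_lengths(reference$models)
  spans <- transcript_spans(reference$models)
  label <- stats::setNames(
    ifelse(spans$biotype == "protein_coding", "coding", "noncoding"),
    spans$transcript_id)[names(lens)]
  seqs <- vapply(names(lens), function(id) {
    if (label[[id]] == "coding") make_coding_seq(lens[[id]], config$coding_bias_strength)
    else make_noncoding_seq(lens[[id]])
  }, character(1))
  list(sequences = seqs, label = label)
}

#' Simulate an assembled transcript set with planted class codes
#'
#' Emits transcripts engineered to receive each class code against the
#' reference: exact copies (`=`, split between coding and lncRNA
#' references), junction-sharing truncations (`j`), same- and
#' opposite-strand exonic overlaps (`o`, `x`), intron-contained transcripts
#' (`i`) and intergenic transcripts (`u`), plus exact sequence duplicates
#' for the deduplication stage. Non-`=` transcripts get a coding or
#' noncoding sequence per `frac_coding_contaminant`.
#'
#' @param reference `sim_reference` object.
#' @param ref_seqs Output of [simulate_sequences()].
#' @param config [sim_config()] object.
#' @return List of class `sim_assembly`: `models`, `sequences`, `truth`
#'   (`data.frame`: `transcript_id`, `planted_code`,
#'   `matched_reference_id`, `coding_label`, `is_duplicate`) and
#'   `novel_lncRNA_ids` (ground-truth novel lncRNAs after deduplication).
#' @export
simulate_assembly <- function(reference, ref_seqs, config) {
  set.seed(config$seed + 2000L)
  genes <- reference$genes
  models <- reference$models
  want <- config$assembly_counts
  exons_by_tx <- split(models, models$transcript_id)
  gene_tx <- stats::setNames(genes$transcript_id, genes$gene_id)

  out_rows <- list(); out_seq <- character(0)
  truth <- list()
  add <- function(id, exon_df, seq, code, ref_id, label, dup = FALSE) {
    out_rows[[length(out_rows) + 1L]] <<- exon_df
    out_seq[id] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = id, planted_code = code,
      matched_reference_id = ref_id, coding_label = label,
      is_duplicate = dup, stringsAsFactors = FALSE)
  }
  exon_df <- function(id, chrom, strand, starts, ends) {
    data.frame(transcript_id = id, gene_id = id, chrom = chrom,
               strand = strand, start = as.integer(starts),
               end = as.integer(ends), biotype = "other",
               stringsAsFactors = FALSE)
  }
  label_for <- function(n) {
    lab <- rep("noncoding", n)
    n_cod <- round(config$frac_coding_contaminant * n)
    if (n_cod > 0) lab[sample.int(n, n_cod)] <- "coding"
    lab
  }
  seq_for <- function(label, len) {
    if (label == "coding") make_coding_seq(len, config$coding_bias_strength)
    else make_noncoding_seq(len)
  }

  # "=": exact copies, alternating lncRNA and coding references
  n_eq <- want[["="]]
  eq_lnc <- genes$gene_id[genes$biotype == "lncRNA"]
  eq_cod <- genes$gene_id[genes$biotype == "protein_coding"]
  pick <- c(sample(eq_lnc, ceiling(n_eq / 2)), sample(eq_cod, floor(n_eq / 2)))
  for (k in seq_along(pick)) {
    tx <- gene_tx[[pick[k]]]
    ex <- exons_by_tx[[tx]]
    id <- sprintf("ASM.EQ%03d", k)
    add(id, exon_df(id, ex$chrom[1], ex$strand[1], ex$start, ex$end),
        ref_seqs$sequences[[tx]], "=", tx,
        unname(ref_seqs$label[tx]))
  }

  # "j": first two exons of a >= 3-exon coding reference
  j_refs <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  j_refs <- j_refs[vapply(j_refs$transcript_id,
                          function(t) nrow(exons_by_tx[[t]]) >= 3L, logical(1)), ]
  two_exon_len <- vapply(j_refs$transcript_id, function(t) {
    ex <- exons_by_tx[[t]]; ex <- ex[order(ex$start), ]
    sum(ex$end[1:2] - ex$start[1:2] + 1L)
  }, integer(1))
  pick <- sample(j_refs$transcript_id[two_exon_len >= 360L], want[["j"]])
  labs <- label_for(want[["j"]])
  for (k in seq_along(pick)) {
    ex <- exons_by_tx[[pick[k]]]
    ex <- ex[order(ex$start), ][1:2, ]
    id <- sprintf("ASM.J%03d", k)
    len <- sum(ex$end - ex$start + 1L)
    add(id, exon_df(id, ex$chrom[1], ex$strand[1], ex$start, ex$end),
        seq_for(labs[k], len), "j", pick[k], labs[k])
  }

  # "o"/"x": two-exon transcript whose downstream exon overlaps the first
  # exon of a coding reference with enough upstream clearance
  ox_refs <- genes[genes$biotype == "protein_coding" & genes$upstream_gap >= 1000, ]
  pick <- sample(ox_refs$transcript_id, want[["o"]] + want[["x"]])
  labs <- label_for(want[["o"]] + want[["x"]])
  for (k in seq_along(pick)) {
    ex <- exons_by_tx[[pick[k]]]
    s <- min(ex$start)
    is_o <- k <= want[["o"]]
    strand <- if (is_o) ex$strand[1] else setdiff(c("+", "-"), ex$strand[1])
    id <- if (is_o) sprintf("ASM.O%03d", k) else sprintf("ASM.X%03d", k - want[["o"]])
    starts <- c(s - 400L, s - 50L); ends <- c(s - 200L, s + 80L)
    add(id, exon_df(id, ex$chrom[1], strand, starts, ends),
        seq_for(labs[k], sum(ends - starts + 1L)),
        if (is_o) "o" else "x", pick[k], labs[k])
  }

  # "i": two-exon transcript inside a long intron of a coding reference
  long_intron <- do.call(rbind, lapply(j_refs$transcript_id, function(t) {
    it <- intron_table(exons_by_tx[[t]]$start, exons_by_tx[[t]]$end)
    it <- it[it[, "end"] - it[, "start"] + 1L >= 400L, , drop = FALSE]
    if (nrow(it) == 0L) return(NULL)
    data.frame(transcript_id = t, start = it[1, "start"], end = it[1, "end"],
               stringsAsFactors = FALSE)
  }))
  pick <- long_intron[sample.int(nrow(long_intron), want[["i"]]), ]
  labs <- label_for(want[["i"]])
  for (k in seq_len(nrow(pick))) {
    ex <- exons_by_tx[[pick$transcript_id[k]]]
    a <- pick$start[k] + 5L
    starts <- c(a, a + 210L); ends <- c(a + 179L, a + 349L)
    id <- sprintf("ASM.I%03d", k)
    add(id, exon_df(id, ex$chrom[1], sample(c("+", "-"), 1L), starts, ends),
        seq_for(labs[k], sum(ends - starts + 1L)), "i",
        pick$transcript_id[k], labs[k])
  }

  # "u": intergenic two-exon transcripts placed midway between gene spans
  gaps <- genes[genes$upstream_gap >= 3000, , drop = FALSE]
  pick <- gaps[sample.int(nrow(gaps), want[["u"]]), ]
  labs <- label_for(want[["u"]])
  for (k in seq_len(nrow(pick))) {
    mid <- pick$start[k] - pick$upstream_gap[k] %/% 2L
    starts <- c(mid, mid + 230L); ends <- c(mid + 179L, mid + 369L)
    id <- sprintf("ASM.U%03d", k)
    add(id, exon_df(id, pick$chrom[k], sample(c("+", "-"), 1L), starts, ends),
        seq_for(labs[k], sum(ends - starts + 1L)), "u", NA_character_, labs[k])
  }

  # exact duplicates of noncoding "u" transcripts, removable by dedup
  tdf <- do.call(rbind, truth)
  u_non <- tdf$transcript_id[tdf$planted_code == "u" & tdf$coding_label == "noncoding"]
  dups <- utils::head(u_non, config$n_duplicates)
  for (k in seq_along(dups)) {
    src <- dups[k]
    ex <- out_rows[[which(vapply(out_rows, function(r) r$transcript_id[1], character(1)) == src)]]
    id <- paste0(src, ".dup")
    df <- ex; df$transcript_id <- id; df$gene_id <- id
    add(id, df, out_seq[[src]], "u", NA_character_, "noncoding", dup = TRUE)
  }

  truth <- do.call(rbind, truth)
  novel <- truth$transcript_id[truth$planted_code %in% c("j", "o", "x", "i", "u") &
                               truth$coding_label == "noncoding" &
                               !truth$is_duplicate]
  structure(list(models = validate_models(do.call(rbind, out_rows)),
                 sequences = out_seq, truth = truth,
                 novel_lncRNA_ids = novel),
            class = "sim_assembly")
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Baseline means are drawn log-uniformly; a fraction of features receives a
#' planted fold change in the treated group (sign equiprobable); planted cis
#' pairs share a per-sample lognormal latent factor so their expression
#' correlates; optionally one treated sample is drawn from an unrelated
#' baseline (outlier).
#'
#' @param features Character vector of feature ids.
#' @param config [sim_config()] object.
#' @param cis_pairs Optional `data.frame` with columns `lnc_gene`,
#'   `target_gene` (both must appear in `features`).
#' @return List with `counts` (a [count_matrix()]), `truth` (`data.frame`:
#'   `feature_id`, `true_lfc`) and `outlier_sample` (id or `NA`).
#' @export
simulate_counts <- function(features, config, cis_pairs = NULL) {
  stopifnot(length(features) > 0L)
  set.seed(config$seed + 3000L)
  m <- length(features)
  samples <- c(sprintf("CT%d", seq_len(config$n_control)),
               sprintf("TAM%d", seq_len(config$n_treated)))
  groups <- stats::setNames(rep(c("control", "treated"),
                                c(config$n_control, config$n_treated)), samples)
  lr <- config$mean_count_log_range
  mu0 <- exp(stats::runif(m, lr[1], lr[2]))
  true_lfc <- numeric(m)
  n_de <- round(config$frac_de * m)
  if (n_de > 0) {
    idx <- sample.int(m, n_de)
    true_lfc[idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$planted_lfc
  }
  mu <- matrix(mu0, m, length(samples), dimnames = list(features, samples))
  treated <- groups == "treated"
  mu[, treated] <- mu[, treated] * 2^true_lfc
  if (!is.null(cis_pairs) && nrow(cis_pairs) > 0L) {
    for (k in seq_len(nrow(cis_pairs))) {
      rows <- match(c(cis_pairs$lnc_gene[k], cis_pairs$target_gene[k]), features)
      if (anyNA(rows)) stop("cis pair feature absent from feature list")
      z <- stats::rlnorm(length(samples), -config$cis_latent_sdlog^2 / 2,
                         config$cis_latent_sdlog)
      mu[rows, ] <- mu[rows, ] * rep(z, each = 2L)
    }
  }
  outlier <- NA_character_
  if (isTRUE(config$outlier_sample)) {
    outlier <- samples[length(samples)]
    mu[, outlier] <- exp(stats::runif(m, lr[1], lr[2]))
  }
  counts <- matrix(as.integer(stats::rnbinom(m * length(samples),
                                             size = 1 / config$nb_dispersion,
                                             mu = mu)),
                   m, length(samples), dimnames = dimnames(mu))
  list(counts = count_matrix(counts, groups),
       truth = data.frame(feature_id = features, true_lfc = true_lfc,
                          stringsAsFactors = FALSE),
       outlier_sample = outlier)
}

#' Run the whole synthetic study
#'
#' Chains [simulate_reference()], [simulate_sequences()],
#' [simulate_assembly()] and [simulate_counts()] (counts at gene level over
#' the reference genes, cis pairs from the reference layout).
#'
#' @param config [sim_config()] object.
#' @param genome Generate chromosome sequences (see
#'   [simulate_reference()]).
#' @return List of class `sim_study` with elements `reference`, `ref_seqs`,
#'   `assembly`, `expression`, `config`.
#' @export
simulate_study <- function(config = sim_config(), genome = TRUE) {
  reference <- simulate_reference(config, genome = genome)
  ref_seqs <- simulate_sequences(reference, config)
  assembly <- simulate_assembly(reference, ref_seqs, config)
  expression <- simulate_counts(reference$genes$gene_id, config,
                                cis_pairs = reference$cis_pairs)
  structure(list(reference = reference, ref_seqs = ref_seqs,
                 assembly = assembly, expression = expression,
                 config = config),
            class = "sim_study")
}

#' Write all synthetic inputs and the ground truth to a directory
#'
#' @param study `sim_study` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  if (!is.null(study$reference$genome)) write_fasta(study$reference$genome, p("genome.fa"))
  write_gtf(study$reference$models, p("reference.gtf"))
  write_gtf(study$assembly$models, p("assembled.gtf"))
  write_fasta(study$assembly$sequences, p("assembled.fa"))
  lab <- study$ref_seqs$label
  write_fasta(study$ref_seqs$sequences[lab == "coding"], p("coding_train.fa"))
  write_fasta(study$ref_seqs$sequences[lab == "noncoding"], p("noncoding_train.fa"))
  write_count_table(study$expression$counts, p("counts.tsv"))
  groups_dt <- data.table::data.table(sample_id = names(study$expression$counts$groups),
                                      group = unname(study$expression$counts$groups))
  data.table::fwrite(groups_dt, p("groups.tsv"), sep = "\t", eol = "\n")
  gt <- list(
    coding_label = as.list(stats::setNames(study$assembly$truth$coding_label,
                                           study$assembly$truth$transcript_id)),
    planted_code = as.list(stats::setNames(study$assembly$truth$planted_code,
                                           study$assembly$truth$transcript_id)),
    novel_lncRNA_ids = study$assembly$novel_lncRNA_ids,
    de = study$expression$truth,
    cis_pairs = study$reference$cis_pairs,
    outlier_sample = study$expression$outlier_sample
  )
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}
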