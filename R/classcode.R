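# Class-code precedence, most informative first.
CLASS_CODE_ORDER <- c("=", "j", "o", "x", "i", "u")

#' Assign gffcompare-style class codes to assembled transcripts
#'
#' Each query transcript is compared with every reference transcript on the
#' same chromosome; a per-reference code is derived and the best code across
#' references is kept, by precedence `=` > `j` > `o` > `x` > `i` > `u`.
#'
#' Per-reference rules, first match wins:
#' \itemize{
#'   \item `=`: same strand, identical ordered intron chain; for a
#'     mono-exonic query against a mono-exonic reference, exonic overlap
#'     with both termini within 100 bp.
#'   \item `j`: same strand, at least one shared intron (identical
#'     donor/acceptor pair).
#'   \item `o`: same strand, any exonic base overlap.
#'   \item `x`: opposite strand, any exonic base overlap.
#'   \item `i`: all query exons within a single reference intron (any
#'     strand).
#'   \item residual span overlap without exonic overlap (e.g. a query
#'     straddling intron and flank) collapses to `o`/`x` by strand.
#' }
#' A query with no per-reference code is `u` (intergenic).
#'
#' @param query_models,reference_models Transcript-model tables
#'   ([read_gtf()] layout).
#' @param mono_exon_tol Terminus tolerance (bp) for mono-exonic `=`
#'   (default 100).
#' @return `data.frame` with `transcript_id`, `code`,
#'   `matched_reference_id` (NA for `u`).
#' @export
assign_class_codes <- function(query_models, reference_models, mono_exon_tol = 100) {
  qs <- split(query_models, query_models$transcript_id)
  ref_list <- split(reference_models, reference_models$transcript_id)
  ref_chrom <- vapply(ref_list, function(r) r$chrom[1], character(1))
  out <- lapply(unique(query_models$transcript_id), function(qid) {
    q <- qs[[qid]]
    refs <- ref_list[ref_chrom == q$chrom[1]]
    res <- classify_one(q, refs, mono_exon_tol)
    data.frame(transcript_id = qid, code = res$code,
               matched_reference_id = res$ref, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

classify_one <- function(q, refs, mono_exon_tol) {
  qstart <- sort(q$start); qend <- sort(q$end)
  qintrons <- intron_table(q$start, q$end)
  best_code <- "u"; best_ref <- NA_character_
  rank <- function(code) match(code, CLASS_CODE_ORDER)
  for (rid in names(refs)) {
    r <- refs[[rid]]
    code <- pair_code(qstart, qend, qintrons, q$strand[1],
                      sort(r$start), sort(r$end),
                      intron_table(r$start, r$end), r$strand[1],
                      mono_exon_tol)
    if (!is.na(code) && rank(code) < rank(best_code)) {
      best_code <- code
      best_ref <- rid
    }
  }
  if (best_code == "u") best_ref <- NA_character_
  list(code = best_code, ref = best_ref)
}

# Code of one query against one reference transcript; NA when unrelated.
pair_code <- function(qs, qe, qint, qstrand, rs, re, rint, rstrand, tol) {
  same <- qstrand == rstrand
  exon_overlap <- any(outer(qs, re, "<=") & outer(qe, rs, ">="))
  if (same) {
    if (nrow(qint) == 0L && nrow(rint) == 0L) {
      if (exon_overlap && abs(qs[1] - rs[1]) <= tol && abs(qe[1] - re[1]) <= tol) {
        return("=")
      }
    } else if (nrow(qint) > 0L && nrow(rint) > 0L &&
               nrow(qint) == nrow(rint) && all(qint == rint)) {
      return("=")
    }
    if (nrow(qint) > 0L && nrow(rint) > 0L) {
      shared <- merge(as.data.frame(qint), as.data.frame(rint))
      if (nrow(shared) > 0L) return("j")
    }
    if (exon_overlap) return("o")
  } else if (exon_overlap) {
    return("x")
  }
  # intronic containment: all query exons inside one reference intron
  if (nrow(rint) > 0L) {
    for (k in seq_len(nrow(rint))) {
      if (all(qs >= rint[k, "start"] & qe <= rint[k, "end"])) return("i")
    }
  }
  # residual span overlap (within the locus but touching no exon wholly
  # inside one intron) collapses to the nearest overlap code
  if (qs[1] <= max(re) && qe[length(qe)] >= min(rs)) {
    return(if (same) "o" else "x")
  }
  NA_character_
}

#' Partition class-coded transcripts into novel candidates and exact matches
#'
#' Transcripts whose code is in `retained` become novel-lncRNA candidates;
#' `=` transcripts are routed to the annotated-lncRNA resolution instead.
#'
#' @param code_results Output of [assign_class_codes()].
#' @param retained Codes kept as novel candidates (default x, o, i, u, j).
#' @return List with `candidates` (ids), `equals` (ids with code `=`).
#' @export
filter_by_class <- function(code_results, retained = c("x", "o", "i", "u", "j")) {
  list(candidates = code_results$transcript_id[code_results$code %in% retained],
       equals = code_results$transcript_id[code_results$code == "="])
}

#' Resolve `=` transcripts into annotated lncRNAs and known transcripts
#'
#' An exact match (`=`) to a reference transcript of biotype `lncRNA` is an
#' already-annotated lncRNA; exact matches to protein-coding (or other)
#' reference transcripts are removed.
#'
#' @param code_results Output of [assign_class_codes()].
#' @param reference_models Reference transcript-model table with biotypes.
#' @return List with `annotated_lncRNAs` (ids) and `removal_log`.
#' @export
split_annotated_lncRNAs <- function(code_results, reference_models) {
  eq <- code_results[code_results$code == "=", , drop = FALSE]
  spans <- transcript_spans(reference_models)
  biotype <- spans$biotype[match(eq$matched_reference_id, spans$transcript_id)]
  ann <- eq$transcript_id[biotype == "lncRNA"]
  rm_mrna <- eq$transcript_id[biotype == "protein_coding"]
  rm_other <- eq$transcript_id[!biotype %in% c("lncRNA", "protein_coding")]
  list(
    annotated_lncRNAs = ann,
    removal_log = rbind(
      removal_log_entries(rm_mrna, "annotated_split", "known_mRNA"),
      removal_log_entries(rm_other, "annotated_split", "known_non_lncRNA")
    )
  )
}

#' Structural lncRNA filter on length and exon count
#'
#' Retains candidates with spliced length >= `min_length` nt and at least
#' `min_exons` exons.
#'
#' @param models Transcript-model table covering the candidates.
#' @param candidates Ids to filter.
#' @param min_length Minimum mature length in nt (default 200).
#' @param min_exons Minimum exon count (default 2).
#' @return List with `retained` and `removal_log`.
#' @export
structural_filter <- function(models, candidates, min_length = 200, min_exons = 2) {
  lens <- transcript_lengths(models)[candidates]
  nex <- exon_counts(models)[candidates]
  if (anyNA(lens)) stop("candidate(s) missing from models: ",
                        paste(candidates[is.na(lens)], collapse = ", "))
  short <- candidates[lens < min_length]
  few <- candidates[lens >= min_length & nex < min_exons]
  list(
    retained = candidates[lens >= min_length & nex >= min_exons],
    removal_log = rbind(
      removal_log_entries(short, "structural", sprintf("length_lt_%d", min_length)),
      removal_log_entries(few, "structural", sprintf("exons_lt_%d", min_exons))
    )
  )
}

#' Remove transcripts with byte-identical sequences
#'
#' Among records sharing a sequence, the lexicographically smallest id is
#' kept; the rest are logged as duplicates of it.
#'
#' @param seqs Named character vector of canonicalized sequences.
#' @return List with `retained` (names, input order), `removal_log`.
#' @export
deduplicate <- function(seqs) {
  ids <- names(seqs)
  keep_of <- tapply(ids, seqs, function(v) min(v))
  kept_id <- unname(keep_of[seqs])
  dup <- ids != kept_id
  list(
    retained = ids[!dup],
    removal_log = removal_log_entries(ids[dup], "dedup",
                                      paste0("duplicate_of:", kept_id[dup]))
  )
}

#' Run the full candidate-retention cascade
#'
#' Applies, in order: class-code filter, annotated-lncRNA resolution,
#' structural filter (length/exon count) and sequence deduplication. The
#' result is a partition: every query transcript lands in exactly one of
#' `novel_candidates`, `annotated_lncRNAs` or `removal_log`.
#'
#' @param query_models Assembled transcript-model table.
#' @param query_seqs Named character vector of assembled transcript
#'   sequences.
#' @param reference_models Reference transcript-model table.
#' @param min_length,min_exons Structural thresholds (defaults 200 nt, 2).
#' @param mono_exon_tol See [assign_class_codes()].
#' @return List of class `candidate_set`: `novel_candidates`,
#'   `annotated_lncRNAs`, `removal_log`, `codes`.
#' @export
filter_cascade <- function(query_models, query_seqs, reference_models,
                           min_length = 200, min_exons = 2, mono_exon_tol = 100) {
  codes <- assign_class_codes(query_models, reference_models, mono_exon_tol)
  cls <- filter_by_class(codes)
  ann <- split_annotated_lncRNAs(codes, reference_models)
  str <- structural_filter(query_models, cls$candidates, min_length, min_exons)
  missing_seq <- setdiff(str$retained, names(query_seqs))
  if (length(missing_seq) > 0L) {
    stop("no sequence for candidate(s): ", paste(missing_seq, collapse = ", "))
  }
  ddp <- deduplicate(query_seqs[str$retained])
  structure(list(
    novel_candidates = ddp$retained,
    annotated_lncRNAs = ann$annotated_lncRNAs,
    removal_log = rbind(ann$removal_log, str$removal_log, ddp$removal_log),
    codes = codes
  ), class = "candidate_set")
}
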