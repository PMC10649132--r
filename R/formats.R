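#' @keywords internal
"_PACKAGE"

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are canonicalized to uppercase; wrapped sequence lines are
#' concatenated. Records must have unique, non-empty identifiers and contain
#' only A, C, G, T or N after canonicalization.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences; names are record
#'   ids, order as in the file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-alphabet character '%s' in sequence '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param line_width Sequence line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), line_width >= 1)
  con <- file(path, open = "wb")  # "wb" forces UNIX newlines on all platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = line_width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + line_width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Parses exon features of a GTF2.2 file (1-based inclusive coordinates) into
#' a transcript-model table: one row per exon, exons grouped by transcript and
#' sorted by start. The biotype is taken from the `gene_biotype` or
#' `transcript_biotype` attribute and collapsed to one of `protein_coding`,
#' `lncRNA` or `other`.
#'
#' @param path Path to a GTF file.
#' @return A `data.frame` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype` (one row per exon).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  mc <- S4Vectors::mcols(gr)
  tx <- as.character(mc$transcript_id)
  if (is.null(tx) || anyNA(tx)) stop("exon feature without transcript_id in ", path)
  gene <- as.character(mc$gene_id)
  if (is.null(gene)) gene <- tx
  biotype <- rep(NA_character_, length(gr))
  if (!is.null(mc$gene_biotype)) biotype <- as.character(mc$gene_biotype)
  if (!is.null(mc$transcript_biotype)) {
    tb <- as.character(mc$transcript_biotype)
    biotype <- ifelse(is.na(biotype), tb, biotype)
  }
  biotype[is.na(biotype)] <- "other"
  biotype[!biotype %in% c("protein_coding", "lncRNA")] <- "other"
  df <- data.frame(
    transcript_id = tx,
    gene_id = gene,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  validate_models(df, path)
}

# Shared invariants for transcript-model tables, whether parsed or simulated.
validate_models <- function(df, what = "transcript models") {
  if (any(df$start < 1L)) {
    stop("exon with start < 1 (coordinates are 1-based) in ", what)
  }
  if (any(df$end < df$start)) stop("exon with start > end in ", what)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("exon with missing/invalid strand in ", what)
  }
  sp <- split(seq_len(nrow(df)), df$transcript_id)
  for (idx in sp) {
    if (length(unique(df$chrom[idx])) > 1L) {
      stop("exons of transcript '", df$transcript_id[idx[1]],
           "' on multiple chromosomes")
    }
    if (length(unique(df$strand[idx])) > 1L) {
      stop("exons of transcript '", df$transcript_id[idx[1]],
           "' on multiple strands")
    }
    o <- idx[order(df$start[idx])]
    if (length(o) > 1L && any(df$start[o][-1] <= df$end[o][-length(o)])) {
      stop("overlapping exons in transcript '", df$transcript_id[idx[1]], "'")
    }
  }
  ord <- order(match(df$transcript_id, unique(df$transcript_id)), df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: emits one `exon` line per row with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes, UNIX newlines.
#'
#' @param models Transcript-model `data.frame` as returned by [read_gtf()].
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "lncpipe") {
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_biotype \"%s\";",
    models$chrom, source, models$start, models$end, models$strand,
    models$gene_id, models$transcript_id, models$biotype)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a raw count table
#'
#' @param path TSV file: first column feature ids, remaining columns one per
#'   sample with sample ids in the header.
#' @param group_map Named character vector mapping sample id to group
#'   (`control` or `treated`).
#' @return A list of class `count_matrix` with elements `counts` (integer
#'   matrix, features x samples) and `groups` (named character vector).
#' @export
read_count_table <- function(path, group_map) {
  if (!file.exists(path)) stop("count table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(dt) < 2L) stop("count table needs a feature column plus >= 1 sample")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) stop("duplicate feature id in count table")
  samples <- colnames(dt)[-1L]
  vals <- as.matrix(dt[, -1L, with = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) stop("non-numeric count cell in ", path)
  if (any(num < 0)) stop("negative count in ", path)
  if (any(num != floor(num))) stop("non-integer count in ", path)
  counts <- matrix(as.integer(num), nrow = length(ids),
                   dimnames = list(ids, samples))
  count_matrix(counts, group_map)
}

#' Construct a count matrix with sample group labels
#'
#' @param counts Non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param groups Named character vector (`control`/`treated`) covering every
#'   column of `counts`.
#' @return `count_matrix` object.
#' @export
count_matrix <- function(counts, groups) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing) > 0L) {
    stop("sample(s) missing from group map: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(counts)]
  if (any(!groups %in% c("control", "treated"))) {
    stop("groups must be 'control' or 'treated'")
  }
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' Write a count matrix to TSV
#'
#' @param cm `count_matrix` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(cm, path) {
  dt <- data.table::data.table(feature_id = rownames(cm$counts))
  for (s in colnames(cm$counts)) dt[[s]] <- cm$counts[, s]
  data.table::fwrite(dt, path, sep = "\t", eol = "\n")
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the 12 standard columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Subject sequences are
#' classified via `subject_class_map`; subjects absent from the map are
#' treated as `coding_or_other`.
#'
#' @param path Path to the hit table (may be empty).
#' @param subject_class_map Named character vector: subject id ->
#'   `coding_or_other` or `lncRNA`.
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `subject_class`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path, subject_class_map = character()) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      subject_class = character(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L)) {
    stop("malformed hit table row (expected 12 columns, got ",
         ncols[which(ncols != 12L)[1L]], ")")
  }
  m <- do.call(rbind, fields)
  evalue <- suppressWarnings(as.numeric(m[, 11L]))
  bitscore <- suppressWarnings(as.numeric(m[, 12L]))
  if (anyNA(evalue) || anyNA(bitscore)) stop("unparseable evalue/bitscore in ", path)
  if (any(evalue < 0)) stop("negative evalue in ", path)
  cls <- unname(subject_class_map[m[, 2L]])
  cls[is.na(cls)] <- "coding_or_other"
  if (any(!cls %in% c("coding_or_other", "lncRNA"))) {
    stop("subject_class_map values must be 'coding_or_other' or 'lncRNA'")
  }
  data.frame(query_id = m[, 1L], subject_id = m[, 2L], subject_class = cls,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

# ---- transcript-model helpers used across modules ----

#' Spliced transcript lengths
#' @param models Transcript-model table.
#' @return Named integer vector, one entry per transcript.
#' @export
transcript_lengths <- function(models) {
  len <- models$end - models$start + 1L
  vapply(split(len, models$transcript_id), sum, integer(1))[unique(models$transcript_id)]
}

#' Exon counts per transcript
#' @param models Transcript-model table.
#' @return Named integer vector.
#' @export
exon_counts <- function(models) {
  tab <- table(models$transcript_id)
  structure(as.integer(tab), names = names(tab))[unique(models$transcript_id)]
}

# One row per transcript: chrom, strand, span start/end, gene, biotype.
transcript_spans <- function(models) {
  sp <- split(seq_len(nrow(models)), models$transcript_id)
  ids <- names(sp)
  out <- data.frame(
    transcript_id = ids,
    gene_id = vapply(sp, function(i) models$gene_id[i[1]], character(1)),
    chrom = vapply(sp, function(i) models$chrom[i[1]], character(1)),
    strand = vapply(sp, function(i) models$strand[i[1]], character(1)),
    start = vapply(sp, function(i) min(models$start[i]), integer(1)),
    end = vapply(sp, function(i) max(models$end[i]), integer(1)),
    biotype = vapply(sp, function(i) models$biotype[i[1]], character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[match(unique(models$transcript_id), out$transcript_id), , drop = FALSE]
}

# Introns of one transcript given its sorted exon starts/ends; matrix with
# columns start,end (empty for mono-exonic transcripts).
intron_table <- function(starts, ends) {
  if (length(starts) < 2L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  cbind(start = ends[-length(ends)] + 1L, end = starts[-1L] - 1L)
}
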