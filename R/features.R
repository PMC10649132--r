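#' Build a hexamer usage-bias table
#'
#' Counts in-frame-agnostic sliding hexamers (step 1) in a coding and a
#' noncoding sequence set and returns, per hexamer h, the log-likelihood
#' ratio `log((c_cod(h)+a)/(N_cod+4096a)) - log((c_non(h)+a)/(N_non+4096a))`
#' with pseudocount a. Windows containing N contribute to neither table.
#'
#' @param coding_seqs,noncoding_seqs Named character vectors of sequences.
#' @param pseudocount Additive smoothing constant (default 1).
#' @return Named numeric vector of length 4096 (all DNA hexamers).
#' @export
build_hexamer_table <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L) {
    stop("both sequence sets must be non-empty")
  }
  count_set <- function(seqs) {
    set <- Biostrings::DNAStringSet(seqs)
    counts <- colSums(Biostrings::oligonucleotideFrequency(set, width = 6, step = 1))
    if (sum(counts) == 0) stop("sequence set has no countable hexamers")
    counts
  }
  ccod <- count_set(coding_seqs)
  cnon <- count_set(noncoding_seqs)
  tab <- log((ccod + pseudocount) / (sum(ccod) + 4096 * pseudocount)) -
    log((cnon + pseudocount) / (sum(cnon) + 4096 * pseudocount))
  tab
}

#' Mean hexamer log-likelihood-ratio score of a sequence
#'
#' @param seq Uppercase nucleotide sequence.
#' @param table Hexamer table from [build_hexamer_table()].
#' @return Mean table entry over all sliding hexamer windows of `seq`
#'   (N-containing windows skipped); 0 with a warning when the sequence is
#'   shorter than 6 nt or has no valid window.
#' @export
hexamer_score <- function(seq, table) {
  if (nchar(seq) < 6L) {
    warning("sequence shorter than 6 nt; hexamer score set to 0")
    return(0)
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = 6)
  total <- sum(counts)
  if (total == 0) return(0)
  sum(counts * table[names(counts)]) / total
}

#' Extract the coding-potential feature vector of a sequence
#'
#' Six features: longest sense-ORF length (nt), ORF coverage (fraction of
#' the transcript), Fickett TESTCODE score, hexamer usage-bias score, GC
#' fraction (N ignored) and natural-log transcript length.
#'
#' @param seq Uppercase nucleotide sequence.
#' @param hexamer_table Table from [build_hexamer_table()].
#' @return Named numeric vector with elements `orf_length`, `orf_coverage`,
#'   `fickett`, `hexamer`, `gc`, `log_length`.
#' @export
extract_features <- function(seq, hexamer_table) {
  n <- nchar(seq)
  orf <- find_longest_orf(seq)
  orf_len <- if (is.null(orf)) 0 else orf$length
  base <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))[c("A", "C", "G", "T")]
  acgt <- sum(base)
  c(orf_length = orf_len,
    orf_coverage = orf_len / n,
    fickett = fickett_score(seq),
    hexamer = suppressWarnings(hexamer_score(seq, hexamer_table)),
    gc = if (acgt > 0) unname((base[["C"]] + base[["G"]]) / acgt) else 0,
    log_length = log(n))
}

FEATURE_NAMES <- c("orf_length", "orf_coverage", "fickett", "hexamer", "gc", "log_length")

#' Feature matrix for a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param hexamer_table Table from [build_hexamer_table()].
#' @return `data.frame`, one row per sequence (rownames = ids), columns in
#'   the fixed order used by the classifier.
#' @export
feature_matrix <- function(seqs, hexamer_table) {
  m <- t(vapply(seqs, extract_features, numeric(6), hexamer_table = hexamer_table))
  df <- as.data.frame(m)
  colnames(df) <- FEATURE_NAMES
  df
}
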