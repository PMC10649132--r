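STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame on the sense strand
#'
#' Scans all three forward frames for spans starting at ATG and ending at the
#' first in-frame stop codon (TAA/TAG/TGA, included in the length). An ATG
#' with no downstream in-frame stop yields an open-ended ORF running to the
#' last complete codon (`has_stop = FALSE`), as assembled transcripts may be
#' 3'-truncated. Codons containing N never match ATG or a stop. Ties on
#' length are broken by the smallest start.
#'
#' @param seq Uppercase nucleotide sequence (single string).
#' @return `NULL` when no ORF exists, else a list with `start` (0-based
#'   offset of the A of ATG), `length` (nt, multiple of 3), `frame` (0/1/2)
#'   and `has_stop`.
#' @export
find_longest_orf <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(NULL)
  best <- NULL
  for (frame in 0:2) {
    starts_nt <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(starts_nt) == 0L) next
    codons <- substring(seq, starts_nt, starts_nt + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stp <- which(codons %in% STOP_CODONS)
    # index (in codon units) of the first stop at or after each ATG
    nxt <- findInterval(atg - 0.5, stp) + 1L
    has_stop <- nxt <= length(stp)
    end_codon <- ifelse(has_stop, stp[pmin(nxt, length(stp))], length(codons))
    len <- (end_codon - atg + 1L) * 3L
    i <- which.max(len)  # first max = smallest start within frame
    cand <- list(start = starts_nt[atg[i]] - 1L, length = len[i],
                 frame = frame, has_stop = has_stop[i])
    if (is.null(best) ||
        cand$length > best$length ||
        (cand$length == best$length && cand$start < best$start)) {
      best <- cand
    }
  }
  best
}

#' Longest-ORF length for a set of sequences
#' @param seqs Named character vector of sequences.
#' @return Named integer vector (0 when no ORF).
#' @export
longest_orf_lengths <- function(seqs) {
  vapply(seqs, function(s) {
    orf <- find_longest_orf(s)
    if (is.null(orf)) 0L else orf$length
  }, integer(1))
}

#' Remove candidates whose longest ORF indicates coding capacity
#'
#' Transcripts whose longest sense-strand ORF reaches `threshold` nt are
#' removed as putatively protein-coding; transcripts with a shorter ORF or no
#' ORF at all are retained as lncRNA candidates.
#'
#' @param seqs Named character vector of candidate sequences.
#' @param threshold Minimum ORF length (nt) that triggers removal
#'   (default 300, i.e. 100 aa).
#' @return List with `retained` (ids), `removal_log` (`data.frame` with
#'   columns `transcript_id`, `stage`, `reason`) and `orf_length` (named
#'   integer vector).
#' @export
orf_filter <- function(seqs, threshold = 300) {
  lens <- longest_orf_lengths(seqs)
  removed <- names(lens)[lens >= threshold]
  list(
    retained = names(lens)[lens < threshold],
    removal_log = removal_log_entries(removed, "orf_filter",
                                      sprintf("orf_ge_%d", threshold)),
    orf_length = lens
  )
}

removal_log_entries <- function(ids, stage, reason) {
  data.frame(transcript_id = as.character(ids),
             stage = rep_len(stage, length(ids)),
             reason = rep_len(reason, length(ids)),
             stringsAsFactors = FALSE)
}
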