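# TESTCODE lookup tables (Fickett 1982, Nucleic Acids Res 10:5303-5318).
# For each base, ten probability bins indexed by the position parameter
# (boundaries 1.9, 1.8, ..., 1.1, 0) or the composition parameter
# (boundaries 0.33, 0.31, ..., 0.17, 0), plus one weight per parameter.

FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_POSITION_BOUNDS <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)

FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
FICKETT_CONTENT_BOUNDS <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)

fickett_lookup <- function(value, bounds, probs) {
  probs[which(value >= bounds)[1L]]
}

#' Fickett TESTCODE coding-potential score
#'
#' Combines, for each of the four bases, a position parameter (asymmetry of
#' the base across the three codon positions, `max/(min + 1)`) and a
#' composition parameter (base fraction) through the published TESTCODE
#' lookup tables, weighted by each parameter's discriminative value. N bases
#' are ignored in all counts. Higher scores indicate coding-like periodicity
#' and composition.
#'
#' @param seq Uppercase nucleotide sequence; sensible from ~200 nt.
#' @return Scalar score in roughly \[0.16, 1.55\].
#' @export
fickett_score <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) stop("fickett_score: empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  phase <- rep_len(1:3, n)
  score <- 0
  total <- sum(chars %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    hits <- chars == b
    pos_counts <- vapply(1:3, function(p) sum(hits & phase == p), numeric(1))
    pos_param <- max(pos_counts) / (min(pos_counts) + 1)
    content <- if (total > 0) sum(hits) / total else 0
    score <- score +
      fickett_lookup(pos_param, FICKETT_POSITION_BOUNDS, FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(content, FICKETT_CONTENT_BOUNDS, FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}
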