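# Independent oracles: brute-force implementations used only to check the
# package's optimized code paths. They share the documented rules but none of
# the implementation machinery (per-base membership vectors instead of
# interval arithmetic, explicit scans instead of vectorized lookups).

# --- class codes, per-base membership logic ---------------------------------
# q / refs: list(starts, ends, strand); refs is a named list.
oracle_class_code <- function(q, refs, tol = 100) {
  ord <- c("=", "j", "o", "x", "i", "u")
  intron_keys <- function(starts, ends) {
    if (length(starts) < 2L) return(character(0))
    o <- order(starts)
    paste(ends[o][-length(ends)] + 1L, starts[o][-1L] - 1L)
  }
  qbases <- unlist(mapply(seq.int, q$starts, q$ends, SIMPLIFY = FALSE))
  qspan <- seq.int(min(q$starts), max(q$ends))
  qint <- intron_keys(q$starts, q$ends)
  best <- "u"
  for (rid in names(refs)) {
    r <- refs[[rid]]
    rbases <- unlist(mapply(seq.int, r$starts, r$ends, SIMPLIFY = FALSE))
    rspan <- seq.int(min(r$starts), max(r$ends))
    rint <- intron_keys(r$starts, r$ends)
    same <- q$strand == r$strand
    ex_ov <- length(intersect(qbases, rbases)) > 0L
    code <- NA_character_
    if (same && length(qint) == 0L && length(rint) == 0L && ex_ov &&
        abs(min(q$starts) - min(r$starts)) <= tol &&
        abs(max(q$ends) - max(r$ends)) <= tol) {
      code <- "="
    } else if (same && length(qint) > 0L && length(qint) == length(rint) &&
               all(qint == rint)) {
      code <- "="
    } else if (same && length(intersect(qint, rint)) > 0L) {
      code <- "j"
    } else if (same && ex_ov) {
      code <- "o"
    } else if (!same && ex_ov) {
      code <- "x"
    } else {
      contained <- FALSE
      for (iv in rint) {
        ab <- as.integer(strsplit(iv, " ", fixed = TRUE)[[1L]])
        if (all(qbases >= ab[1] & qbases <= ab[2])) { contained <- TRUE; break }
      }
      if (contained) {
        code <- "i"
      } else if (length(intersect(qspan, rspan)) > 0L) {
        code <- if (same) "o" else "x"
      }
    }
    if (!is.na(code) && match(code, ord) < match(best, ord)) best <- code
  }
  best
}

# random small locus: <= 5 reference transcripts plus one query on one strand
# system; returns a list consumable by both assign_class_codes and the oracle
random_locus <- function() {
  rand_tx <- function() {
    n_ex <- sample(1:4, 1L)
    s <- sample(1:4000, 1L)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- s
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + sample(20:200, 1L)
      pos <- ends[i] + 1L + sample(20:300, 1L)
    }
    list(starts = starts, ends = ends, strand = sample(c("+", "-"), 1L))
  }
  n_ref <- sample(1:5, 1L)
  refs <- stats::setNames(lapply(seq_len(n_ref), function(i) rand_tx()),
                          sprintf("R%02d", seq_len(n_ref)))
  list(query = rand_tx(), refs = refs)
}

locus_to_models <- function(tx, id, biotype = "other") {
  data.frame(transcript_id = id, gene_id = id, chrom = "chr1",
             strand = tx$strand, start = tx$starts, end = tx$ends,
             biotype = biotype, stringsAsFactors = FALSE)
}

# --- longest ORF, explicit per-ATG scan -------------------------------------
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(NULL)
  atgs <- which(vapply(seq_len(n - 2L),
                       function(i) substr(seq, i, i + 2L) == "ATG", logical(1)))
  best <- NULL
  for (a in atgs) {
    j <- a + 3L
    len <- NA_integer_; stopped <- FALSE
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% c("TAA", "TAG", "TGA")) {
        len <- j + 2L - a + 1L; stopped <- TRUE; break
      }
      j <- j + 3L
    }
    if (!stopped) len <- 3L * ((n - a + 1L) %/% 3L)
    if (is.null(best) || len > best$length ||
        (len == best$length && a - 1L < best$start)) {
      best <- list(start = a - 1L, length = len, frame = (a - 1L) %% 3L,
                   has_stop = stopped)
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# --- Fickett TESTCODE, independent ladder lookup ----------------------------
oracle_fickett <- function(seq) {
  probs <- rbind(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  cprobs <- rbind(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  pw <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  cw <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  ch <- strsplit(seq, "")[[1L]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(p) {
      if (p > length(ch)) 0L else sum(ch[seq(p, length(ch), by = 3L)] == b)
    }, integer(1))
    posv <- max(cnt) / (min(cnt) + 1)
    pos_bin <- if (posv >= 1.9) 1 else if (posv >= 1.8) 2 else if (posv >= 1.7) 3 else
      if (posv >= 1.6) 4 else if (posv >= 1.5) 5 else if (posv >= 1.4) 6 else
      if (posv >= 1.3) 7 else if (posv >= 1.2) 8 else if (posv >= 1.1) 9 else 10
    comp <- sum(ch == b) / sum(ch %in% c("A", "C", "G", "T"))
    comp_bin <- if (comp >= 0.33) 1 else if (comp >= 0.31) 2 else if (comp >= 0.29) 3 else
      if (comp >= 0.27) 4 else if (comp >= 0.25) 5 else if (comp >= 0.23) 6 else
      if (comp >= 0.21) 7 else if (comp >= 0.19) 8 else if (comp >= 0.17) 9 else 10
    total <- total + probs[b, pos_bin] * pw[[b]] + cprobs[b, comp_bin] * cw[[b]]
  }
  unname(total)
}

# --- Benjamini-Hochberg step-up, literal definition -------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- vapply(seq_len(m),
                function(k) min(m * p[o][k:m] / (k:m)),
                numeric(1))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- hypergeometric upper tail by exhaustive enumeration (N <= 12) ----------
oracle_hyper_enum <- function(universe, term, n_hits, k_obs) {
  sets <- utils::combn(universe, n_hits, simplify = FALSE)
  mean(vapply(sets, function(s) length(intersect(s, term)) >= k_obs, logical(1)))
}

# small helper: empty temp hit table path
empty_hits <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}
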