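---
title: "lncpipe: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncpipe: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models each
stage implements, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be made.

## The problem

Bulk RNA-seq of a treated-vs-control design yields, after assembly, a mixed
bag of transcript models: re-discovered known mRNAs, known lncRNAs, novel
isoforms, and noise. The pipeline answers three questions in sequence:
*which assembled transcripts are lncRNAs* (annotated or novel), *which
genes and lncRNAs respond to the treatment*, and *which responding genes
are plausibly regulated by the responding lncRNAs*. The reference design
throughout is four control versus three treated biological replicates — a
deliberately small study in which calibration and honest uncertainty
matter more than asymptotics.

## Class codes and the retention cascade

`assign_class_codes()` compares each query transcript against every
reference transcript on its chromosome and keeps the most informative
relationship, with precedence `=` > `j` > `o` > `x` > `i` > `u`:

* `=`: same strand and identical ordered intron chain. Intron-chain
  equality is undefined for mono-exonic transcripts, so a mono-exonic
  query matches a mono-exonic reference when they overlap and both termini
  agree within 100 bp. The tolerance must exist and must be explicit;
  100 bp is of the order of assembler end-imprecision.
* `j`: same strand, at least one shared intron (exact donor and acceptor).
* `o` / `x`: any exonic base overlap on the same / opposite strand.
* `i`: all exons inside a single reference intron, any strand.
* `u`: no overlap with any reference exon or intron (intergenic).

A residual geometry exists — a query overlapping a reference span without
touching an exon and without being contained in one intron (for example,
one exon in an intron and one beyond the locus). Such cases collapse to
`o`/`x` by strand: they are "overlapping the locus" in every practical
sense, and finer sub-codes would not change retention. The test suite
checks the implementation against a brute-force oracle that classifies by
per-base membership vectors rather than interval arithmetic.

Retention follows the lncRNA-discovery convention: codes `x, o, i, u, j`
become novel candidates; `=` matches are annotated lncRNAs when the
matched reference has biotype `lncRNA` and are otherwise discarded as
known mRNAs (or known non-lncRNA transcripts). The structural filter then
keeps candidates with **mature (spliced) length ≥ 200 nt** — the lncRNA
definition applies to the RNA, not the genomic span — **and ≥ 2 exons**;
byte-identical sequences are deduplicated, keeping the lexicographically
smallest identifier so reruns are stable.

## Coding potential

The ORF filter removes candidates whose longest sense-strand ORF is
**≥ 300 nt (100 aa)**. The scan covers the three forward frames only
(assembled transcripts are stranded); an ATG with no downstream in-frame
stop yields an open-ended ORF (`has_stop = FALSE`) because assembled
transcripts can be 3'-truncated, and codons containing N match nothing.
The direction of this filter deserves a note: the filter's purpose is to
remove transcripts with *protein-coding capacity*, so long-ORF transcripts
are the ones removed; a filter in the opposite direction would discard
every plausible lncRNA.

Surviving candidates are scored with six features:

| feature | definition | default-relevant notes |
|---|---|---|
| `orf_length` | longest sense ORF, nt | 0 when no ORF |
| `orf_coverage` | `orf_length` / transcript length | in [0,1] |
| `fickett` | TESTCODE statistic | published position/composition lookup tables |
| `hexamer` | mean log((c_cod+1)/N_cod) − log((c_non+1)/N_non) over sliding 6-mers | pseudocount 1; N-windows skipped |
| `gc` | GC fraction | N ignored |
| `log_length` | natural-log length | scale feature |

Secondary-structure features were deliberately excluded: they require an
external folding engine, and on desk-scale data the six features above
carry the discriminative signal (ORF length/coverage alone nearly separate
the classes when coding sequences carry real ORFs).

The classifier is a random forest trained with a stratified 80/20
train/held-out split, then stratified 10-fold cross-validation on the
training portion over a small grid — `ntree ∈ {100, 300}`,
`nodesize ∈ {1, 5}`, class-weighted by inverse class frequency — selected
by mean CV F1 for the noncoding class and refit on all training data.
(`nodesize` is the forest's complexity knob here; the implementation has
no per-tree depth parameter.) All randomness flows from one seed, so
training is exactly reproducible. Transcripts with predicted coding
probability ≥ 0.5 are removed.

Homology triage is pluggable: the pipeline consumes a BLAST outfmt-6 hit
table and applies the three-group rule at E ≤ 1e-5 — any significant hit
to a coding/other subject removes the candidate; significant hits only to
lncRNA subjects, or no hits, keep it. When no hit table is supplied the
stage passes everything through (group 3), which is the correct behaviour
for a fully synthetic study with no database to search.

## Differential expression

The DE stage is a self-contained simplified negative-binomial Wald
pipeline — deliberately *not* a call into an external DE package, and not
expected to reproduce one numerically (no trend-fitted dispersion, no LFC
shrinkage, no independent filtering). Its validation is by simulation:
type-I error calibration and power/FDR against planted effects.

* **Size factors** are median-of-ratios: per-feature geometric means over
  samples (features containing zeros excluded), per-sample median of
  count/geomean ratios, rescaled to geometric mean 1.
* **Dispersion** is method-of-moments per feature,
  α = max(0, (s² − μ)/μ²), from the within-group pooled variance of
  normalized counts. With 4 + 3 samples this estimator is extremely noisy,
  and chance *under*-estimates translate directly into understated
  standard errors and excess false positives. Shrinkage is therefore
  asymmetric: estimates below the 10%-trimmed mean of all per-feature
  estimates are raised to that common value; estimates above keep their
  own value. A symmetric 50/50 blend toward the common value was measured
  on null simulations and left the empirical type-I error at nominal 0.05
  in the 0.06–0.074 range across seeds; the asymmetric floor brings it to
  0.038–0.049 while planted-effect sensitivity stays above 0.9. Features
  with zero moment estimate are floored at 1e-8.
* **Wald test**: group means on normalized counts with a moderating
  constant of 0.5 on both sides — log2FC = log2((μ_t + ½)/(μ_c + ½)) —
  which keeps low-count fold changes finite and mildly biased toward the
  null; the standard error follows from Var(K) = μ + αμ² by the delta
  method, and the statistic is referred to a standard normal. With the
  floor-shrunk dispersions, the normal reference is empirically calibrated
  at this design size.
* **Multiple testing** is Benjamini–Hochberg, applied separately to the
  gene table and the lncRNA table, mirroring the convention of reporting
  DEGs and DELs as separate lists. Calls use padj ≤ 0.05 **and**
  |log2FC| ≥ 1, boundaries inclusive.
* **Sample QC** runs PCA on log2(normalized + 1) and flags a sample whose
  median distance to same-group replicates exceeds the group median of
  those medians by more than 3 MADs. Flags are advisory: excluding a
  replicate is a documented, explicit user action (`exclude =` argument),
  never automatic.

## Target inference

Correlations are computed on log2(normalized count + 1): Pearson r on raw
counts is dominated by expression magnitude, and the log scale is the
conventional choice when the scale is otherwise unspecified. Edges require
|r| ≥ 0.90 and p ≤ 0.05 from the exact t transform
t = r·√((n−2)/(1−r²)); at n = 7 the r threshold is the binding one
(p(r = 0.90, n = 7) ≈ 0.0058). No multiple-testing correction is applied
across the DEL×DEG family — the network is *defined* by the joint
threshold — and the output metadata carries that caveat.

The *cis* window is anchored on **gene bodies**: the distance between two
genes is the minimal gap between the unions of their transcript spans,
0 when they overlap, strand ignored; pairs closer than 20 kb on one
chromosome are cis candidates. Gene-body distance was chosen over TSS
distance as the more conservative and least convention-dependent anchor.
Cis status only annotates an edge's `mode`; cis and trans edges satisfy
the same correlation thresholds.

Over-representation of a hit set in annotated gene sets uses the
hypergeometric upper tail P(X ≥ k) with BH adjustment across terms —
database-agnostic by design; the term→gene map is an input.

Structure summaries compare transcript length, exon length and exon count
between lncRNAs and mRNAs with two-sided Mann–Whitney U tests, plus
histograms (length bins of 500 bp to 5 kb with an overflow bin; exon
counts 1–10 with overflow). The comparison test is a choice — the metrics
are heavily skewed, so a rank test is the defensible default.

## The synthetic study

`sim_config()` defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_coding_genes`, `n_lnc_genes` | 300, 120 | reference annotation size |
| `n_control`, `n_treated` | 4, 3 | replicate design |
| `frac_de`, `planted_lfc` | 0.1, 2.0 | planted effect prevalence and size |
| `nb_dispersion` | 0.1 | NB dispersion α |
| `mean_count_log_range` | log 20 – log 2000 | baseline means, log-uniform |
| `n_cis_pairs`, `cis_max_distance_bp` | 10, 20000 | planted cis lnc–gene pairs |
| `cis_latent_sdlog` | 1.5 | shared lognormal latent factor (log-sd) |
| `coding_bias_strength` | 0.8 | codon-usage bias of coding ORFs |
| `outlier_sample` | FALSE | one treated sample from an unrelated baseline |

The generator places non-overlapping single-transcript genes with > 20 kb
gaps (so no accidental cis pairs); the planted cis lncRNAs sit at a
uniform 0–20 kb gene-body gap from their partner gene. Coding transcripts
carry one sense ORF ≥ 300 nt from a codon model biased toward GC-ending,
purine-leading codons (mixed with uniform at strength 0.8, which gives
both hexamer and Fickett-periodicity signal); noncoding transcripts are
background sequence rejection-sampled until the longest ORF is < 300 nt.
Assembled transcripts are engineered per class code, with a configurable
fraction (0.3) given coding sequences as contaminants and a few exact
duplicates planted for the deduplication stage. Counts are NB draws from
per-feature log-uniform baselines; planted cis pairs share a per-sample
lognormal factor, which at sdlog = 1.5 puts the true latent correlation
near 0.95 — high enough that most (not all) planted pairs clear the
|r| ≥ 0.90 screen at n = 7, exactly the marginal regime such a small
design lives in.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: read-level noise and mapping ambiguity (counts
are generated directly), isoform complexity (one transcript per gene),
batch effects beyond the single planted outlier, sequence homology between
genes (every gene is independent random sequence), and real codon usage
(the bias is synthetic, so classifier performance on real data will be
lower than the near-perfect separation seen here).

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere, the native convention of
  R/Bioconductor interval code; GTF on disk uses the same convention, so
  there is no conversion layer to confine.
* All sub-stage RNG streams derive from one master seed
  (seed, seed+1000, seed+2000, seed+3000), making every artifact
  byte-reproducible; the pipeline manifest records per-file checksums.
* Constant expression profiles are skipped (with a warning) in the
  correlation stage; constant features get the dispersion floor; features
  with any zero count are excluded from the size-factor reference (an
  error is raised only when *no* feature is zero-free).
* `hexamer_score` of a sequence shorter than 6 nt is 0 with a warning;
  `fickett_score` of an empty sequence is an error.
* Duplicate resolution, tie-breaks in the ORF scan (smallest start) and in
  deduplication (smallest id) are deterministic by construction.
* Test problem sizes: the oracle comparisons run on 500 random loci,
  1000 random 2-kb sequences and 1000 random p-value vectors; calibration
  uses m = 2000 features; the classifier sweep uses five seeds of the
  default study. These sizes make the Monte-Carlo error small relative to
  every asserted margin while keeping the default suite fast.

## Known limitations

* The DE stage is a two-group Wald test only: no covariates, no GLM
  designs, no transcript-level uncertainty.
* The class-code vocabulary is the six retention-relevant codes; the finer
  distinctions a full comparison tool draws (contained, polymerase run-on,
  repeat, etc.) are collapsed into the nearest of o/x/i/u.
* The built-in homology stage only consumes a precomputed hit table; it
  does not search.
* Correlation-based target inference at n = 7 has very low resolution:
  the |r| ≥ 0.90 threshold controls the per-pair false-positive rate
  (≈ 0.006 under the null) but true pairs with latent correlation below
  ~0.95 are missed more often than found. This is a property of the
  design, not of the implementation, and it is why the planted cis
  recovery rate in the acceptance report sits well below 1.
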