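---
title: "Scoring miRNA target de-repression against the transcriptome background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA target de-repression against the transcriptome background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

When miRNA-mediated repression is lost — for example when a peptide that
blocks miRISC assembly is expressed — the predicted targets of abundant
miRNA families should be *de-repressed*: preferentially upregulated
relative to the rest of the transcriptome. derepressr turns that question
into a per-family statistic. For each seed family (miRNAs sharing the
nucleotide 2–8 seed, hence a common predicted-target set):

1. quantify the family's small-RNA abundance from precursor-space
   alignments,
2. compute per-gene log2-fold changes (treatment vs. control) from a
   count matrix,
3. standardize the target-set mean log2-fold change against the
   background:

   $$ z = \frac{(S_m - \mu)\,\sqrt{m}}{\sigma} $$

   where $S_m$ is the mean log2-fold change of the family's $m$ expressed
   predicted targets, and $\mu$, $\sigma$ are the mean and standard
   deviation of background log2-fold changes,
4. compare the targets' empirical CDF of log2-fold changes with the
   background CDF (two-sample Kolmogorov–Smirnov).

A positive $z$ means the family's targets are preferentially upregulated.
Plotting $z$ against the family's log10 small-RNA abundance, with bubble
area proportional to $m$, summarizes whether de-repression tracks how
abundant each family is — the expected signature of global miRISC
inhibition.

## Mature miRNA quantification

Small-RNA reads are assumed to be aligned to a *precursor* index (one
reference sequence per pre-miRNA hairpin). A read is counted for a mature
miRNA when **both** its 5′ and 3′ aligned ends fall within ±4 nt of the
annotated mature ends (bounds inclusive). Design choices behind this rule:

- **Conjunction, not disjunction.** Requiring both ends in-window excludes
  degradation fragments that happen to share one end with the mature.
  `count_mature(rule = "either_end")` exposes the disjunctive reading.
- **Primary, sense-strand alignments only.** The precursor index is
  sense-stranded (miRNA biogenesis produces sense reads); secondary hits
  would double-count. Each read therefore contributes at most one count.
- **Closest-assignment tie-break.** A read compatible with several matures
  (possible when 5p and 3p arms are close) is assigned to the mature
  minimizing $|\Delta 5'| + |\Delta 3'|$, ties broken by smallest
  `mature_id`; `multi = "all"` switches to per-hit counting.
- **Aligned-segment ends.** End positions are the aligned ends in
  precursor coordinates (soft clips excluded), since the window rule is
  defined on precursor coordinates.

Family abundance is `log10` of the summed counts over the family's
members; a family whose members received no reads has undefined abundance
and is flagged rather than scored. The base is configurable
(`aggregate_families(log_base = )`) — only the axis scale, not any
statistic, depends on it.

## Fold changes: ingest or estimate

The z-score consumes only per-gene log2-fold changes, so the preferred
input is a table computed by a dedicated differential-expression tool
(`read_fold_changes()` passes it through verbatim). For self-contained
runs the package provides a deliberately simple estimator:

- **median-of-ratios size factors** — per sample, the median over genes
  (nonzero in all samples) of the ratio to the gene-wise geometric mean —
  followed by
- **pseudocount log-ratio**: `log2((mean_trt + 0.5) / (mean_ctl + 0.5))`.

No dispersion shrinkage or inference is performed; those belong to the
upstream tool. Two numerical notes:

- With the geometric-mean reference, scaling one sample by $c$ rescales
  the whole normalized matrix by the single constant $c^{1/n}$; every
  ratio, and hence every log2-fold change, is invariant. The tests assert
  this proportional form of scaling invariance.
- The pseudocount (default 0.5) keeps fold changes finite for genes with
  zeros; genes are filtered to `mean_expr >= 10` normalized counts by
  default (`filter_expressed`), a conventional bulk RNA-seq floor. Both
  are configurable.

## The de-repression statistic

`background_stats()` uses the sample standard deviation ($n-1$); at
transcriptome scale the difference from the population form is
negligible, but the choice is fixed and documented. Degenerate inputs are
hard errors: fewer than 2 background genes ("empty background") or zero
background SD ("degenerate background").

**Background definition.** For each family the background is the expressed
transcriptome *minus that family's own predicted targets*; targets of
other families remain. Removing every family's targets would empty the
background, since most genes are predicted targets of something.
`per_family_background = FALSE` switches to the full expressed universe.

**Minimum set size.** Families with fewer than `m_min = 10` expressed
targets are reported with status `too_few_targets` instead of a z-score:
below that the normal approximation underlying the statistic is not
trustworthy.

**CDF comparison.** `cdf_compare()` computes both one-sided sup-deviations
$D^+ = \sup(F_{bg} - F_{tgt})$ and $D^-$, reports
$D = \max(D^+, D^-)$ and a shift direction ($+1$ = targets right-shifted,
de-repression), and takes the two-sided p-value from `stats::ks.test`
(exact when the smaller set has ≤ 25 members, asymptotic otherwise — the
exact computation is quadratic and unnecessary at transcriptome scale).
Benjamini–Hochberg adjusted p-values across families are reported next to
the raw ones; this is an addition for reuse, not part of the original
statistic.

## What the synthetic generator emulates

`sim_dataset()` produces every input the pipeline consumes, with the
statistical structure the analysis assumes:

- **Annotation**: random precursor hairpins (70–100 nt) carrying 1–2
  mature arms (20–23 nt); family members share the seed heptamer at
  mature positions 2–8. Matures are placed with an end margin covering
  the widest configured jitter.
- **Small-RNA reads**: expected family totals span three decades
  (`reads_per_mirna_scale * 10^U(0,3)`); realized per-mature counts are
  Poisson. Each read's 5′ and 3′ ends are the mature ends plus
  independent offsets from `end_jitter_probs` (default support includes
  ±5/±6 so the ±4 window rule's exclusion side is exercised).
- **Counts**: negative binomial with a single shared dispersion (default
  0.05, a typical bulk RNA-seq value for replicate cell lines), baselines
  log-uniform over 10–1000 counts, three replicates per condition.
- **Effect model**: the generator needs a quantitative link between
  family abundance and de-repression, and the minimal choice reproducing
  a monotone, roughly proportional trend is linear in log abundance:
  $\delta_f = \delta_{max} \cdot a_f / \max_g(a_g)$ with
  $a_f = \log_{10}$ (realized family reads). Targets of several families
  take the **maximum** $\delta$, not the sum — compound effects of
  stacked sites are bounded this way, and the choice is configurable in
  spirit by editing the ground truth before `sim_counts()`.

What it deliberately does **not** emulate: FASTQ-level artifacts
(sequencing error, adapters, ligation biases), isomiR biology beyond end
jitter, gene-length or GC effects, correlated gene-gene noise, and
genuine TargetScan site-strength heterogeneity (every predicted target of
a family receives the same $\delta_f$). Passing tests therefore
demonstrate that the statistics behave correctly under the assumed
generative model — calibration and rank recovery on real data depend
additionally on how well DESeq2-style fold changes and TargetScan
predictions hold up, which no simulation can certify.

## Calibration and recovery checks

The test suite runs the full chain at study scale (sizes chosen to keep a
single-CPU run in seconds while leaving Monte-Carlo error well inside the
asserted bands):

- **Null calibration**: 200 families × 100 disjoint targets + 2000
  untargeted genes, $\delta_{max} = 0$, five seeds; per-seed family
  z-scores must have |mean| < 0.1, SD in [0.9, 1.1], Kolmogorov distance
  to N(0,1) < 0.1.
- **Signal recovery**: same geometry with $\delta_{max} = 0.5$; Spearman
  ρ(true $\delta_f$, z) ≥ 0.8, all top-quartile-abundance families at
  z > 0, and the KS shift direction agreeing with sign(z) for ≥ 99% of
  families with |z| > 2.
- **Counting**: the optimized counter must equal a brute-force
  read-by-mature enumeration exactly on 20 seeded fixtures with jitter
  mass at ±5/±6.

One practical caveat surfaced by the recovery tests: when a large
fraction of the transcriptome is perturbed upward, median-of-ratios size
factors absorb part of the effect (the median ratio is no longer anchored
by unperturbed genes), biasing absolute log2-fold changes toward zero.
The *ranking* of families — what the bubble plot shows — is unaffected,
but absolute effect sizes should be interpreted cautiously whenever most
genes are targets, exactly as with any global-perturbation experiment
normalized by a majority-invariance assumption.

## Reproducibility

Every generator derives its RNG stream from the single `rng_seed`;
re-running any stage, or the whole pipeline, with the same configuration
and seed reproduces byte-identical analysis tables (asserted in the
tests). `run_pipeline()` writes a manifest with the resolved
configuration, input MD5 digests, and per-stage row counts.

```{r example}
library(derepressr)
res <- run_pipeline(
  pipeline_config(simulation = list(n_genes = 3000, n_families = 10)),
  outdir = "derepress_run", seed = 1
)
head(res$bubble)
render_report("derepress_run")
```
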