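---
title: "Charting eccDNA catalogs: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting eccDNA catalogs: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Extrachromosomal circular DNA (eccDNA) catalogs — interval calls from
circle-seq, one BED-dialect file per sample — are the primary input to this
package. The package characterizes such catalogs (abundance, size
distribution, genomic origin, GC context, repeat-element preference),
relates eccDNA burden to chromosomal instability (wGII from copy-number
segments), stratifies samples into high/low abundance groups by NMF, and
carries the stratification into patient outcome: group differential
expression, a top-gene panel, per-patient ssGSEA scores, optimal-cutoff
Kaplan–Meier comparison, and marker ROC analysis.

Every coordinate in the package is 0-based half-open (BED convention);
1-based inputs are converted at the I/O boundary and nowhere else. Strand
is ignored throughout: interval membership and GC content are
strand-symmetric quantities.

# The synthetic-data generator

Real circle-seq cohorts of this design are controlled-access, so the
package ships a generator that plants, with known parameters, every
statistical structure the analysis modules assume. The generator is
first-class, tested code; its truth tables let each analysis be checked as
a recovery problem.

* **Genome.** Bases are drawn independently per position with the window's
  target GC probability (`gc_landscape`, realized over `gc_window` = 10 kb
  windows). Any 10-kb window lands within about 0.03 of its target. This is
  the simplest process with controllable window GC; it has no
  autocorrelation, CpG structure or N runs.
* **Annotation.** Gene density follows a linear per-Mb gradient along each
  chromosome (`gene_density_gradient`), planting the covariate behind the
  gene-density correlation. Genes carry exons (roughly 40% of gene bp).
  Repeat elements of seven RepeatMasker-style classes are placed uniformly
  and kept mutually non-overlapping until their union covers
  `repeat_fraction` of the genome — default 0.525, the approximate repeat
  content of the human genome. Class bp shares (Alu 24%, LINE 22%, LTR 15%,
  SINE 9.5%, simple repeat 12%, low complexity 8.75%, DNA transposon 8.75%
  of repeat bp) are a compromise between human-genome proportions and
  keeping every class populous enough that per-class statistics on a 1-Mb
  test genome are stable. Classes are filled longest-first so that
  non-overlap rejection cannot crowd long elements out of a filling genome.
* **Catalogs.** Per-sample record counts are Poisson around the group mean
  (`abundance_split`, default 4000 for H vs 400 for L — a bimodal burden
  split). Placement intensity on 1-kb windows is
  `exp(gc_bias * GC) * (1 + a * geneDensity + b * AluDensity)` with
  densities measured per `density_window` and scaled to [0, 1]; sampling is
  inverse-CDF over windows and uniform within, which makes every record's
  planted intensity recomputable from the emitted truth table. Optional
  per-element-class multipliers (`element_weights`) are applied to the
  record midpoint by rejection sampling, preserving exact per-bp relative
  intensity. Lengths are log-normal parameterized by mode (80 bp) and
  log-sd `size_sigma`, truncated to [30 bp, 1 Mb]. `size_sigma = 0.45` was
  chosen once so that the modal 100-bp histogram bin is the sub-100-bp bin,
  the size profile circle-seq studies report; at 0.7 the mode of the
  *binned* distribution would drift to [100, 200) even though the density
  mode stays at 80.
* **Copy number.** Each sample draws a target wGII around its group value
  (`wgii_targets`, default 0.6 vs 0.1) and every chromosome gets one
  aberrant segment (CN 1, 3 or 4 on a diploid background) sized to its
  aberrant fraction. Segments tile chromosomes exactly by construction.
* **Expression and survival.** Expression is log-normal around gene
  baselines with the first `n_de` genes split half up / half down by
  `fold_change` between H and L. Survival times are exponential with the
  hazard multiplied by `survival_hr` for the above-median-score stratum;
  censoring truncates a configured fraction of patients uniformly before
  their event, so `censoring_rate = 1` censors everyone.
* **Seeding.** Every generator draws from its own stream, derived from the
  master seed by a fixed label hash, so adding one generator never perturbs
  another and identical configurations are byte-identical on disk.

What the generator does *not* emulate — sequence autocorrelation, mappability
structure, eccDNA junction chemistry, read-level noise, per-cell expression
counts, covariate-dependent censoring — bounds what green tests mean for
real data: they validate the estimators and nulls, not robustness to every
artifact of real libraries.

# Estimators and nulls

**Abundance.** Normalized abundance is EPM, eccDNA records per million
mapped reads; the H/L contrast survives any monotone normalization, and EPM
makes depth-invariance explicit. Per-chromosome shares are per-Mb densities
normalized to percentages.

**Windowed densities.** Records and covariate features are counted in the
fixed genome window containing their midpoint — each record counts exactly
once — and expressed per Mb. Windows are at least 10 kb.

**GC context.** Each locus is compared against its 1-kb flanks and against
`n_random` random genome stretches of exactly its length, drawn uniformly
over all valid start positions (chromosome chosen proportionally to its
valid starts, so stretches are never truncated). Draws are fully determined
by (seed, record index): reordering records never changes a record's
background. The enrichment statistic is mean locus GC minus mean pooled
background GC; significance is a two-sided Mann–Whitney of locus values
against the *pooled* background draws. Pooling matters: each background
draw is one length-matched stretch, identically distributed with a locus
under uniform placement, so the two samples are exchangeable and the test
holds its nominal level. Comparing loci against per-record background
*means* instead mixes a high-variance sample with a low-variance one and
over-rejects (measured ~12% at nominal 5%); the per-record means are still
computed and reported per record. Stretches more than half N are redrawn
(at most 100 rounds) to keep GC defined.

**Element mapping ratio.** For each repeat class, the observed share is the
fraction of records whose midpoint lies in the class, divided by the
class's share of genome bp. Under uniform placement every ratio is 1. A
binary any-overlap share would exceed 1 under the null for short-element
classes (by roughly record length / element length), and a record-bp share
attenuates planted effects because records straddle element edges; both
are nevertheless reported (`n_overlapping`, `ratio_bp`), along with a
copy-number-normalized variant and a percentile bootstrap CI over records.
Region classification (exon/intron/intergenic and friends) uses an
exclusive partition with precedence exon > UTR > intron > intergenic, and a
record takes the class holding the majority of its bp, ties to precedence.

**wGII.** Sample ploidy is the length-weighted modal integer copy number
(or a supplied baseline); each chromosome's aberrant fraction is the
fraction of its length at CN different from ploidy; wGII is the unweighted
mean over chromosomes, so short chromosomes weigh as much as long ones.
This is the index's standard construction; sex chromosomes can be excluded.

**NMF grouping.** Multiplicative-update NMF (Frobenius loss, best of
`n_restarts` restarts, ties to the lowest restart index, error asserted
non-increasing every run) factorizes a per-sample feature matrix; a sample
joins the component with the larger basis coefficient after scaling
coefficients by each component's basis norm, and the component with larger
mean abundance is labelled H. The default feature matrix is per-chromosome
EPM with *complementary augmentation*: each feature is paired with its
distance to the cohort maximum. This matters because a pure burden split
gives H and L samples parallel chromosome profiles, making the rank-2
factorization degenerate — assignments come out random (we measured 0/5
recoveries on linear features and 0/10 on log features). Mirror coding
turns the magnitude split into orthogonal directions, after which recovery
of a 10-fold burden split is exact. Plain and log feature builders remain
available.

**Differential expression and the panel.** Fold change is
`(mean_H + 1e-9) / (mean_L + 1e-9)`; the pseudocount keeps 0/0 at 1 and
makes label swapping map every fold change to its reciprocal, so up and
down lists exchange exactly. Significance gating is Wilcoxon rank-sum with
Benjamini–Hochberg (expression here is normalized values, not counts); an
FC-only mode reproduces the bare 1.2-fold filter. The panel takes the top
`n` up-genes by fold change, ties by adjusted p then gene id.

**ssGSEA.** Per sample, genes are ranked by expression; walking the ranked
list, the in-set cumulative weight (weight = within-sample rank to the
power alpha = 0.25, normalized over panel genes) minus the uniform
out-of-set cumulative fraction is accumulated, and the score is the sum of
the running difference — the integrated-difference form. Scores depend on
expression only through within-sample ranks (invariant under monotone
transforms) and are min-max normalized across samples by default.

**Optimal cutoff.** Candidate cutoffs are midpoints between consecutive
distinct scores leaving both groups at least `min_group_frac` of the
cohort; the selected cutoff maximizes the log-rank chi-square. The scan is
vectorized: at-risk and event indicator matrices are accumulated
cumulatively in score order, giving the exact hypergeometric-variance
log-rank statistic for every split at once (verified split-by-split
against `survival::survdiff`). Because maximal selection inflates the naive
chi-square p, a permutation p is the primary result: scores are permuted
against (time, event) — which leaves the sorted score vector and hence the
valid-cutoff mask unchanged — and the maximum is re-taken each time;
`p = (1 + #{perm max >= observed}) / (1 + B)`. Under a null hazard this p
is uniform while the naive p over-rejects several-fold. Curves, the
log-rank test and the Cox hazard ratio at the chosen split come from the
survival package; ROC/AUC (midrank Mann–Whitney with DeLong CI) from pROC.

# Tunables

| parameter | default | unit | why |
|---|---|---|---|
| `gc_window` | 10 kb | bp | smallest window with stable realized GC |
| `repeat_fraction` | 0.525 | fraction | human repeat content |
| `size_mode`, `size_sigma` | 80, 0.45 | bp, log | sub-100-bp modal bin |
| `abundance_split` | 4000 / 400 | records | bimodal H/L burden |
| `wgii_targets` | 0.6 / 0.1 | — | instability contrast between groups |
| `fold_change`, `fc_threshold` | 1.5, 1.2 | ratio | planted effect vs call filter |
| ssGSEA `alpha` | 0.25 | — | common ssGSEA weighting |
| `min_group_frac` | 0.2 | fraction | keeps cutoff groups interpretable |
| `n_perm` | 1000 (200 in the pipeline) | — | permutation resolution ~1/(B+1) |
| `n_random` | 1000 (50–100 in tests) | stretches | background resolution per record |

Density-coupling strength is a free parameter; `a = 0.8` with a 30–300
genes-per-Mb gradient yields a per-window Pearson r near 0.8 at 10,000
records over 100 windows, which is the regime the recovery tests exercise.

# Degenerate inputs and tie rules

Zero-length intervals are parse errors naming the line; records on unknown
chromosomes stay in counts but leave sequence-dependent analyses, with a
logged tally. All-N stretches have undefined GC and are reported missing.
Identical scores admit no cutoff (an error); constant wGII or abundance
makes correlations undefined (warning + NA). Histogram modal ties break to
the smallest bin start; classification ties to precedence; NMF restart ties
to the lowest index; panel ties to adjusted p then lexicographic id.

# Problem sizes

The test suite and acceptance script run on 0.2–1 Mb genomes, catalogs of
500–10,000 records, 12–18 samples, 200–2000 genes and cohorts of 60–300
patients, with 50–200 background stretches per record and 100–200
permutations — sizes chosen so the planted effects are comfortably
detectable and the whole suite stays fast; all statistics scale to larger
inputs without code changes.

# Limitations

The GC null assumes placement that is uniform conditional on length; the
element ratio's midpoint convention under-counts classes made of elements
much shorter than a record; the NMF grouping is built for a two-group
burden split (k = 2) and the mirror augmentation presumes burden is the
dominant axis; the optimal-cutoff permutation treats scores as exchangeable
across patients, which breaks under strong score–censoring dependence; and
the generator's independence assumptions mean real-data robustness (GC
autocorrelation, mappability, batch structure) is untested here.
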