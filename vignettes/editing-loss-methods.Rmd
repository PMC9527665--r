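---
title: "Quantifying A-to-I editing loss from edit-site tables: models and methods"
author: "aluedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying A-to-I editing loss from edit-site tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Adenosine-to-inosine (A-to-I) editing by ADAR enzymes marks endogenous
double-stranded RNA — overwhelmingly inverted Alu repeats in primates — as
"self". When editing is lost, unedited Alu dsRNA can trigger innate-immune
dsRNA sensors and an interferon response. `aluedit` implements the
downstream analysis used to ask whether a case cohort (for example,
Alzheimer's disease hippocampal vasculature) has lost A-to-I editing
relative to a control cohort, starting from the per-sample edit-site tables
an editing caller produces, not from raw reads.

The pipeline covers: site-inclusion filtering; cohort-wide common-site
sets; per-site, genome-wide and per-gene editing indices with case/control
log2 ratios; Alu and gene-feature annotation; per-lineage editing
comparisons driven by single-cell marker percentages; and expression
screens of RNA-binding-protein (RBP) genes and interferon/NF-κB gene
panels. A seeded generator supplies every input with known ground truth.

# The editing index

For sample $s$ and site $i$, the caller reports edited reads $e_{is}$ and
total reads $n_{is}$; the edit/read ratio is $r_{is} = e_{is}/n_{is}$. A
site enters the analysis in a sample only if $n_{is} > 5$ and
$r_{is} > 0.05$ — both strict inequalities, applied before anything else,
so a site failing them counts as absent everywhere downstream. Within a
cohort, a site qualifies when it is present (after filtering) in at least
2 samples, and its **per-site editing index** is

$$ I_i = \bar r_i \cdot m_i, $$

where $m_i$ is the number of samples containing the site and $\bar r_i$
the mean ratio over those samples (absent samples do not contribute zeros —
the mean is over samples *with* edits). The **genome-wide index** is
$\sum_i I_i$; the **per-gene index** is the same sum restricted to sites
assigned to the gene.

Two consequences of the thresholds are worth noting:

* every admitted ratio exceeds 0.05 and every qualifying site has at least
  2 samples, so $I_i > 0.05 \times 2 = 0.1$. The infimum 0.1 is approached
  but never attained (`site_index_floor()` computes it for any
  configuration); it matches the observed lower end of per-site index
  distributions.
* $I_i \le m_i \le$ cohort size, which is why index ranges scale with the
  number of samples.

For the case/control per-gene comparison, genes qualify with **more than
5** editing sites in either cohort, and the effect is reported as
$\log_2(I^{case}_g / I^{ctrl}_g)$. When one cohort has no qualifying edits
in a gene the ratio is undefined; such genes carry a sentinel category
(`case_only`, `control_only`, `both_zero`) and the nonzero cohort's index,
rather than a pseudo-counted ratio — they are the extreme points of the
ranked log2 plot, not numbers to be averaged. The per-gene index is the
*sum of per-site indices* rather than a raw edit count; both readings are
computable from the site-index table, and the sum is the default because
the per-lineage comparison plots "the editing index" per gene.

# Common-site sets

Between cohorts A and B, sites are classified by cohort-wide presence:
present in *all* samples of A but not all of B (`A_only`), the symmetric
`B_only`, and present in all samples of both (`shared`). "Not all"
includes complete absence. Mean ratios for shared sites are reported per
cohort, never pooled, since the two cohorts are plotted separately. Site
counts between cohorts are compared with a 2-cell goodness-of-fit
chi-square against equal expectation (df = 1); the construction is the
minimal test of "different numbers of sites" given that the source
analyses report only the two counts. Ranked edit/read curves order sites
by descending mean ratio with a deterministic (chrom, pos, strand)
tie-break.

# Annotation

Sites are annotated by point-in-interval queries (via
GenomicRanges/IRanges) against BED-derived gene features (intron, 5'UTR,
3'UTR, ncRNA) and repeat elements; a site is "in Alu" when it lies inside
any repeat of family `Alu`. On-disk intervals are 0-based half-open (BED);
internal coordinates are 1-based inclusive. When features overlap, the
precedence 3'UTR > 5'UTR > ncRNA > intron resolves the class, and within a
class the gene whose interval start is nearest wins; the UTR-first order
reflects the analysis's focus on UTR Alu editing, since no rule is
dictated by the data format itself. Strand is ignored for membership by
default (`strict_strand = TRUE` restores strict matching): editing calls
and repeat databases frequently disagree on strand bookkeeping, and the
permissive default maximizes concordance.

The template designer (`design_edited_template()`) builds the edited
counterpart of an Alu sequence by substituting A→G at declared positions
only — positions must hold A, errors name the first offending position —
and prepends an SP6 promoter (canonical
`ATTTAGGTGACACTATAG`, overridable) for in-vitro transcription export.

# Lineage analysis

Lineage-defining genes are selected from a single-cell marker table by
pct1/pct2 > 10, where pct1 is the fraction of cells in the cluster
expressing the gene and pct2 the fraction in all other clusters; pct2 = 0
with pct1 > 0 counts as infinite and selects. Per lineage, the unit of
observation is the **gene**: the vectors of per-gene indices of the
lineage's markers in control vs case are compared with Welch's unpaired
t-test. This reading is forced by the degrees of freedom in the source
summary tables (df near 130 for ~85 genes is only consistent with per-gene
observations under Welch–Satterthwaite). Genes with no qualifying sites
contribute index 0 rather than being dropped — under uniform loss,
dropping them would thin the case vector asymmetrically and bias the
comparison. Lineages with fewer than 3 genes are flagged untestable.

# Expression screens

The per-sample **ratio screen** divides each sample's expression of a
gene by the control-cohort mean; ratios strictly below 0.5 are `under`,
strictly above 2.0 `over`. This is the readout for "gene X reduced in k of
n case samples". Genes with a zero control mean are flagged unevaluable,
not dropped.

**Panel fold changes** report, per gene of each panel (ISG, NF-κB), the
log2 ratio of case to control mean FPKM
($\mathrm{FPKM} = 10^9 c / (L \cdot N)$ for count $c$, gene length $L$,
library size $N$), a delta-method standard error, and a two-sided
Monte-Carlo label-permutation p-value (10,000 permutations by default)
with Benjamini–Hochberg adjustment across the panel. The permuted
statistic is the difference of cohort means — it orders permutations
identically to the mean ratio while remaining finite when a permuted group
mean is zero. A transparent permutation test replaces a shrinkage-based
differential-expression fit deliberately: the pipeline's claims are about
panel-level direction and magnitude, not per-gene dispersion modelling,
and the self-contained construction keeps every number derivable from the
matrix alone. Panel-level significance is a two-way (gene × cohort) ANOVA
on log2(FPKM + 1); the +1 guards zeros on the log scale.

# Statistical routines

Welch's t (with Welch–Satterthwaite df), the chi-square goodness-of-fit
test, the BH step-up adjustment, and one-/two-way fixed-effects ANOVA are
implemented as closed forms and verified in the test suite against the
corresponding base-R routines (`t.test`, `chisq.test`, `p.adjust`, `aov`)
to 1e-8 on randomized instances; the base routines serve only as test
oracles, keeping implementation and check independent. All p-values are
two-sided. The two-way ANOVA covers balanced designs (equal cell counts;
with one observation per cell the additive model is fitted) and rejects
unbalanced ones — the cohort designs this pipeline addresses are balanced,
and closed-form sums of squares are only unambiguous there.
Kruskal–Wallis and Dunn post-hoc wrappers are provided for completeness
but no reported quantity depends on them.

# The synthetic-data generator

`sim_config()` defines the emulated study; the defaults are the study
conditions, chosen once:

| parameter | default | meaning |
|---|---|---|
| `n_control`, `n_case` | 7, 7 | cohort sizes of the vasculature design |
| `n_genes` | 760 | 14 lineages × 50 markers + background |
| `sites_per_gene_mean` | 10 | negative binomial, ~7,600 sites |
| `alu_fraction` | 0.95 | >90% of sites in Alu elements |
| `depth_mean`, `depth_size` | 100, 10 | deep bulk coverage at sites |
| `ratio_shape1/2` | Beta(2, 8) | low baseline ratios typical of Alu sites |
| `retention` | 0.5 | uniform halving of case edit probability |
| `expr_mean`, `expr_size` | 500, 20 | bulk count dispersion |
| `n_background_expr` | 2000 | transcriptome-scale expression matrix |

Sites are placed on slot positions ≥ 400 b apart inside simulated gene
bodies (5'UTR/intron/3'UTR, or ncRNA for 5% of genes), so the ±150 b Alu
windows written around Alu-designated sites never cover a neighbouring
site. Per sample, reads are negative binomial and edited reads binomial at
the site's true cohort ratio; a site is emitted only when at least one
edited read is drawn, as callers only report observed edits. Editing loss
is a single multiplicative retention factor on case edit probabilities —
the uniform-loss model — with optional per-lineage overrides to simulate
the localized-loss alternative. The expression matrix needs its ~2,000
background genes: panel effects on a small gene universe would shift
library sizes enough to visibly compress FPKM fold changes, an artifact a
transcriptome-scale matrix does not have.

What the generator does **not** emulate: real Alu sequence context,
correlated editing within inverted repeat pairs, cell-composition shifts,
batch effects, or covariate structure between samples. Passing
ground-truth recovery on this generator therefore demonstrates the
pipeline's arithmetic and inference machinery, not robustness to those
real-data complications.

## Problem sizes used in the tests

The test suite and acceptance checks run the generator at 150–760 genes
(up to ~7,600 sites, 7+7 samples), 200 brute-force-checked random
set-comparison instances, 100 randomized statistical instances per test,
and 200 null replicates for the type-I-error check; these sizes make every
distributional check stable while each file of the suite stays in the
seconds-to-a-minute range.

# Numerical and degenerate-input choices

* All thresholds are strict (>); boundary cases (reads = 5, ratio = 0.05,
  ratio screen at exactly 0.5) fall on the excluded side, following the
  wording "greater than".
* Rankings break ties by (chrom, pos, strand) so all outputs are
  deterministic; reruns with the same inputs and seed are byte-identical.
* Empty results (no qualifying sites, empty common-site sets) are valid
  and propagate as zero-row tables; empty *inputs* (empty cohort, empty
  annotation set for a composition) are errors.
* BH adjustment can equal the raw p-value; to floating-point rounding the
  adjusted value may differ by ~1e-16, which tests must tolerate.
* The permutation p-value uses the add-one estimator (never exactly 0).

# Known limitations

* **The per-lineage Welch test is conservative under the null.** Control
  and case per-gene indices are computed for the same genes, and a gene's
  editing propensity (site count × baseline ratio) is shared between
  cohorts — by construction in the generator (measured between-cohort
  per-gene index correlation ≈ 0.99) and by biology in real data. The
  unpaired test ignores that coupling, so its null rejection rate falls
  far below the nominal 0.05 (observed ≈ 0 over 200 null replicates,
  median null P ≈ 0.95). This makes significant per-lineage *losses*
  harder, not easier, to obtain — the all-lineages-significant result
  under uniform retention 0.5 survives a strongly conservative test — but
  the test cannot be read as calibrated: a paired or per-gene-ratio
  formulation would be required for nominal type-I error.
* The two-way ANOVA requires balanced designs; unequal cohort sizes need
  a regression formulation out of scope here.
* The chi-square site-count comparison treats each site as an independent
  count; clustering of sites within repeats makes its p-values
  anti-conservative, which is acceptable only because the compared counts
  differ grossly.
* No multiple-testing correction is applied across lineages (the source
  tables report raw per-lineage P); the BH machinery is available if
  desired.

# Reproducing the analysis

The `analysis/` scripts run the whole workflow on generated data
(`01_simulate.R` through `07_alu_templates.R`), writing tables under
`results/`; `scripts/acceptance.R --seed 1 --out results/acceptance.json`
recomputes the reported acceptance quantity from scratch.
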