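# aluedit

Downstream analysis of adenosine-to-inosine (A-to-I) RNA editing loss from
per-sample edit-site tables.

A-to-I editing by ADAR enzymes marks endogenous double-stranded RNA —
chiefly inverted Alu repeats — as "self"; losing it leaves unedited Alu
dsRNA that can activate innate-immune sensors. Given the text tables an
editing caller emits (genomic position, edit type, strand, edited reads,
total reads per site), `aluedit` answers the comparative question: *does a
case cohort show less editing than a control cohort, where, and in which
cell lineages?* It is written for transcriptomics analysts who already have
edit-site calls and count matrices and need the cohort-level statistics,
not another caller.

## The statistic at the core

A site enters the analysis in a sample only if total reads $n > 5$ and the
edit/read ratio $r = e/n > 0.05$ (strict). Within a cohort, a site present
in $m \ge 2$ samples gets the **editing index**

$$I = \bar r \cdot m,$$

the mean edit/read ratio over the samples containing the site times the
number of such samples. The genome-wide index is $\sum_i I_i$; a gene's
index is the same sum over its sites, and case/control comparisons are
reported as $\log_2(I^{case}/I^{ctrl})$ for genes with more than 5 sites in
either cohort. Under the default thresholds every per-site index strictly
exceeds $0.05 \times 2 = 0.1$ — the analytic floor of the index scale.

Around that core the package provides: cohort common-site sets (present in
all samples of one cohort but not all of the other) with ranked edit/read
curves and a chi-square site-count comparison; Alu / gene-feature
annotation (BED-style inputs, 3'UTR > 5'UTR > ncRNA > intron precedence);
per-lineage editing comparisons from single-cell marker pct1/pct2 ratios
(Welch's t-test, gene as unit); per-sample expression ratio screens with
0.5/2.0 cutoffs; panel-level log2 FPKM fold changes with permutation
p-values and BH adjustment; in-silico edited Alu template design (A→G with
an SP6 promoter); and a seeded synthetic-data generator that produces every
input with known ground truth, so the full analysis runs with no external
data.

## Worked example

`analysis/` contains the numbered workflow scripts; each is a thin driver
over the package functions and writes tables under `results/`. Running them
in order on the default simulated study (7 control "NCI" + 7 case "AD"
samples, uniform 50% editing retention in the case cohort):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_and_index.R
Rscript analysis/03_cohort_comparison.R
Rscript analysis/04_gene_index.R
Rscript analysis/05_lineage_comparison.R
Rscript analysis/06_expression_screens.R
Rscript analysis/07_alu_templates.R
```

prints, among other lines:

```
simulated 760 genes, 7697 editing sites (95.1% in Alu), retention 0.50
NCI: 7 samples, 7365 qualifying sites, genome-wide index 10690.2, index/site range 0.102-5.13
AD: 7 samples, 6617 qualifying sites, genome-wide index 5013.1, index/site range 0.101-2.55
present in all NCI only: 2305; all AD only: 15; shared by all: 3874
chi-square on all-sample site counts: X2 = 520.9, P = 2.74e-115
611 genes with > 5 sites; 100.0% show reduced editing in AD; median AD/NCI ratio 0.47
14 of 14 lineages significant at P < 0.05; case mean lower in 14
ISG: mean log2 AD/NCI ratio 0.95; 25/25 genes FDR < 0.05; cohort ANOVA P = 7.7e-74
```

Reading these numbers: the case cohort retains about half the genome-wide
editing index (5013 vs 10690; the simulation's true retention is 0.5), far
more sites are edited in every control sample than in every case sample
(2305 vs 15), essentially all multi-site genes shift down (median per-gene
AD/NCI index ratio 0.47), the loss appears in all 14 cell lineages at
similar strength — the uniform-loss signature — and the
interferon-stimulated gene panel recovers its simulated 2-fold case
up-regulation (mean log2 ratio ≈ 1).

The same stages are available as one call on file inputs via
`run_config()` + `run_full_analysis()`, which writes the numbered stage
tables and a `manifest.json`.

## Layout

```
R/                  package code (I/O, filtering, indices, annotation,
                    lineage, expression, statistics, generator, pipeline)
analysis/           numbered workflow scripts (worked example above)
scripts/acceptance.R  reported-number reproduction
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette: models, parameters, limitations
```
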