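---
title: "Methods: expression and splicing QTL mapping with meatqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression and splicing QTL mapping with meatqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meatqtl)
```

## The analysis in one paragraph

`meatqtl` maps genetic variants that regulate gene expression (eQTL) and
exon usage (sQTL) in a muscle transcriptome study designed around a
composite meat-quality phenotype. Animals are genotyped on a dense SNP
panel and phenotyped for six quality traits; a subset with extreme values
of a PCA-based quality index is RNA-sequenced. Every SNP is then tested
against every expressed feature with an ordinary linear model on
variance-stabilized expression, with year of birth and the first genotype
principal component as covariates. Significant pairs are classified by
distance (cis within 1 Mb of the gene span, otherwise trans) and by
whether the gene belongs to the set whose expression explains quality
variation (the "DEG" set, called by Huber robust regression). SNPs that
trans-regulate at least 20 genes (or exons) are hotspots; their harboring
or nearest gene is the candidate master regulator.

## The meat-quality index

The six traits — marbling (visual score 100–999), Warner-Bratzler shear
force (kg), cooking loss (%), and panel juiciness, tenderness, and
connective tissue (1–8) — live on incommensurate scales, so `compute_index()`
runs the PCA on the trait correlation matrix (standardized traits). The
index for animal $i$ is the eigenvalue-weighted sum of its first three PC
scores,

$$\mathrm{index}_i = \sum_{j=1}^{3} \mathrm{PCS}_{ij}\,\mathrm{PCW}_j,$$

with $\mathrm{PCW}_j$ the $j$-th eigenvalue. Eigenvalue weighting means a
PC contributes in proportion to the trait variance it captures. PC signs
are fixed by making the largest-magnitude trait loading positive, so
indices are reproducible across runs and platforms. `select_extremes()`
keeps the 40 highest- and 40 lowest-index animals of 120 by default; the
even split is a design choice ("extreme values" admits several readings)
and ties break deterministically by animal id.

If *every* trait is constant the index degenerates to all zeros with a
warning; if only some traits are constant the correlation matrix is
undefined and the function stops — silently imputing a direction there
would manufacture an index out of nothing.

## DEG calling by Huber robust regression

`deg_scan()` fits, per feature,

$$\mathrm{index} \sim \mathrm{expression} + \mathrm{year} + \mathrm{PC1}$$

by an M-estimator with Huber's $\psi$ (tuning $k = 1.345$, 95% Gaussian
efficiency), iteratively reweighted least squares with a concurrent
MAD-based scale. Robust regression is the right tool here because
sensory-panel phenotypes and RNA-seq expression both produce occasional
gross outliers that would dominate an OLS slope. Standard errors use the
usual M-estimator sandwich with Huber's small-sample correction and a $t$
reference with $n - p$ degrees of freedom (at $n = 80$ the normal
reference is noticeably anticonservative). A gene is DEG when its
gene-level test has $p < 0.05$, or when at least three of its exons are
individually associated at $p < 0.05$; the exon rule uses the same
covariates as the gene rule. No multiplicity correction is applied at
this stage — the DEG label feeds classification, not inference — and the
expected null DEG rate is therefore the nominal 5%. Expression enters
this branch as `log2(count / TMM factor + 1)`; the robust fit makes the
exact transform choice secondary, and the log scale keeps leverage of
highly expressed genes bounded.

DEG sets from external categorical contrasts can be merged via
`call_degs(extra_deg = ...)`, since studies often combine several DEG
definitions before classification.

## Normalization and the variance stabilizing transformation

`tmm_factors()` implements trimmed-mean-of-M normalization against a
reference animal (upper-quartile rule), trimming 30% of M and 5% of A and
weighting by inverse asymptotic variance. The returned factors carry
size-factor semantics — they include sequencing depth and have geometric
mean 1 — so `counts / factor` is directly comparable across animals. The
implementation is cross-checked against edgeR's in the test suite.

For the association scan, counts are transformed with a closed-form
variance stabilizer. With a single dataset-level negative-binomial
dispersion $\alpha$ (median of per-feature method-of-moments estimates),
the exact stabilizer of the NB variance law $\sigma^2 = \mu + \alpha\mu^2$
is

$$t(q) = \frac{2}{\sqrt{\alpha}}\,\operatorname{asinh}\!\sqrt{\alpha q},$$

affinely rescaled so that $t(q) \to \log_2 q$ for large $q$. This is a
deliberate design choice over a fitted mean–dispersion trend: the
closed form is fully specified, parameter-light, monotone, and achieves
the same goal — removing the mean–variance dependence so that one OLS
residual variance per feature is meaningful across the expression range.
The test suite verifies that it flattens the log-variance/log-mean slope
of NB data from $\approx 1$ to $|\text{slope}| < 0.2$. When the estimated
dispersion is zero the transform falls back to $\log_2(q + 1)$ with a
notice. Size factors default to median-of-ratios against the
geometric-mean pseudo-reference.

For sQTL mapping the response is exon usage: the fraction of a gene's
counts on one exon, kept to three decimals and scaled by 1000 into an
integer (half-up rounding; truncation is available since the convention
is genuinely ambiguous), then passed through the same VST. A zero gene
count gives fraction 0; an exon exceeding its gene clamps to 1000 with a
warning rather than stopping, since such rows in real data are counting
artifacts.

## The association scan

`association_scan()` fits every SNP × feature pair by OLS of the
transformed feature on dosage (0/1/2), year of birth, and PC1. The
implementation residualizes the features and the dosages on the
covariates once (QR projection) and then runs the simple regressions on
residuals — by the Frisch–Waugh theorem this is *numerically identical*
to the full OLS, and the contract is enforced to 1e-8 against a plain
`lm()` oracle in the tests. SNPs with missing calls are handled per SNP
on their pairwise-complete animals (missingness is never imputed in the
tests themselves, only in the PCA); SNPs monomorphic among the used
animals are skipped and logged.

Classification: a pair is cis when the SNP sits on the feature's
chromosome within $[\mathrm{start} - 1\,\mathrm{Mb},\ \mathrm{end} +
1\,\mathrm{Mb}]$, inclusive on both boundaries ("no more than 1 Mb");
exons inherit their parent gene's span, and strand is ignored because the
window is symmetric. Retention is $p \le$ threshold. The final trans
thresholds default to $10^{-5}$ (eQTL) and $10^{-6}$ (sQTL); cis eQTLs
use per-gene simpleM Bonferroni thresholds, and cis sQTLs a flat
$2 \times 10^{-4}$. Both the simpleM-derived and the configured final
thresholds are computed and logged, so the deliberate use of
less-stringent final trans cutoffs is always visible.

## simpleM effective number of tests

`simple_m()` eigendecomposes the SNP × SNP correlation matrix of a block
(missing dosages mean-imputed) and returns the smallest $k$ whose top-$k$
eigenvalues reach 99.5% of the total variance. Genome-wide, SNPs are
processed in consecutive map-ordered blocks of 133 (restarting at each
chromosome) and the per-block values summed — whole-panel
eigendecomposition is infeasible and per-block additivity is the standard
windowed practice; both the window and the variance fraction are exposed
as configuration. With 42,246 effective tests at $\alpha = 0.05$ the
Bonferroni trans threshold is $1.18 \times 10^{-6}$. Per-gene cis
thresholds apply the same statistic to the SNPs in each gene's cis
window (clipped at position 1 near chromosome ends); genes with no cis
SNP are recorded and excluded rather than given a vacuous threshold.

Worth knowing: at the 99.5% fraction, simpleM only collapses
*near-duplicate* SNPs. Blocks with moderate pairwise LD (r ≈ 0.6) still
count nearly one test per SNP; the reduction to ~38% of the panel seen on
real chip data comes from the long tail of extremely correlated markers.

## Hotspots and master regulators

`detect_hotspots()` counts, per SNP, the distinct trans-regulated genes
(eQTL mode) or exons (sQTL mode) among retained records; a SNP with at
least 20 is a hotspot, and its DEG percentage is the share of targets in
the DEG set. Nearby hotspots cluster by single linkage within 1 Mb
(consecutive SNPs on a chromosome at most 1 Mb apart share a cluster),
numbered in genome order. The master regulator of a hotspot is the gene
harboring the SNP, or for intergenic SNPs the nearer flanking gene, with
both flanks and their distances reported and ties broken by lower start
coordinate and flagged. This is a deterministic stand-in for what is, in
practice, partly a curation step (choosing among flanks by biological
plausibility); the package reports the evidence and makes the default
choice reproducible. `export_network()` writes the bipartite
regulator → target edge list (TSV and SIF) with DEG and regulator flags
on the nodes.

## The synthetic study generator

The generator exists so that every downstream stage can be validated
against a known truth without any external data. Its defaults describe
the emulated study population:

| knob | default | what it emulates |
|---|---|---|
| `n_animals`, `n_breed_groups` | 120, 6 | multibreed herd in six breed-composition groups |
| ancestry gradient | group mean $(g-0.5)/6$, sd 0.05 | admixture between two ancestral pools |
| `pool_divergence` | 0.3 | allele-frequency divergence making PC1 track breed composition |
| `n_snps`, `ld_block_size`, `ld_r` | 2000, 10, 0.6 | chip panel in LD blocks (Gaussian-copula haplotypes) |
| `maf_range`, `missing_rate` | 0.05–0.5, 2% | MAF spectrum and call failures for the QC filters |
| `dispersion`, `mean_count_range` | 0.1, 0.05–500 | NB counts spanning sub-10-total genes (exercises the count filter) |
| `n_cis_effects`, `cis_beta` | 20, 1.0 | cis eQTLs, in VST units per allele copy |
| `n_hotspots`, `hotspot_targets`, `hotspot_beta` | 2, 25, 1.0 | trans hotspots above the 20-target detection rule |
| `n_sqtl`, `susage_effect` | 10, 0.1 | usage-fraction shifts per allele, clipped to the simplex |
| `n_deg_genes`, `deg_pheno_weight` | 30, 1.0 | genes driving the six traits through one latent factor |
| `year_effect_sd`, `expr_batch_sd` | 0.5, 0.3 | year-of-birth batch effects on traits and counts |

Effect sizes enter the count model as $\log 2 \times \beta \times$
dosage on the log mean, so a planted $\beta$ is exactly $\beta$ VST units
per allele copy at high expression — verified by simulation in the tests.
Planted effects are placed on *expressed* genes (baseline mean at least
20 counts): a trans effect on a gene whose counts hover at zero is
undetectable by construction and would measure the expression floor, not
the scan. Exon counts are a multinomial split of the gene count, so
conservation is exact; phenotypes are linear in the mean VST expression
of the DEG genes plus year and noise, mapped into realistic trait ranges.

What the generator does **not** emulate: read-level sampling (mapping
bias, positional coverage), realistic genome annotation (gene density,
overlapping genes), pedigree relatedness, linkage between the planted
truth classes, and dominance or epistasis. Passing tests therefore
demonstrate the correctness and calibration of the *pipeline* under its
own model assumptions, not performance on real cattle data.

"All-null" data (used for calibration checks) means all planted effects
zero *and* the ancestry–expression coupling zero, with baseline means
5–500 so calibration is measured on expressed genes; the VST of
near-zero counts is too discrete for exact p-value uniformity, which is a
property of count data, not a pipeline defect.

## Numerical choices and degenerate inputs

* Scan p-values use the $t$ distribution with residual degrees of
  freedom; dosage collinear with covariates (residual sum of squares
  below 1e-10) is skipped rather than reported with an unstable estimate.
* `huber_fit` declares convergence when the coefficient change falls
  below 1e-8 (relative); an exact fit collapses the MAD scale to zero and
  returns the interpolating coefficients with $p = 0$ for nonzero ones.
* MAF uses the pairwise-complete denominator; QC boundaries are
  inclusive (MAF exactly 0.03 and call rate exactly 0.9 are kept, since
  the exclusion rules are "lower than 3%" and "< 0.9"). The parenthetical
  genotype-count reading of the MAF rule (at least 2 animals carrying the
  less frequent genotype) is available behind
  `filter_snps(genotype_count_rule = TRUE)`.
* Missing dosages are mean-imputed for PCA and for the simpleM
  correlation matrix only; association tests drop the missing pairs, which
  keeps effect estimates unbiased at the cost of per-SNP sample size.
* Coordinates are 1-based inclusive internally (VCF/GFF convention); BED
  input/output converts with `start + 1`, an exact bijection on valid
  records.
* All tie-breaks (extreme selection, master-regulator flanks) are by id
  or coordinate, never by input order.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances — 60–300 SNPs, 30–120 genes, 80–120 animals, 50–100 simulation
replicates — chosen so the whole validation completes in a few minutes
while keeping every statistical check (calibration bands, power
properties, analytic eigenvalues) well-powered at its stated tolerance.
The pipeline itself is vectorized over SNP × feature pairs and handles
panels of a few hundred thousand tests comfortably; a full chip-scale
panel (~10^5 SNPs × ~10^4 features) would want chunked scanning, which is
the main known scalability limitation.

## Known limitations

* The per-gene cis thresholds and the final flat thresholds coexist; the
  scan applies the final ones by default for trans and sQTL cis, which is
  deliberately less stringent than the simpleM values and is always
  logged.
* The DEG branch implements only the robust-regression definition;
  categorical-contrast DEG calls must be supplied externally if wanted.
* Master-regulator assignment is purely positional.
* The breed-group covariate is not in the QTL model (year + PC1 only);
  PC1 absorbs breed composition by construction, and the property tests
  measure exactly how much trans inflation its removal causes.
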