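---
title: "Methods: fast association scans for methylation, genotype and environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast association scans for methylation, genotype and environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemscan)
```

## The problem

An epigenome-wide association study holds a CpG methylation matrix
$M$ (features × samples, beta values in $[0,1]$), a genotype dosage
matrix $G$ (0/1/2 minor-allele counts), a set of environmental
exposures $E$ and nuisance covariates. Three families of hypotheses
matter:

* **Emodel** — is a CpG's methylation associated with an exposure?
  $M = \alpha + \beta E + \gamma\,\mathrm{cvrt} + \varepsilon$
* **Gmodel** — is it associated with a genotype (a methQTL)?
  $M = \alpha + \beta G + \gamma\,\mathrm{cvrt} + \varepsilon$
* **GxEmodel** — is it shaped by their interplay?
  $M = \alpha + \delta E + \eta G + \beta (G \circ E) +
  \gamma\,\mathrm{cvrt} + \varepsilon$

The hypothesis space is the full cross of features: a cohort with
1,423 CpGs and 708,365 SNPs already implies 1,008,003,395 Gmodel
regressions, times the number of environments for GxE. Fitting these
one `lm()` at a time is infeasible on ordinary hardware; the point of
this package is that none of them needs to be fitted individually.

## Projection and the correlation identity

For a single pair, the t-test of $\beta$ in
$y = \alpha + \beta x + \gamma\,\mathrm{cvrt} + \varepsilon$ depends
on the data only through the partial correlation of $y$ and $x$ given
the covariates. `residualize_standardize()` therefore projects every
feature row onto the orthogonal complement of
$\mathrm{span}\{\mathbf{1}, \mathrm{cvrt}\}$ (via the QR factorization
of the design) and scales it to unit norm. For standardized rows
$\tilde y, \tilde x$,

$$r = \langle \tilde x, \tilde y \rangle, \qquad
t = r \sqrt{\frac{\mathrm{df}}{1 - r^2}}, \qquad
\mathrm{df} = n - n_{\mathrm{cvrt}} - 2,$$

and the slope on the original scale is recovered from the residual
norms kept alongside the unit rows:
$\hat\beta = r\,\lVert y_\perp \rVert / \lVert x_\perp \rVert$. A whole
scan is then one matrix product of standardized matrices. The df
convention (intercept + covariates projected, one slope, one residual
df) is pinned operationally: the package's oracle — an explicit
per-pair QR least-squares fit, `lm_single()` — must reproduce every
(β, t, p) to 1e-8 relative, and the test suite enforces this on
complete-data instances for all three models.

The interaction test avoids the five-column fit the same way. With
$h = g \circ e$ and all of $y, g, h$ residualized against
$\{\mathbf{1}, \mathrm{cvrt}, e\}$, the t-statistic of the interaction
coefficient in the *full* model equals the partial correlation

$$r_{\mathrm{p}} = \frac{r_{yh} - r_{yg} r_{gh}}
{\sqrt{(1 - r_{yg}^2)(1 - r_{gh}^2)}}, \qquad
\mathrm{df} = n - n_{\mathrm{cvrt}} - 4.$$

The main effects of $G$ and $E$ are deliberately part of the tested
model even though the headline equation only names the cross term: a
cross-only model confounds the interaction with the genotype main
effect, and the partial-correlation construction above is exactly the
full-model t-test (the oracle cross-checks both `interaction_stat()`
and the blocked scan against `lm(y ~ g * e + cvrt)`).

## Blocking and numerical choices

Predictor matrices stream through `correlate_block()` in blocks of
`block_size` rows (default 1,000), bounding peak memory at
`block_size × n_outcomes` correlations regardless of scan size.
Results are byte-identical for every block size; this required one
non-obvious workaround — optimized BLAS libraries dispatch a different
kernel for one-row matrix products whose summation order differs in
the last bits, so single-row blocks are padded to two rows and the
duplicate discarded.

Other numerical decisions, all visible in the API:

* Correlations are clipped to $[-1, 1]$; $|r|$ within $10^{-12}$ of 1
  is reported at the smallest representable positive p-value with a
  `saturated` flag rather than an infinite t.
* Rows whose residual norm after projection falls below $10^{-10}$
  relative to the input row are *degenerate* (no testable signal given
  the covariates) and are set aside and itemized, not silently dropped.
  The threshold is relative, not absolute, so a row lying exactly in
  the covariate span is caught regardless of its scale.
* An intercept is always added implicitly; a constant covariate row is
  rejected by name (it would otherwise be a silent rank deficiency),
  as is any linearly dependent covariate.
* Ties in the output ordering (equal p) are broken lexicographically
  by outcome then predictor ID, so result files are deterministic
  across platforms.

## Missing data

Matrix inner products cannot skip sample pairs the way a per-pair
regression drops incomplete cases, so missing cells are mean-imputed
per feature row before projection (`impute_row_means()`); genotype
rows are imputed on the dosage scale, not re-rounded. The consequence
is documented and tested rather than hidden: for rows with no missing
cells the fast path is exactly the complete-case fit, while rows with
missing cells drift slightly (imputation keeps $n$ samples where the
complete-case fit uses fewer). Users who prefer failure to imputation
set `impute_missing = FALSE` (CLI `--no-impute`). Rows with *no*
observed values are dropped and reported.

## Multiple testing and bookkeeping

FDR is Benjamini–Hochberg (`bh_fdr()`, a validated wrapper over
`stats::p.adjust`). The family size $m$ is the number of tests
*computed*, not the number of records emitted: genome-scale Gmodel/GxE
scans emit only records with $p \le$ `p_threshold` (defaults: 1 for
Emodel, $10^{-5}$ for the genome-scale scans), and adjusting over the
emitted subset alone would overstate significance. Since the emitted
records are exactly the smallest p-values of the family, the step-up
formula over them with the full $m$ is exact. Degenerate rows produce
no p-value and are excluded from $m$ but itemized in `glance()` and
the CLI scan report. Emodel treats each environment row as an
independent scan with its own FDR family of $n_{\mathrm{CpG}}$ tests;
Gmodel and GxEmodel adjust across the whole scan.

Each scan's `glance()` reports attempted tests (the exact dimension
product), computed tests, emitted records, residual df, and the
genomic inflation factor $\lambda_{GC}$ — the median observed 1-df
$\chi^2$ over its null expectation. $\lambda_{GC}$ is only estimable
from the full p-value distribution, so it is `NA` whenever
`p_threshold < 1`.

## Pair classification

SNP–CpG pairs are classified from BED (0-based, half-open)
annotations: different chromosomes → *trans*; same chromosome → *cis*;
same chromosome with interval gap ≤ `disrupting_window_bp` →
*disrupting*, taking precedence over cis. The disrupting definition is
a design choice of this package: a variant physically coinciding with
the CpG site destroys the dinucleotide itself, and the default window
of 0 bp (overlap only) encodes that reading while leaving the
criterion configurable, since usage of the term varies. The optional
`cis_window` argument restricts a Gmodel scan to nearby pairs — off by
default, because trans methQTLs are real and the full cross is the
package's point; when it is on, the FDR family shrinks to the eligible
pair count.

## The synthetic-data generator

`simulation_spec()` / `simulate_dataset()` generate studies shaped
like a neonatal EWAS cohort: 237 samples, 1,423 variably methylated
CpGs, 19 environments, one binary covariate (sex), per-SNP minor
allele frequencies uniform on $[0.05, 0.5]$ with Hardy–Weinberg
dosages. The SNP panel defaults to 2,000 — scan cost is linear in it,
so nothing about model behaviour depends on running the full panel.
Environments are standard normal, a deliberate neutral choice.
Methylation is built on the logit scale: per-CpG baseline uniform in
$[0.2, 0.8]$, plus planted effects ($\beta E$, $\beta G$,
$\beta\,G \circ E$) and Gaussian noise (default SD 0.05), squashed
through the logistic function. Squashing rather than truncating keeps
values strictly inside $(0,1)$ without boundary atoms that would break
uniformity diagnostics. Ground truth is recorded on the latent scale;
planted-QTL CpGs are placed adjacent to (or overlapping, alternating)
their SNP so cis and disrupting classes occur in fixtures. Two
synthetic chromosomes guarantee trans pairs.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: linkage disequilibrium between
SNPs, spatial correlation of neighbouring CpGs, cell-type-mixture
structure, array batch effects, and non-Gaussian exposure
distributions. The generator demonstrates statistical correctness and
calibration of the engine, not robustness to those artefacts.

## Verification strategy and problem sizes

The test suite's end-to-end check runs all three scans on one seeded
complete-data study of 200 samples × 500 CpGs × 2,000 SNPs × 2
environments with one covariate — about three million oracle
regressions, the largest instance at which the deliberately naive
oracle sweep stays comfortable on one core — and requires agreement to
1e-8 relative on every emitted (β, t, p). Calibration is checked on
10,000 null Emodel tests (type-I error within the 99% binomial band
around 0.05, Kolmogorov–Smirnov uniformity, and $\lambda_{GC}$ near
1), the interaction test's size on 1,000 null repetitions at $n=200$,
and recovery on planted effects: ten cis methQTLs at latent
signal-to-noise ≥ 5 (β = ±0.2, noise SD 0.02, n = 300) must all clear
BH FDR < 0.05 with correct signs, and a planted interaction (latent
β = 0.1, chosen so the interaction t-statistic exceeds ~10 even at the
lowest admissible allele frequency) must rank first in its scan.
`scripts/acceptance.R` recomputes the same quantities from scratch at
slightly smaller scan sizes (200 CpGs × 400 SNPs) and writes them as
JSON.

## Known limitations

* Mean imputation is a speed-for-exactness trade-off, not a
  missing-data model; heavily incomplete features deserve a dedicated
  method.
* No permutation p-values, mixed models, kinship correction or
  logistic outcomes; p-values assume the Gaussian linear model.
* The r² reported per record is the squared (partial) correlation of
  the tested term, which is the quantity the "best fit per CpG"
  reduction (`best_per_outcome()`) ranks on; it equals the multiple R²
  only in the no-covariate case.
* A cross-only interaction model (no main effects) is intentionally
  not offered.
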