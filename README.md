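# gemscan

Fast genome-scale linear models for epigenome-wide association: scan
DNA methylation against environmental exposures (**Emodel**), against
genotype to map methQTLs (**Gmodel**), and against genotype-by-
environment interactions (**GxEmodel**) — millions to billions of
regressions on a single desktop core, with a naive per-pair
least-squares oracle built in to prove the fast path exact.

## Who this is for

EWAS and methQTL analysts with the usual data triplet — a CpG beta-value
matrix, an additive genotype dosage matrix (0/1/2) and a table of
exposures or phenotypes on shared samples — who need the full cross of
hypotheses tested, not just a cis window, and who cannot wait for
`lm()` to be called a billion times.

## The statistical core

Every scan fits, for outcome $y$ (one CpG row) and predictor $x$ (one
environment or SNP row),

$$y = \alpha + \beta x + \gamma\,\mathrm{cvrt} + \varepsilon,$$

but never one pair at a time. Both matrices are **residualized**
against the span of the intercept and covariates and scaled to unit
norm; after that the inner product of two rows is the partial
correlation $r$, and the slope test for $\beta$ is

$$t = r\sqrt{\frac{\mathrm{df}}{1-r^2}}, \qquad
\mathrm{df} = n - n_{\mathrm{cvrt}} - 2,$$

so a whole scan is one (blocked) matrix product. The interaction scan
tests $\beta$ in

$$M = \alpha + \gamma\,\mathrm{cvrt} + \delta E + \eta G + \beta\,(G
\circ E) + \varepsilon$$

via the partial correlation of the residualized outcome and product
term given the residualized genotype
($\mathrm{df} = n - n_{\mathrm{cvrt}} - 4$) — three inner products per
pair instead of a five-column least-squares fit, and algebraically
identical to it. Predictor matrices stream through in blocks
(`block_size` rows at a time), so memory stays bounded no matter how
many SNPs are scanned, and results are byte-identical for every block
size. Missing cells are mean-imputed per feature row (the documented
trade-off: rows with missing values shift slightly relative to a
complete-case fit; complete rows are exact). FDR is Benjamini–Hochberg
over the *attempted* test count, so p-value-thresholded output does not
inflate significance.

## Worked example

Simulate a study shaped like a neonatal EWAS cohort (237 samples, one
binary covariate), plant three methQTLs, and scan:

```r
library(gemscan)

spec <- simulation_spec(
  n_samples = 237, n_cpgs = 200, n_snps = 300, n_envs = 3,
  g_effects = tibble::tibble(cpg = 1:3, snp = c(10, 20, 30), beta = 0.3),
  seed = 2026)
dat <- simulate_dataset(spec)

scan <- run_gmodel(dat$M, dat$G, dat$cvrt, p_threshold = 1e-5,
                   cpg_ann = dat$cpg_ann, snp_ann = dat$snp_ann)
scan
#> <gem_scan: Gmodel> 60,000 tests computed of 60,000 attempted; 3 emitted; lambda_GC = NA
#> # A tibble: 3 × 9
#>   outcome_id predictor_id   beta t_stat   p_value       fdr r_squared saturated
#>   <chr>      <chr>         <dbl>  <dbl>     <dbl>     <dbl>     <dbl> <lgl>
#> 1 cg00003    rs00030      0.0655   66.9 1.62e-154 9.73e-150     0.950 FALSE
#> 2 cg00001    rs00010      0.0711   65.0 8.45e-152 2.54e-147     0.948 FALSE
#> 3 cg00002    rs00020      0.0589   63.8 5.02e-150 1.00e-145     0.946 FALSE
#> # ℹ 1 more variable: pair_class <chr>
```

All three planted pairs — and only those — clear the output threshold
at genome-wide significance. `beta` is the methylation change per
minor allele (here ~6–7 percentage points on the beta-value scale),
`fdr` is BH-adjusted over all 60,000 attempted tests, and
`pair_class` labels each pair cis / trans / disrupting from the BED
annotations (the planted pairs are placed on the SNP's chromosome, so
they come back cis or disrupting). `lambda_GC` is reported only when a
scan emits its full p-value set (`p_threshold = 1`):

```r
glance(run_emodel(dat$M, dat$E, dat$cvrt))
#> # A tibble: 1 × 6
#>   model  tests_attempted tests_computed emitted    df lambda_gc
#>   <chr>            <dbl>          <dbl>   <dbl> <int>     <dbl>
#> 1 Emodel             600            600     600   234     0.999
```

λ_GC ≈ 1 on the (null) environment scan: the tests are calibrated.
`autoplot(scan)` draws the QQ plot; `segregation_plot()` shows a
CpG's methylation against an exposure, one regression line per
genotype group (AA/AB/BB).

The same runs from a shell:

```sh
Rscript exec/gemscan simulate --seed 2026 --out data/
Rscript exec/gemscan gmodel --meth data/methylation.tsv \
    --geno data/genotype.tsv --cvrt data/covariate.tsv \
    --cpg-ann data/cpg_annotation.bed --snp-ann data/snp_annotation.bed \
    --out scan/
```

Every run directory gets `results.tsv`, a QQ plot, a `scan_report.txt`
with the test bookkeeping, and a `run_manifest.json` that reproduces
the run.

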