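#' Specify a synthetic methylation study
#'
#' Bundles every knob of the fixture generator. The defaults emulate
#' the structure of the benchmark cohort the scans are designed for —
#' 237 samples, 1,423 variably methylated CpGs, 19 environmental
#' factors, one binary covariate (sex), SNP minor-allele frequencies
#' uniform on \[0.05, 0.5\] — with the SNP panel scaled down to a
#' desk-size 2,000 (the full 708,365 is a matter of runtime, not of
#' model behaviour). Effects are planted on a latent (logit) scale;
#' see [simulate_methylation()].
#'
#' @param n_samples,n_cpgs,n_snps,n_envs,n_covariates Dimensions.
#' @param maf_range Range of per-SNP minor-allele frequencies.
#' @param e_effects,g_effects,gxe_effects Planted effects: tibbles with
#'   columns (`cpg`, `env`, `beta`), (`cpg`, `snp`, `beta`) and
#'   (`cpg`, `snp`, `env`, `beta`) respectively — feature indices, not
#'   IDs. `NULL` means no planted signal of that type.
#' @param noise_sd Gaussian noise SD on the latent methylation scale.
#' @param missing_rate Independent per-cell missingness probability
#'   applied to the methylation matrix by [simulate_dataset()].
#' @param seed Integer seed; every draw the generator makes is a
#'   deterministic function of it.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples = 237L, n_cpgs = 1423L,
                            n_snps = 2000L, n_envs = 19L,
                            n_covariates = 1L,
                            maf_range = c(0.05, 0.5),
                            e_effects = NULL, g_effects = NULL,
                            gxe_effects = NULL,
                            noise_sd = 0.05, missing_rate = 0,
                            seed = 1L) {
  stopifnot(n_samples >= 1, n_cpgs >= 1, n_snps >= 1, n_envs >= 1,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L],
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1)
  check_effects <- function(tab, cols, limits) {
    if (is.null(tab)) return(invisible())
    stopifnot(all(c(cols, "beta") %in% names(tab)))
    for (cc in cols) {
      if (any(tab[[cc]] < 1 | tab[[cc]] > limits[[cc]])) {
        stop("planted effect index out of range in column ", cc,
             call. = FALSE)
      }
    }
  }
  limits <- list(cpg = n_cpgs, snp = n_snps, env = n_envs)
  check_effects(e_effects, c("cpg", "env"), limits)
  check_effects(g_effects, c("cpg", "snp"), limits)
  check_effects(gxe_effects, c("cpg", "snp", "env"), limits)
  structure(list(n_samples = as.integer(n_samples),
                 n_cpgs = as.integer(n_cpgs),
                 n_snps = as.integer(n_snps),
                 n_envs = as.integer(n_envs),
                 n_covariates = as.integer(n_covariates),
                 maf_range = maf_range,
                 e_effects = e_effects, g_effects = g_effects,
                 gxe_effects = gxe_effects,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

sim_ids <- function(prefix, n) sprintf("%s%05d", prefix, seq_len(n))

with_sim_seed <- function(spec, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((spec$seed * 31L + offset) %% .Machine$integer.max)
  expr
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP gets a minor-allele frequency drawn uniformly from the
#' spec's `maf_range`; each sample's dosage is the sum of two binomial
#' allele draws at that frequency, giving hard calls in \{0, 1, 2\}.
#' Positions are placed uniformly on two synthetic chromosomes (`chr1`,
#' `chr2`, 1 Mb each) so that cis, trans and disrupting pair classes
#' all occur in fixtures; the annotation is attached as the
#' `"annotation"` attribute.
#'
#' @param spec A [simulation_spec()].
#' @return Genotype matrix (SNPs x samples) with an `"annotation"`
#'   attribute (tibble: `feature_id`, `chrom`, `start`, `end`) and
#'   `"maf"` attribute.
#' @export
simulate_genotypes <- function(spec) {
  with_sim_seed(spec, 1L, {
    ids <- sim_ids("rs", spec$n_snps)
    maf <- runif(spec$n_snps, spec$maf_range[1L], spec$maf_range[2L])
    g <- matrix(rbinom(spec$n_snps * spec$n_samples, 2L,
                       rep(maf, spec$n_samples)),
                nrow = spec$n_snps, ncol = spec$n_samples,
                dimnames = list(ids, sim_ids("s", spec$n_samples)))
    g <- g * 1.0
    ann <- tibble::tibble(
      feature_id = ids,
      chrom = sample(c("chr1", "chr2"), spec$n_snps, replace = TRUE),
      start = as.integer(floor(runif(spec$n_snps, 0, 1e6))))
    ann$end <- ann$start + 1L
    attr(g, "annotation") <- ann
    attr(g, "maf") <- maf
    attr(g, "kind") <- "genotype"
    g
  })
}

#' Simulate environmental factors
#'
#' Independent standard-normal exposures per environment and sample —
#' a neutral stand-in for quantitative exposures; the generator makes
#' no claim to any particular real exposure distribution.
#'
#' @param spec A [simulation_spec()].
#' @return Environment matrix (environments x samples).
#' @export
simulate_environments <- function(spec) {
  with_sim_seed(spec, 2L, {
    e <- matrix(rnorm(spec$n_envs * spec$n_samples),
                nrow = spec$n_envs,
                dimnames = list(sim_ids("env", spec$n_envs),
                                sim_ids("s", spec$n_samples)))
    attr(e, "kind") <- "environment"
    e
  })
}

#' Simulate covariates
#'
#' One binary row (sex, Bernoulli 1/2) plus standard-normal rows for
#' any further covariates.
#'
#' @param spec A [simulation_spec()].
#' @return Covariate matrix (covariates x samples), or `NULL` when the
#'   spec has none.
#' @export
simulate_covariates <- function(spec) {
  if (spec$n_covariates == 0L) return(NULL)
  with_sim_seed(spec, 3L, {
    k <- spec$n_covariates
    v <- rbind(rbinom(spec$n_samples, 1L, 0.5) * 1.0,
               if (k > 1L) matrix(rnorm((k - 1L) * spec$n_samples),
                                  nrow = k - 1L))
    dimnames(v) <- list(c("sex", if (k > 1L) sim_ids("cv", k - 1L)),
                        sim_ids("s", spec$n_samples))
    attr(v, "kind") <- "covariate"
    v
  })
}

#' Simulate methylation beta values with planted effects
#'
#' Each CpG has a baseline level drawn uniformly in \[0.2, 0.8\]. A
#' latent signal is assembled on the logit scale — the sum of every
#' planted effect (`beta * E`, `beta * G`, `beta * G * E`) plus
#' Gaussian noise — and squashed through the logistic function around
#' the baseline, so values stay strictly inside (0, 1) without the
#' boundary atoms truncation would create. The planted truth (latent
#' scale) is attached as the `"ground_truth"` attribute; CpG positions
#' on the two synthetic chromosomes as `"annotation"`. A fraction of
#' planted-QTL CpG positions is placed adjacent to its SNP so the
#' disrupting class occurs.
#'
#' @param spec A [simulation_spec()].
#' @param G Genotype matrix from [simulate_genotypes()].
#' @param E Environment matrix from [simulate_environments()].
#' @return Methylation matrix (CpGs x samples), values in (0, 1), with
#'   `"ground_truth"` and `"annotation"` attributes.
#' @export
simulate_methylation <- function(spec, G, E) {
  stopifnot(nrow(G) == spec$n_snps, nrow(E) == spec$n_envs,
            ncol(G) == spec$n_samples, ncol(E) == spec$n_samples)
  with_sim_seed(spec, 4L, {
    ids <- sim_ids("cg", spec$n_cpgs)
    baseline <- runif(spec$n_cpgs, 0.2, 0.8)
    latent <- matrix(rnorm(spec$n_cpgs * spec$n_samples,
                           sd = spec$noise_sd),
                     nrow = spec$n_cpgs,
                     dimnames = list(ids, colnames(G)))
    truth <- list()
    if (!is.null(spec$e_effects)) {
      tab <- spec$e_effects
      for (k in seq_len(nrow(tab))) {
        latent[tab$cpg[k], ] <- latent[tab$cpg[k], ] +
          tab$beta[k] * E[tab$env[k], ]
      }
      truth$e <- tibble::tibble(outcome_id = ids[tab$cpg],
                                predictor_id = rownames(E)[tab$env],
                                env_id = NA_character_,
                                beta = tab$beta, type = "E")
    }
    if (!is.null(spec$g_effects)) {
      tab <- spec$g_effects
      for (k in seq_len(nrow(tab))) {
        latent[tab$cpg[k], ] <- latent[tab$cpg[k], ] +
          tab$beta[k] * G[tab$snp[k], ]
      }
      truth$g <- tibble::tibble(outcome_id = ids[tab$cpg],
                                predictor_id = rownames(G)[tab$snp],
                                env_id = NA_character_,
                                beta = tab$beta, type = "G")
    }
    if (!is.null(spec$gxe_effects)) {
      tab <- spec$gxe_effects
      for (k in seq_len(nrow(tab))) {
        latent[tab$cpg[k], ] <- latent[tab$cpg[k], ] +
          tab$beta[k] * G[tab$snp[k], ] * E[tab$env[k], ]
      }
      truth$gxe <- tibble::tibble(outcome_id = ids[tab$cpg],
                                  predictor_id = rownames(G)[tab$snp],
                                  env_id = rownames(E)[tab$env],
                                  beta = tab$beta, type = "GxE")
    }
    m <- plogis(qlogis(baseline) + latent)
    # positions: uniform, but planted-QTL CpGs sit next to their SNP so
    # cis (and, for even planted indices, overlapping = disrupting)
    # pairs exist in fixtures
    snp_ann <- attr(G, "annotation")
    ann <- tibble::tibble(
      feature_id = ids,
      chrom = sample(c("chr1", "chr2"), spec$n_cpgs, replace = TRUE),
      start = as.integer(floor(runif(spec$n_cpgs, 0, 1e6))))
    if (!is.null(spec$g_effects) && !is.null(snp_ann)) {
      tab <- spec$g_effects
      for (k in seq_len(nrow(tab))) {
        i <- tab$cpg[k]
        s <- snp_ann[tab$snp[k], ]
        ann$chrom[i] <- s$chrom
        ann$start[i] <- if (k %% 2L == 0L) s$start else s$start + 50L
      }
    }
    ann$end <- ann$start + 2L
    attr(m, "annotation") <- ann
    attr(m, "ground_truth") <- dplyr::bind_rows(truth)
    attr(m, "kind") <- "methylation"
    m
  })
}

#' Mask cells at random
#'
#' Sets each cell to missing independently with probability `rate`.
#'
#' @param m A feature matrix.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed for the mask.
#' @return The matrix with `NA` in masked cells.
#' @export
apply_missingness <- function(m, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(m)
  a <- attributes(m)
  spec <- list(seed = as.integer(seed))
  with_sim_seed(spec, 5L, {
    mask <- runif(length(m)) < rate
    m[mask] <- NA_real_
  })
  attributes(m) <- a
  m
}

#' Generate a complete synthetic study, in memory or on disk
#'
#' Draws genotype, environment, covariate and methylation matrices
#' under one spec, applies the spec's missingness to the methylation
#' matrix, and (optionally) writes the whole study in the file dialects
#' the readers consume: matrix TSVs, BED4 annotations and a
#' `ground_truth.tsv` of planted effects.
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional output directory (created if needed). `NULL`
#'   keeps everything in memory.
#' @return A list: `M`, `G`, `E`, `cvrt`, `cpg_ann`, `snp_ann`,
#'   `ground_truth`, `spec`, and (when written) `paths`.
#' @export
simulate_dataset <- function(spec, dir = NULL) {
  G <- simulate_genotypes(spec)
  E <- simulate_environments(spec)
  cvrt <- simulate_covariates(spec)
  M <- simulate_methylation(spec, G, E)
  out <- list(M = apply_missingness(M, spec$missing_rate, spec$seed),
              G = G, E = E, cvrt = cvrt,
              cpg_ann = attr(M, "annotation"),
              snp_ann = attr(G, "annotation"),
              ground_truth = attr(M, "ground_truth"),
              spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_feature_matrix(out$M, p("methylation.tsv"))
    write_feature_matrix(out$G, p("genotype.tsv"))
    write_feature_matrix(out$E, p("environment.tsv"))
    if (!is.null(cvrt)) write_feature_matrix(cvrt, p("covariate.tsv"))
    write_bed4 <- function(ann, f) {
      readr::write_tsv(ann[, c("chrom", "start", "end", "feature_id")],
                       f, col_names = FALSE)
    }
    write_bed4(out$cpg_ann, p("cpg_annotation.bed"))
    write_bed4(out$snp_ann, p("snp_annotation.bed"))
    gt <- out$ground_truth
    if (is.null(gt)) {
      gt <- tibble::tibble(outcome_id = character(),
                           predictor_id = character(),
                           env_id = character(), beta = numeric(),
                           type = character())
    }
    readr::write_tsv(gt, p("ground_truth.tsv"))
    out$paths <- list(M = p("methylation.tsv"), G = p("genotype.tsv"),
                      E = p("environment.tsv"),
                      cvrt = if (!is.null(cvrt)) p("covariate.tsv"),
                      cpg_ann = p("cpg_annotation.bed"),
                      snp_ann = p("snp_annotation.bed"),
                      ground_truth = p("ground_truth.tsv"))
  }
  out
}
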