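test_that("model-count bookkeeping is the exact dimension product", {
  expect_identical(n_models(1423, 19), 27037)
  expect_identical(n_models(1423, 708365), 1008003395)
  expect_identical(n_models(2, 3, 2), 12)
})

test_that("Emodel enumerates every pair and matches the oracle", {
  study <- rand_study(n = 30, n_cpg = 5, n_snp = 1, n_env = 3,
                      n_cvrt = 1, seed = 21)
  res <- run_emodel(study$M, study$E, study$cvrt)
  expect_identical(nrow(res), 15L)
  expect_identical(glance(res)$tests_attempted, 15)
  expect_true(all(res$fdr >= res$p_value))
  expect_false(is.unsorted(res$p_value))

  ora <- oracle_scan(study$M, study$E, study$cvrt)
  ora <- match_oracle(res, ora)
  expect_lt(max_rel_diff(res$beta, ora$beta), 1e-8)
  expect_lt(max_rel_diff(res$t_stat, ora$t_stat), 1e-8)
  expect_lt(max_rel_diff(res$p_value, ora$p_value), 1e-8)
})

test_that("Emodel FDR is controlled within each environment family", {
  study <- rand_study(n = 40, n_cpg = 20, n_env = 2, n_cvrt = 0,
                      seed = 22)
  res <- run_emodel(study$M, study$E)
  for (env in unique(res$predictor_id)) {
    sub <- res[res$predictor_id == env, ]
    expect_equal(sub$fdr[order(sub$p_value)],
                 bh_fdr(sort(sub$p_value)), tolerance = 1e-12)
  }
})

test_that("an environment equal to a CpG row saturates", {
  set.seed(23)
  M <- fm(runif(3 * 20), 3, 20, "cg")
  E <- M[2, , drop = FALSE]
  rownames(E) <- "env1"
  res <- run_emodel(M, E)
  top <- res[res$outcome_id == "cg2", ]
  expect_true(top$saturated)
  expect_identical(top$p_value, .Machine$double.xmin)
})

test_that("planted environmental effects occupy the top ranks", {
  planted <- tibble::tibble(cpg = 1:5, env = 1L, beta = 2)
  spec <- simulation_spec(n_samples = 200, n_cpgs = 50, n_snps = 2,
                          n_envs = 1, n_covariates = 0,
                          e_effects = planted, noise_sd = 1, seed = 77)
  dat <- simulate_dataset(spec)
  res <- run_emodel(dat$M, dat$E)
  expect_setequal(res$outcome_id[1:5], sprintf("cg%05d", 1:5))
})

test_that("Gmodel recovers a noiseless affine relation exactly", {
  set.seed(24)
  g <- sample(0:2, 30, replace = TRUE) * 1.0
  M <- fm(0.1 + 0.2 * g, 1, 30, "cg")
  G <- fm(g, 1, 30, "rs")
  res <- run_gmodel(M, G, p_threshold = 1)
  expect_true(res$saturated)
  expect_identical(res$p_value, .Machine$double.xmin)
  expect_equal(res$beta, 0.2, tolerance = 1e-10)
})

test_that("Gmodel matches the oracle and classifies emitted pairs", {
  study <- rand_study(n = 30, n_cpg = 4, n_snp = 6, n_cvrt = 1,
                      seed = 25)
  cpg_ann <- tibble::tibble(feature_id = rownames(study$M),
                            chrom = c("chr1", "chr1", "chr2", "chr2"),
                            start = c(100L, 500L, 100L, 800L))
  cpg_ann$end <- cpg_ann$start + 2L
  snp_ann <- tibble::tibble(feature_id = rownames(study$G),
                            chrom = rep(c("chr1", "chr2"), 3),
                            start = c(100L, 300L, 900L, 101L, 50L, 799L))
  snp_ann$end <- snp_ann$start + 1L
  res <- run_gmodel(study$M, study$G, study$cvrt, p_threshold = 1,
                    cpg_ann = cpg_ann, snp_ann = snp_ann)
  expect_identical(nrow(res), 24L)
  ora <- match_oracle(res, oracle_scan(study$M, study$G, study$cvrt))
  expect_lt(max_rel_diff(res$beta, ora$beta), 1e-8)
  expect_lt(max_rel_diff(res$p_value, ora$p_value), 1e-8)

  # rs1 overlaps cg1 -> disrupting; same-chromosome pairs cis; rest trans
  expect_identical(
    res$pair_class[res$outcome_id == "cg1" & res$predictor_id == "rs1"],
    "disrupting")
  expect_identical(
    res$pair_class[res$outcome_id == "cg1" & res$predictor_id == "rs3"],
    "cis")
  expect_identical(
    res$pair_class[res$outcome_id == "cg1" & res$predictor_id == "rs2"],
    "trans")
})

test_that("Gmodel without annotations marks pairs unannotated", {
  study <- rand_study(n = 25, n_cpg = 2, n_snp = 2, n_cvrt = 0,
                      seed = 26)
  res <- run_gmodel(study$M, study$G, p_threshold = 1)
  expect_true(all(res$pair_class == "unannotated"))
})

test_that("thresholded Gmodel FDR uses the attempted-test family size", {
  study <- rand_study(n = 40, n_cpg = 10, n_snp = 20, n_cvrt = 0,
                      seed = 27)
  full <- run_gmodel(study$M, study$G, p_threshold = 1)
  thr <- 0.05
  part <- run_gmodel(study$M, study$G, p_threshold = thr)
  expect_identical(nrow(part), sum(full$p_value <= thr))
  i <- match(paste(part$outcome_id, part$predictor_id),
             paste(full$outcome_id, full$predictor_id))
  expect_equal(part$fdr, full$fdr[i], tolerance = 1e-12)
})

test_that("a cis-window restriction narrows the scan and its FDR family", {
  study <- rand_study(n = 30, n_cpg = 3, n_snp = 4, n_cvrt = 0,
                      seed = 28)
  cpg_ann <- tibble::tibble(feature_id = rownames(study$M),
                            chrom = "chr1",
                            start = c(0L, 1000L, 900000L))
  cpg_ann$end <- cpg_ann$start + 2L
  snp_ann <- tibble::tibble(feature_id = rownames(study$G),
                            chrom = c("chr1", "chr1", "chr2", "chr2"),
                            start = c(10L, 500000L, 5L, 10L))
  snp_ann$end <- snp_ann$start + 1L
  res <- run_gmodel(study$M, study$G, p_threshold = 1,
                    cpg_ann = cpg_ann, snp_ann = snp_ann,
                    cis_window = 5000L)
  # chr1 SNPs within 5 kb: rs1 of cg1/cg2, rs2 of nothing
  expect_setequal(paste(res$outcome_id, res$predictor_id),
                  c("cg1 rs1", "cg2 rs1"))
  expect_identical(glance(res)$tests_computed, 2)
})

test_that("GxE scan enumerates triplets and matches the oracle sweep", {
  study <- rand_study(n = 30, n_cpg = 2, n_snp = 3, n_env = 2,
                      n_cvrt = 1, seed = 29)
  res <- run_gxemodel(study$M, study$G, study$E, study$cvrt,
                      p_threshold = 1)
  expect_identical(nrow(res), 12L)
  expect_identical(glance(res)$tests_attempted, 12)
  ora <- match_oracle(res,
                      oracle_interaction_scan(study$M, study$G, study$E,
                                              study$cvrt))
  expect_lt(max_rel_diff(res$beta, ora$beta), 1e-8)
  expect_lt(max_rel_diff(res$t_stat, ora$t_stat), 1e-8)
  expect_lt(max_rel_diff(res$p_value, ora$p_value), 1e-8)
})

test_that("constant environments are skipped with a warning, not fatally", {
  study <- rand_study(n = 30, n_cpg = 2, n_snp = 2, n_env = 2,
                      n_cvrt = 0, seed = 30)
  study$E[2, ] <- 5
  expect_warning(
    res <- run_gxemodel(study$M, study$G, study$E, p_threshold = 1),
    "constant")
  expect_setequal(unique(res$env_id), "env1")
  expect_true("env2" %in% attr(res, "excluded"))
})

test_that("a planted interaction ranks first in its scan", {
  planted <- tibble::tibble(cpg = 3L, snp = 7L, env = 1L, beta = 0.6)
  spec <- simulation_spec(n_samples = 300, n_cpgs = 20, n_snps = 30,
                          n_envs = 2, n_covariates = 0,
                          gxe_effects = planted, noise_sd = 0.1,
                          seed = 31)
  dat <- simulate_dataset(spec)
  res <- run_gxemodel(dat$M, dat$G, dat$E, p_threshold = 1)
  expect_identical(res$outcome_id[1], sprintf("cg%05d", 3L))
  expect_identical(res$predictor_id[1], sprintf("rs%05d", 7L))
  expect_identical(res$env_id[1], sprintf("env%05d", 1L))
})

test_that("pair classification follows the chromosome/window rules", {
  ann <- function(chrom, start, end) {
    tibble::tibble(feature_id = "x", chrom = chrom, start = start,
                   end = end)
  }
  expect_identical(
    classify_pair(ann("chr1", 500L, 501L), ann("chr2", 500L, 501L)),
    "trans")
  expect_identical(
    classify_pair(ann("chr1", 10000L, 10001L),
                  ann("chr1", 900000L, 900001L)),
    "cis")
  expect_identical(
    classify_pair(ann("chr1", 100L, 101L), ann("chr1", 100L, 102L)),
    "disrupting")
  # window widens the disrupting call; it takes precedence over cis
  expect_identical(
    classify_pair(ann("chr1", 100L, 101L), ann("chr1", 150L, 152L),
                  window_bp = 50L),
    "disrupting")
  expect_identical(
    classify_pair(ann("chr1", 100L, 101L), ann("chr1", 150L, 152L),
                  window_bp = 48L),
    "cis")
  expect_identical(
    classify_pair(ann(NA_character_, 1L, 2L), ann("chr1", 1L, 2L)),
    "unannotated")
})

test_that("best_per_outcome keeps the largest r-squared with tie rules", {
  recs <- tibble::tibble(
    outcome_id = c("cg1", "cg1", "cg1", "cg2", "cg3", "cg3"),
    predictor_id = c("rs1", "rs2", "rs3", "rs9", "rsB", "rsA"),
    r_squared = c(0.1, 0.7, 0.3, 0.2, 0.5, 0.5),
    p_value = c(0.3, 0.001, 0.1, 0.2, 0.01, 0.01))
  best <- best_per_outcome(recs)
  expect_identical(nrow(best), 3L)
  expect_identical(best$predictor_id[best$outcome_id == "cg1"], "rs2")
  expect_identical(best$predictor_id[best$outcome_id == "cg2"], "rs9")
  # exact tie on r2 and p: lexicographically smaller predictor wins
  expect_identical(best$predictor_id[best$outcome_id == "cg3"], "rsA")

  tiep <- tibble::tibble(outcome_id = "cg1",
                         predictor_id = c("rs1", "rs2"),
                         r_squared = c(0.4, 0.4),
                         p_value = c(0.05, 0.01))
  expect_identical(best_per_outcome(tiep)$predictor_id, "rs2")
})

test_that("bh_fdr implements the step-up rule over the full family", {
  expect_identical(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # thresholded family: m larger than the p-values in hand
  expect_equal(bh_fdr(c(0.001, 0.002), m = 100),
               c(0.1, 0.1))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 0.2), m = 1), "at least")

  set.seed(33)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_identical(order(p), order(q, p))
  expect_true(all(q >= p & q <= 1))
})

test_that("scan results carry tidy/glance summaries", {
  study <- rand_study(n = 25, n_cpg = 3, n_env = 2, n_cvrt = 0,
                      seed = 34)
  res <- run_emodel(study$M, study$E)
  g <- glance(res)
  expect_identical(g$model, "Emodel")
  expect_identical(g$emitted, 6)
  td <- tidy(res)
  expect_false(inherits(td, "gem_scan"))
  expect_identical(nrow(td), 6L)
})
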