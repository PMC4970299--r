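# Shared helpers for the three genome-wide scans -------------------------

check_aligned <- function(mats) {
  ids <- lapply(mats, colnames)
  first <- ids[[1L]]
  same <- vapply(ids, identical, logical(1L), y = first)
  if (!all(same)) {
    stop("matrices are not sample-aligned (", names(mats)[!same][1L],
         " differs); run align_samples() first", call. = FALSE)
  }
  invisible(TRUE)
}

prepare_input <- function(m, impute_missing) {
  if (!anyNA(m)) {
    attr(m, "dropped_features") <- character(0)
    return(m)
  }
  if (!impute_missing) {
    stop("input contains missing values and impute_missing = FALSE",
         call. = FALSE)
  }
  impute_row_means(m)
}

# Vectorized r -> (t, p, saturated) on a matrix of correlations.
stats_from_r <- function(r, df) {
  sat <- abs(r) >= 1 - 1e-12
  t <- r * sqrt(df / (1 - r^2))
  t[sat] <- sign(r[sat]) * sqrt(df) / sqrt(.Machine$double.eps)
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  p[sat] <- .Machine$double.xmin
  list(t = t, p = p, saturated = sat)
}

finalize_scan <- function(records, summary, excluded) {
  records <- dplyr::arrange(records, .data$p_value, .data$outcome_id,
                            .data$predictor_id)
  attr(records, "scan_summary") <- summary
  attr(records, "excluded") <- excluded
  class(records) <- c("gem_scan", class(records))
  records
}

#' Number of regression models a scan enumerates
#'
#' The bookkeeping product: every outcome is tested against every
#' predictor (and, for the interaction scan, every environment), so
#' the attempted-model count is the exact product of the input
#' dimensions. Returned as a double because genome-scale products
#' (e.g. 1,423 CpGs x 708,365 SNPs = 1,008,003,395 models) overflow
#' 32-bit integers.
#'
#' @param n_outcomes Number of outcome features (CpGs).
#' @param n_predictors Number of predictors (environments or SNPs).
#' @param n_envs Number of environments (interaction scan only).
#' @return The model count as a double.
#' @export
n_models <- function(n_outcomes, n_predictors, n_envs = 1) {
  as.double(n_outcomes) * as.double(n_predictors) * as.double(n_envs)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR: for p-values ranked ascending,
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, clipped at 1 and returned in
#' the input order. `m` is the size of the test family, which may
#' exceed `length(p)` when only the smallest p-values of a thresholded
#' scan are in hand — the scans pass the attempted-test count so that
#' thresholded output does not inflate significance.
#'
#' @param p P-values in (0, 1\].
#' @param m Total number of tests in the family (default `length(p)`).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("m must be at least length(p)", call. = FALSE)
  }
  p.adjust(p, method = "BH", n = m)
}

# Interval gap between [s1, e1) and [s2, e2); 0 when they overlap.
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Classify SNP-CpG pairs as cis, trans or disrupting
#'
#' By chromosome co-location: different chromosomes give `trans`, the
#' same chromosome gives `cis`, unless the SNP interval lies within
#' `window_bp` of the CpG interval (interval gap `<= window_bp`), which
#' gives `disrupting` — a variant physically coinciding with the CpG
#' site destroys the dinucleotide itself. With the default
#' `window_bp = 0` only overlapping intervals are disrupting. Pairs
#' with either feature unannotated are `unannotated`.
#'
#' @param snp_ann,cpg_ann Annotation tibbles (`feature_id`, `chrom`,
#'   `start`, `end`) positionally matched (recycled if length 1).
#' @param window_bp Maximum gap (bp) for the disrupting call.
#' @return Character vector of `"cis"`, `"trans"`, `"disrupting"`,
#'   `"unannotated"`.
#' @export
classify_pair <- function(snp_ann, cpg_ann, window_bp = 0L) {
  n <- max(nrow(snp_ann), nrow(cpg_ann))
  if (nrow(snp_ann) == 1L) snp_ann <- snp_ann[rep(1L, n), ]
  if (nrow(cpg_ann) == 1L) cpg_ann <- cpg_ann[rep(1L, n), ]
  stopifnot(nrow(snp_ann) == nrow(cpg_ann))
  out <- rep("unannotated", n)
  known <- !is.na(snp_ann$chrom) & !is.na(cpg_ann$chrom)
  same <- known & snp_ann$chrom == cpg_ann$chrom
  out[known & !same] <- "trans"
  out[same] <- "cis"
  if (any(same)) {
    gap <- interval_distance(snp_ann$start[same], snp_ann$end[same],
                             cpg_ann$start[same], cpg_ann$end[same])
    out[same][gap <= window_bp] <- "disrupting"
  }
  out
}

annotate_pairs <- function(records, snp_ann, cpg_ann, window_bp) {
  if (is.null(snp_ann) || is.null(cpg_ann)) {
    records$pair_class <- "unannotated"
    return(records)
  }
  si <- match(records$predictor_id, snp_ann$feature_id)
  ci <- match(records$outcome_id, cpg_ann$feature_id)
  records$pair_class <- classify_pair(snp_ann[si, ], cpg_ann[ci, ],
                                      window_bp)
  records
}

# The three scans --------------------------------------------------------

#' Scan methylation against environmental factors (Emodel)
#'
#' For every CpG and every environment row, tests the slope of
#' `M ~ intercept + cvrt + E` via covariate projection and a single
#' inner product per pair. Each environment row is an independent scan
#' (its own model family): FDR is controlled per environment across its
#' CpGs. Records with `p_value <= p_threshold` are returned, sorted by
#' ascending p-value.
#'
#' @param M Methylation matrix, CpGs x samples.
#' @param E Environment matrix, environments x samples.
#' @param cvrt Optional covariate matrix, covariates x samples.
#' @param p_threshold Emit records with p at or below this (default 1,
#'   i.e. everything).
#' @param block_size CpG rows per correlation block.
#' @param impute_missing Mean-impute missing cells per feature row
#'   (default). With `FALSE`, missing data is an error.
#' @return A `gem_scan` tibble: `outcome_id`, `predictor_id` (the
#'   environment), `beta`, `t_stat`, `p_value`, `fdr`, `r_squared`,
#'   `saturated`. `glance()` returns the per-scan bookkeeping
#'   (tests attempted / computed / emitted, genomic inflation).
#' @export
run_emodel <- function(M, E, cvrt = NULL, p_threshold = 1,
                       block_size = 1000L, impute_missing = TRUE) {
  check_aligned(c(list(M = M, E = E), if (!is.null(cvrt)) list(cvrt = cvrt)))
  n_attempted <- n_models(nrow(M), nrow(E))
  M <- prepare_input(M, impute_missing)
  E <- prepare_input(E, impute_missing)
  dropped <- c(attr(M, "dropped_features"), attr(E, "dropped_features"))
  Y <- residualize_standardize(M, cvrt)
  if (length(Y$feature_ids) == 0L) {
    stop("no CpG rows left after degeneracy filtering", call. = FALSE)
  }
  Xe <- residualize_standardize(E, cvrt)
  skipped_envs <- Xe$degenerate_ids
  for (e in skipped_envs) {
    warning("environment ", e,
            " is degenerate after covariate projection; skipped",
            call. = FALSE)
  }
  df <- Y$df_resid
  recs <- vector("list", length(Xe$feature_ids))
  for (j in seq_along(Xe$feature_ids)) {
    xv <- Xe$values[j, , drop = FALSE]
    r <- as.vector(tcrossprod(Y$values, rbind(xv, xv))[, 1L])
    r <- pmin(1, pmax(-1, r))
    st <- stats_from_r(r, df)
    fdr <- bh_fdr(st$p, m = length(r))
    keep <- st$p <= p_threshold
    recs[[j]] <- tibble::tibble(
      outcome_id = Y$feature_ids[keep],
      predictor_id = Xe$feature_ids[j],
      beta = (r * Y$norms / Xe$norms[j])[keep],
      t_stat = st$t[keep], p_value = st$p[keep], fdr = fdr[keep],
      r_squared = r[keep]^2, saturated = st$saturated[keep])
  }
  records <- dplyr::bind_rows(recs)
  n_computed <- length(Y$feature_ids) * length(Xe$feature_ids)
  summary <- tibble::tibble(
    model = "Emodel",
    tests_attempted = n_attempted,
    tests_computed = as.double(n_computed),
    emitted = as.double(nrow(records)),
    df = df,
    lambda_gc = if (p_threshold >= 1 && nrow(records) > 0L) {
      lambda_gc(records$p_value)
    } else NA_real_)
  finalize_scan(records, summary,
                excluded = c(dropped, Y$degenerate_ids, skipped_envs))
}

#' Genome-wide methQTL scan (Gmodel)
#'
#' Tests every CpG against every SNP under
#' `M ~ intercept + cvrt + G` (additive dosage coding), blockwise over
#' SNPs so memory stays bounded at `block_size` x `n_CpG` correlations
#' regardless of scan size. Only records with
#' `p_value <= p_threshold` are kept (a genome-scale scan emits
#' billions of rows otherwise); FDR uses the full attempted-test count,
#' so thresholding does not inflate significance. With annotations,
#' each emitted pair is classified cis / trans / disrupting; an
#' optional `cis_window` restricts the scan to same-chromosome pairs
#' within that distance.
#'
#' @inheritParams run_emodel
#' @param G Genotype dosage matrix, SNPs x samples.
#' @param cpg_ann,snp_ann Optional annotation tibbles (see
#'   [read_annotation()]).
#' @param disrupting_window_bp Gap (bp) at or under which a
#'   same-chromosome pair is called disrupting.
#' @param cis_window Optional: test only same-chromosome pairs whose
#'   interval gap is `<= cis_window` bp (requires both annotations).
#' @return A `gem_scan` tibble as in [run_emodel()], plus `pair_class`.
#' @export
run_gmodel <- function(M, G, cvrt = NULL, p_threshold = 1e-5,
                       block_size = 1000L, impute_missing = TRUE,
                       cpg_ann = NULL, snp_ann = NULL,
                       disrupting_window_bp = 0L, cis_window = NULL) {
  check_aligned(c(list(M = M, G = G), if (!is.null(cvrt)) list(cvrt = cvrt)))
  if (!is.null(cis_window) && (is.null(cpg_ann) || is.null(snp_ann))) {
    stop("cis_window requires both cpg_ann and snp_ann", call. = FALSE)
  }
  n_attempted <- n_models(nrow(M), nrow(G))
  M <- prepare_input(M, impute_missing)
  G <- prepare_input(G, impute_missing)
  dropped <- c(attr(M, "dropped_features"), attr(G, "dropped_features"))
  Y <- residualize_standardize(M, cvrt)
  if (length(Y$feature_ids) == 0L) {
    stop("no CpG rows left after degeneracy filtering", call. = FALSE)
  }
  X <- residualize_standardize(G, cvrt)
  df <- Y$df_resid
  ny <- length(Y$feature_ids)
  nx <- length(X$feature_ids)
  cis_mask_info <- if (!is.null(cis_window)) {
    list(snp = ann_lookup(snp_ann, X$feature_ids),
         cpg = ann_lookup(cpg_ann, Y$feature_ids))
  }
  n_eligible <- 0
  recs <- list()
  starts <- seq(1L, nx, by = min(block_size, nx))
  for (s in starts) {
    e <- min(s + block_size - 1, nx)
    r <- block_tcrossprod(X$values, s, e, Y$values)
    r[r > 1] <- 1; r[r < -1] <- -1
    st <- stats_from_r(r, df)
    keep <- st$p <= p_threshold
    if (!is.null(cis_window)) {
      elig <- cis_eligible(cis_mask_info, s, e, cis_window)
      n_eligible <- n_eligible + sum(elig)
      keep <- keep & elig
    }
    if (any(keep)) {
      idx <- which(keep, arr.ind = TRUE)
      i <- idx[, 1L]; j <- idx[, 2L]
      recs[[length(recs) + 1L]] <- tibble::tibble(
        outcome_id = Y$feature_ids[j],
        predictor_id = X$feature_ids[s:e][i],
        beta = r[keep] * Y$norms[j] / X$norms[s:e][i],
        t_stat = st$t[keep], p_value = st$p[keep],
        r_squared = r[keep]^2, saturated = st$saturated[keep])
    }
  }
  records <- dplyr::bind_rows(recs)
  if (nrow(records) == 0L) {
    records <- tibble::tibble(outcome_id = character(), predictor_id = character(),
                              beta = numeric(), t_stat = numeric(),
                              p_value = numeric(), r_squared = numeric(),
                              saturated = logical())
  }
  m_family <- if (is.null(cis_window)) as.double(ny) * nx else n_eligible
  records$fdr <- bh_fdr(records$p_value, m = max(m_family, nrow(records)))
  records <- annotate_pairs(records, snp_ann, cpg_ann, disrupting_window_bp)
  records <- records[, c("outcome_id", "predictor_id", "beta", "t_stat",
                         "p_value", "fdr", "r_squared", "saturated",
                         "pair_class")]
  summary <- tibble::tibble(
    model = "Gmodel",
    tests_attempted = n_attempted,
    tests_computed = m_family,
    emitted = as.double(nrow(records)),
    df = df,
    # inflation is only estimable from the full p-value set
    lambda_gc = if (p_threshold >= 1 && nrow(records) > 0L) {
      lambda_gc(records$p_value)
    } else NA_real_)
  finalize_scan(records, summary,
                excluded = c(dropped, Y$degenerate_ids, X$degenerate_ids))
}

ann_lookup <- function(ann, ids) {
  i <- match(ids, ann$feature_id)
  list(chrom = ann$chrom[i], start = ann$start[i], end = ann$end[i])
}

# Eligibility mask (SNP block x CpGs) for a cis-window restricted scan.
cis_eligible <- function(info, s, e, window) {
  sc <- info$snp$chrom[s:e]; ss <- info$snp$start[s:e]
  se <- info$snp$end[s:e]
  same <- outer(sc, info$cpg$chrom, `==`)
  same[is.na(same)] <- FALSE
  gap <- pmax(0, outer(ss, info$cpg$start, pmax) -
                outer(se, info$cpg$end, pmin))
  same & gap <= window
}

#' Genome-wide genotype-by-environment interaction scan (GxEmodel)
#'
#' For every (CpG, SNP, environment) triplet, tests the interaction
#' coefficient of the full model
#' `M ~ intercept + cvrt + E + G + G*E` without fitting it: per
#' environment, methylation, genotype and the elementwise product G*E
#' are residualized against \{intercept, cvrt, E\}, and the interaction
#' t-statistic is recovered from three inner products per pair as a
#' partial correlation (see [interaction_stat()]). SNPs are processed
#' in blocks. Constant or degenerate environments are skipped with a
#' warning; SNPs whose product term is collinear with the genotype
#' (e.g. dosage all 0/2 with a binary environment) are excluded and
#' itemized. FDR is controlled across the whole scan.
#'
#' @inheritParams run_gmodel
#' @param E Environment matrix, environments x samples.
#' @return A `gem_scan` tibble as in [run_emodel()], with `env_id`;
#'   `beta` is the interaction slope.
#' @export
run_gxemodel <- function(M, G, E, cvrt = NULL, p_threshold = 1e-5,
                         block_size = 1000L, impute_missing = TRUE) {
  check_aligned(c(list(M = M, G = G, E = E),
                  if (!is.null(cvrt)) list(cvrt = cvrt)))
  n_attempted <- n_models(nrow(M), nrow(G), nrow(E))
  M <- prepare_input(M, impute_missing)
  G <- prepare_input(G, impute_missing)
  E <- prepare_input(E, impute_missing)
  dropped <- c(attr(M, "dropped_features"), attr(G, "dropped_features"),
               attr(E, "dropped_features"))
  n <- ncol(M)
  k <- if (is.null(cvrt)) 0L else nrow(cvrt)
  df <- n - k - 4L
  if (df < 1L) stop("not enough samples for the interaction scan",
                    call. = FALSE)
  excluded <- dropped
  n_computed <- 0
  recs <- list()
  for (l in seq_len(nrow(E))) {
    e_row <- E[l, ]
    env_id <- rownames(E)[l]
    if (max(e_row) - min(e_row) == 0) {
      warning("environment ", env_id, " is constant; skipped",
              call. = FALSE)
      excluded <- c(excluded, env_id)
      next
    }
    Z <- rbind(cvrt, env = e_row)
    Y <- residualize_standardize(M, Z)
    Gs <- residualize_standardize(G, Z)
    H <- G * rep(e_row, each = nrow(G))
    rownames(H) <- rownames(G)
    Hs <- residualize_standardize(H, Z)
    common <- intersect(Gs$feature_ids, Hs$feature_ids)
    gi <- match(common, Gs$feature_ids)
    hi <- match(common, Hs$feature_ids)
    r_gh <- rowSums(Gs$values[gi, , drop = FALSE] *
                      Hs$values[hi, , drop = FALSE])
    ok <- abs(r_gh) < 1 - 1e-12
    excluded <- c(excluded, Y$degenerate_ids,
                  setdiff(rownames(G), common[ok]))
    common <- common[ok]; gi <- gi[ok]; hi <- hi[ok]; r_gh <- r_gh[ok]
    ny <- length(Y$feature_ids)
    nx <- length(common)
    if (ny == 0L || nx == 0L) next
    n_computed <- n_computed + as.double(ny) * nx
    Gv <- Gs$values[gi, , drop = FALSE]
    Hv <- Hs$values[hi, , drop = FALSE]
    Hnorm <- Hs$norms[hi]
    starts <- seq(1L, nx, by = min(block_size, nx))
    for (s in starts) {
      e2 <- min(s + block_size - 1, nx)
      r_yg <- block_tcrossprod(Gv, s, e2, Y$values)
      r_yh <- block_tcrossprod(Hv, s, e2, Y$values)
      rgh_blk <- r_gh[s:e2]
      num <- r_yh - r_yg * rgh_blk
      r_p <- num / sqrt((1 - r_yg^2) * (1 - rgh_blk^2))
      r_p[r_p > 1] <- 1; r_p[r_p < -1] <- -1
      st <- stats_from_r(r_p, df)
      keep <- st$p <= p_threshold
      if (any(keep)) {
        idx <- which(keep, arr.ind = TRUE)
        i <- idx[, 1L]; j <- idx[, 2L]
        beta <- Y$norms[j] * num[keep] /
          (Hnorm[s:e2][i] * (1 - rgh_blk[i]^2))
        recs[[length(recs) + 1L]] <- tibble::tibble(
          outcome_id = Y$feature_ids[j],
          predictor_id = common[s:e2][i],
          env_id = env_id,
          beta = beta, t_stat = st$t[keep], p_value = st$p[keep],
          r_squared = r_p[keep]^2, saturated = st$saturated[keep])
      }
    }
  }
  records <- dplyr::bind_rows(recs)
  if (nrow(records) == 0L) {
    records <- tibble::tibble(outcome_id = character(), predictor_id = character(),
                              env_id = character(), beta = numeric(),
                              t_stat = numeric(), p_value = numeric(),
                              r_squared = numeric(), saturated = logical())
  }
  records$fdr <- bh_fdr(records$p_value,
                        m = max(n_computed, nrow(records), 1))
  records <- records[, c("outcome_id", "predictor_id", "env_id", "beta",
                         "t_stat", "p_value", "fdr", "r_squared",
                         "saturated")]
  summary <- tibble::tibble(
    model = "GxEmodel",
    tests_attempted = n_attempted,
    tests_computed = n_computed,
    emitted = as.double(nrow(records)),
    df = df,
    lambda_gc = if (p_threshold >= 1 && nrow(records) > 0L) {
      lambda_gc(records$p_value)
    } else NA_real_)
  finalize_scan(records, summary, excluded = unique(excluded))
}

#' Best association per outcome
#'
#' Reduces a scan's records to one per CpG: the record with the largest
#' `r_squared`; exact ties go to the smaller p-value, then to the
#' lexicographically smallest predictor ID. This is the "best fit"
#' reduction used to summarise a methQTL map.
#'
#' @param records A `gem_scan` tibble (or any data frame with
#'   `outcome_id`, `predictor_id`, `r_squared`, `p_value`).
#' @return One record per outcome.
#' @export
best_per_outcome <- function(records) {
  records |>
    dplyr::arrange(dplyr::desc(.data$r_squared), .data$p_value,
                   .data$predictor_id) |>
    dplyr::distinct(.data$outcome_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$p_value, .data$outcome_id, .data$predictor_id)
}

#' Scan bookkeeping summary
#'
#' @param x A `gem_scan` result.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `tests_attempted`,
#'   `tests_computed`, `emitted`, `df`, `lambda_gc`.
#' @export
glance.gem_scan <- function(x, ...) {
  attr(x, "scan_summary")
}

#' Association records of a scan as a plain tibble
#'
#' @param x A `gem_scan` result.
#' @param ... Unused.
#' @return The records, without scan attributes.
#' @export
tidy.gem_scan <- function(x, ...) {
  out <- x
  attr(out, "scan_summary") <- NULL
  attr(out, "excluded") <- NULL
  class(out) <- setdiff(class(out), "gem_scan")
  out
}

#' @export
print.gem_scan <- function(x, ...) {
  s <- attr(x, "scan_summary")
  cat("<gem_scan: ", s$model, "> ",
      format(s$tests_computed, big.mark = ","), " tests computed of ",
      format(s$tests_attempted, big.mark = ","), " attempted; ",
      format(s$emitted, big.mark = ","), " emitted; lambda_GC = ",
      signif(s$lambda_gc, 4), "\n", sep = "")
  NextMethod()
}
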