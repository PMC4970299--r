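#' Impute missing cells with the feature's mean
#'
#' Replaces each missing cell by the mean of the non-missing values in
#' the same feature row, the policy the matrix fast path needs before
#' projection (an inner product cannot skip cells pairwise the way a
#' per-pair regression can). Rows with no observed value at all are
#' dropped and reported via the `"dropped_features"` attribute.
#'
#' Mean imputation keeps the fast path exact for complete rows but
#' shifts p-values slightly for rows that had missing cells, relative
#' to a complete-case per-pair fit; see the methods vignette.
#'
#' @param m A feature matrix (features x samples) possibly containing `NA`.
#' @return The matrix with no missing cells; attribute
#'   `"dropped_features"` lists all-missing rows that were removed.
#' @export
impute_row_means <- function(m) {
  stopifnot(is.matrix(m))
  kind <- attr(m, "kind")
  obs <- !is.na(m)
  n_obs <- rowSums(obs)
  dropped <- rownames(m)[n_obs == 0L]
  if (length(dropped) > 0L) {
    m <- m[n_obs > 0L, , drop = FALSE]
  }
  if (anyNA(m)) {
    means <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- means[idx[, 1L]]
  }
  attr(m, "kind") <- kind
  attr(m, "dropped_features") <- dropped
  m
}

#' Project out covariates and standardize feature rows
#'
#' The engine's standardization step: every feature row is projected
#' onto the orthogonal complement of the span of the intercept and the
#' covariate rows, then scaled to unit Euclidean norm. After this, the
#' plain inner product of a standardized outcome row and a standardized
#' predictor row equals the partial correlation controlling for the
#' covariates, which carries the full multiple-regression t-test for
#' the predictor's slope (see [t_from_r()]).
#'
#' An intercept is always added implicitly, so covariate rows must not
#' contain a constant row (that would be silently rank-deficient); a
#' constant covariate row, or any linearly dependent covariate, is
#' rejected by name. Rows whose residual after projection is numerically
#' zero (norm below `1e-10` relative to the input row) carry no testable
#' signal and are set aside in `degenerate_ids`.
#'
#' @param m Feature matrix (features x samples), no missing values.
#' @param cvrt Optional covariate matrix (covariates x samples), sample
#'   columns aligned with `m`. `NULL` means intercept only.
#' @return An object of class `standardized_matrix`: a list with
#'   `values` (kept rows, residualized, unit norm), `feature_ids`,
#'   `norms` (residual norms before scaling, needed to recover slopes
#'   on the original scale), `degenerate_ids`, `df_resid`
#'   (`n - n_cvrt - 2`), `n_covariates` and `n_samples`.
#' @export
residualize_standardize <- function(m, cvrt = NULL) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) {
    stop("matrix contains missing values; impute (impute_row_means) or ",
         "drop them first", call. = FALSE)
  }
  n <- ncol(m)
  k <- if (is.null(cvrt)) 0L else nrow(cvrt)
  if (k > 0L) {
    stopifnot(is.matrix(cvrt), ncol(cvrt) == n)
    if (anyNA(cvrt)) {
      stop("covariate matrix contains missing values", call. = FALSE)
    }
    const <- apply(cvrt, 1L, function(x) max(x) - min(x) == 0)
    if (any(const)) {
      stop("constant covariate row(s) ",
           paste(rownames(cvrt)[const], collapse = ", "),
           ": the intercept is added implicitly, remove them",
           call. = FALSE)
    }
  }
  Z <- cbind(`(intercept)` = rep(1, n),
             if (k > 0L) t(cvrt))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dep <- colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop("rank-deficient covariates: ", paste(dep, collapse = ", "),
         " lie in the span of the others", call. = FALSE)
  }
  Q <- qr.Q(qz)
  resid <- m - (m %*% Q) %*% t(Q)
  norms <- unname(sqrt(rowSums(resid^2)))
  in_norms <- unname(sqrt(rowSums(m^2)))
  keep <- norms >= 1e-10 * pmax(1, in_norms)
  df_resid <- n - (1L + k) - 1L
  if (df_resid < 1L) {
    stop("not enough samples: ", n, " samples with ", k,
         " covariate(s) leave ", df_resid, " residual df", call. = FALSE)
  }
  structure(list(
    values = resid[keep, , drop = FALSE] / norms[keep],
    feature_ids = rownames(m)[keep],
    norms = norms[keep],
    degenerate_ids = rownames(m)[!keep],
    df_resid = df_resid,
    n_covariates = k,
    n_samples = n
  ), class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat("<standardized_matrix> ", length(x$feature_ids), " features x ",
      x$n_samples, " samples, ", x$n_covariates,
      " covariate(s) projected, df_resid = ", x$df_resid, "\n", sep = "")
  if (length(x$degenerate_ids) > 0L) {
    cat("  degenerate (zero residual variance): ",
        paste(head(x$degenerate_ids, 5L), collapse = ", "),
        if (length(x$degenerate_ids) > 5L) " ...", "\n", sep = "")
  }
  invisible(x)
}

#' Blockwise correlation of two standardized matrices
#'
#' Entry (i, j) is the inner product of standardized row i of `X` and
#' standardized row j of `Y` — the (partial) correlation of the two
#' underlying features given the projected covariates. `X` is processed
#' in blocks of `block_size` rows so peak memory is bounded by
#' `block_size * nrow(Y)` result entries plus one block of `X`;
#' the result is identical for every block size. Values are clipped
#' to \[-1, 1\] against floating-point drift.
#'
#' @param X,Y `standardized_matrix` objects sharing the sample dimension.
#' @param block_size Rows of `X` per block. `Inf` means one block.
#' @return Correlation matrix (`nrow(X)` x `nrow(Y)`) with feature-ID
#'   dimnames.
#' @export
correlate_block <- function(X, Y, block_size = 1000L) {
  stopifnot(inherits(X, "standardized_matrix"),
            inherits(Y, "standardized_matrix"))
  if (X$n_samples != Y$n_samples) {
    stop("sample-dimension mismatch: ", X$n_samples, " vs ", Y$n_samples,
         call. = FALSE)
  }
  stopifnot(block_size >= 1)
  nx <- nrow(X$values)
  out <- matrix(NA_real_, nx, nrow(Y$values),
                dimnames = list(X$feature_ids, Y$feature_ids))
  starts <- seq(1L, max(nx, 1L), by = min(block_size, .Machine$integer.max))
  for (s in starts) {
    if (s > nx) break
    e <- min(s + block_size - 1, nx)
    out[s:e, ] <- block_tcrossprod(X$values, s, e, Y$values)
  }
  out[out > 1] <- 1
  out[out < -1] <- -1
  out
}

# tcrossprod of X[s:e, ] with Y, padding single-row blocks to two rows:
# the BLAS dispatches a different (vector) kernel for one-row operands
# whose summation order differs at the last ulp, which would make
# results depend on block_size.
block_tcrossprod <- function(X, s, e, Y) {
  if (s == e) {
    tcrossprod(X[c(s, s), , drop = FALSE], Y)[1L, , drop = FALSE]
  } else {
    tcrossprod(X[s:e, , drop = FALSE], Y)
  }
}

#' Convert correlations to t statistics and p-values
#'
#' For a (partial) correlation `r` on `df` residual degrees of freedom,
#' the slope t-test of the corresponding regression is
#' `t = r * sqrt(df / (1 - r^2))`, with a two-sided p-value from the t
#' distribution on `df` degrees of freedom. A correlation within
#' `1e-12` of +/-1 would give an infinite statistic; such entries are
#' reported at the smallest representable positive p with
#' `saturated = TRUE`.
#'
#' @param r Numeric vector (or matrix) of correlations in \[-1, 1\].
#' @param df Residual degrees of freedom (single integer >= 1).
#' @return A tibble with columns `r`, `t`, `p`, `df`, `saturated`,
#'   in the input order of `r`.
#' @export
t_from_r <- function(r, df) {
  if (length(df) != 1L || is.na(df) || df < 1) {
    stop("df must be a single integer >= 1", call. = FALSE)
  }
  r <- as.numeric(r)
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  sat <- abs(r) >= 1 - 1e-12
  t <- ifelse(sat, sign(r) * sqrt(df) / sqrt(.Machine$double.eps),
              r * sqrt(df / (1 - r^2)))
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  p[sat] <- .Machine$double.xmin
  tibble::tibble(r = r, t = t, p = p, df = as.integer(df), saturated = sat)
}

#' Test one genotype-by-environment interaction
#'
#' Tests the coefficient of the elementwise product G*E in the full
#' model `M ~ intercept + cvrt + E + G + G*E`, without fitting it: all
#' three rows (outcome, genotype, product) are residualized against
#' \{intercept, cvrt, E\}, and the interaction t-test equals the
#' partial correlation of the residualized outcome and product given
#' the residualized genotype,
#' `r_p = (r_yh - r_yg * r_gh) / sqrt((1 - r_yg^2) (1 - r_gh^2))`,
#' with `t = r_p * sqrt(df / (1 - r_p^2))` on `df = n - n_cvrt - 4`.
#' This is algebraically identical to the interaction-term t of the
#' explicit least-squares fit (the oracle cross-checks this).
#'
#' @param y_row Outcome (methylation) vector, no missing values.
#' @param g_row Genotype dosage vector.
#' @param e_row Environment vector.
#' @param cvrt Optional covariate matrix (covariates x samples).
#' @return A one-row tibble: `beta` (interaction slope on the original
#'   scale), `r` (partial correlation), `t`, `p`, `df`, `saturated`.
#' @export
interaction_stat <- function(y_row, g_row, e_row, cvrt = NULL) {
  n <- length(y_row)
  stopifnot(length(g_row) == n, length(e_row) == n)
  if (anyNA(y_row) || anyNA(g_row) || anyNA(e_row) ||
      (!is.null(cvrt) && anyNA(cvrt))) {
    stop("inputs contain missing values; impute first", call. = FALSE)
  }
  if (max(e_row) - min(e_row) == 0) {
    stop("degenerate interaction: environment is constant, the product ",
         "G*E is collinear with the genotype", call. = FALSE)
  }
  k <- if (is.null(cvrt)) 0L else nrow(cvrt)
  Z <- rbind(cvrt, env = e_row)
  m <- rbind(y = y_row, g = g_row, h = g_row * e_row)
  std <- residualize_standardize(m, Z)
  if (!all(c("y", "g", "h") %in% std$feature_ids)) {
    stop("degenerate interaction: ",
         paste(std$degenerate_ids, collapse = ", "),
         " has zero residual variance given {intercept, cvrt, E}",
         call. = FALSE)
  }
  v <- std$values[c("y", "g", "h"), ]
  nm <- std$norms[match(c("y", "g", "h"), std$feature_ids)]
  r_yg <- sum(v[1L, ] * v[2L, ])
  r_yh <- sum(v[1L, ] * v[3L, ])
  r_gh <- sum(v[2L, ] * v[3L, ])
  if (abs(r_gh) >= 1 - 1e-12) {
    stop("degenerate interaction: product term collinear with genotype ",
         "(|r| = 1)", call. = FALSE)
  }
  df <- n - k - 4L
  if (df < 1L) stop("not enough samples for the interaction test",
                    call. = FALSE)
  r_p <- (r_yh - r_yg * r_gh) / sqrt((1 - r_yg^2) * (1 - r_gh^2))
  r_p <- min(1, max(-1, r_p))
  st <- t_from_r(r_p, df)
  # slope of the interaction term on the original scale: project the
  # genotype direction out of the product residual first
  beta <- unname(nm[1L] * (r_yh - r_yg * r_gh) / (nm[3L] * (1 - r_gh^2)))
  tibble::tibble(beta = beta, r = st$r, t = st$t, p = st$p, df = st$df,
                 saturated = st$saturated)
}
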