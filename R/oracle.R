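#' Naive per-pair least-squares fit (reference implementation)
#'
#' The explicit regression `y ~ 1 + x + cvrt`, fitted pair by pair by
#' orthogonal decomposition, exactly as a sequential `lm()` sweep would
#' do it. This is the correctness oracle for the matrix fast path: on
#' complete data the two must agree on (beta, t, p) to floating-point
#' accuracy, and the test suite treats any disagreement as a build
#' failure. It is deliberately simple and slow — never used by the
#' scans themselves.
#'
#' Missing values are handled by complete-case deletion (the rows a
#' plain `lm()` would drop), which is what makes the documented
#' divergence from mean imputation on incomplete rows observable.
#'
#' @param y Outcome vector.
#' @param x Predictor vector.
#' @param cvrt Optional covariate matrix (covariates x samples).
#' @return An object of class `ols_fit`: a list with `coefficients`
#'   (intercept, slope, covariate terms), `beta`, `se`, `t`, `p` (for
#'   the predictor slope), `df`, `r_squared` (multiple R^2),
#'   `residuals`, `n_used`.
#' @export
lm_single <- function(y, x, cvrt = NULL) {
  X <- cbind(`(intercept)` = 1, x = x,
             if (!is.null(cvrt)) t(cvrt))
  oracle_fit(y, X, term = 2L)
}

#' Naive least-squares fit of the full interaction model
#'
#' The explicit regression `y ~ 1 + g + e + g:e + cvrt`; `t` and `p`
#' are reported for the interaction coefficient. Reference for
#' [interaction_stat()] and the genotype-by-environment scan.
#'
#' @param y Outcome vector.
#' @param g Genotype dosage vector.
#' @param e Environment vector.
#' @param cvrt Optional covariate matrix (covariates x samples).
#' @return An `ols_fit` (see [lm_single()]); `beta`, `t`, `p` refer to
#'   the `g:e` product term.
#' @export
lm_interaction_single <- function(y, g, e, cvrt = NULL) {
  X <- cbind(`(intercept)` = 1, g = g, e = e, `g:e` = g * e,
             if (!is.null(cvrt)) t(cvrt))
  oracle_fit(y, X, term = 4L)
}

# QR fit of y on design X; returns stats for column `term`.
oracle_fit <- function(y, X, term) {
  cc <- complete.cases(y, X)
  y <- y[cc]
  X <- X[cc, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p) {
    stop("not enough complete observations (", n, ") for ", p,
         " coefficients", call. = FALSE)
  }
  fit <- .lm.fit(X, y)
  if (fit$rank < p) {
    stop("singular design: column ",
         paste(colnames(X)[fit$pivot[(fit$rank + 1L):p]], collapse = ", "),
         " is collinear", call. = FALSE)
  }
  res <- fit$residuals
  df <- n - p
  rss <- sum(res^2)
  sigma2 <- rss / df
  # (X'X)^{-1} from the R factor of the pivoted QR
  R <- fit$qr[seq_len(p), , drop = FALSE]
  R[lower.tri(R)] <- 0
  xtx_inv <- chol2inv(R)[order(fit$pivot), order(fit$pivot), drop = FALSE]
  coefs <- fit$coefficients[order(fit$pivot)]
  names(coefs) <- colnames(X)
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- coefs / se
  pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = coefs,
    beta = unname(coefs[term]),
    se = unname(se[term]),
    t = unname(tval[term]),
    p = max(unname(pval[term]), .Machine$double.xmin),
    df = df,
    r_squared = if (tss > 0) max(0, min(1, 1 - rss / tss)) else NA_real_,
    residuals = res,
    n_used = n,
    term = colnames(X)[term],
    all_t = tval,
    all_p = pval,
    all_se = se
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit> n =", x$n_used, " df =", x$df,
      " R^2 =", signif(x$r_squared, 4), "\n")
  cat("  tested term ", x$term, ": beta = ", signif(x$beta, 6),
      ", t = ", signif(x$t, 6), ", p = ", signif(x$p, 6), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a naive least-squares fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$all_se),
                 statistic = unname(x$all_t),
                 p.value = unname(x$all_p))
}

#' One-row model summary of a naive least-squares fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `df.residual`, `nobs`, and
#'   the tested term's `statistic` and `p.value`.
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, df.residual = x$df,
                 nobs = x$n_used, statistic = x$t, p.value = x$p)
}

#' Oracle sweeps over a scan's hypothesis space
#'
#' Run the naive per-pair fit over every (outcome, predictor) pair —
#' or every (outcome, SNP, environment) triplet for the interaction
#' sweep — mirroring what the fast scans test. Used in verification;
#' cost grows as pairs x n^2 and is only sensible at desk scale.
#'
#' @param M Outcome (methylation) matrix, features x samples.
#' @param X Predictor matrix (environments or genotypes), features x
#'   samples.
#' @param cvrt Optional covariate matrix.
#' @return A tibble with `outcome_id`, `predictor_id` (and `env_id` for
#'   the interaction sweep), `beta`, `t_stat`, `p_value`, `r_squared`,
#'   in row-major (outcome-fastest) enumeration order.
#' @export
oracle_scan <- function(M, X, cvrt = NULL) {
  grid <- expand.grid(i = seq_len(nrow(M)), j = seq_len(nrow(X)),
                      KEEP.OUT.ATTRS = FALSE)
  nr <- nrow(grid)
  beta <- t_stat <- p_value <- r2 <- numeric(nr)
  for (k in seq_len(nr)) {
    f <- lm_single(M[grid$i[k], ], X[grid$j[k], ], cvrt)
    beta[k] <- f$beta; t_stat[k] <- f$t; p_value[k] <- f$p
    r2[k] <- f$r_squared
  }
  tibble::tibble(outcome_id = rownames(M)[grid$i],
                 predictor_id = rownames(X)[grid$j],
                 beta = beta, t_stat = t_stat, p_value = p_value,
                 r_squared = r2)
}

#' @rdname oracle_scan
#' @param G Genotype matrix, SNPs x samples.
#' @param E Environment matrix, environments x samples.
#' @export
oracle_interaction_scan <- function(M, G, E, cvrt = NULL) {
  grid <- expand.grid(i = seq_len(nrow(M)), j = seq_len(nrow(G)),
                      l = seq_len(nrow(E)), KEEP.OUT.ATTRS = FALSE)
  nr <- nrow(grid)
  beta <- t_stat <- p_value <- r2 <- numeric(nr)
  for (k in seq_len(nr)) {
    f <- lm_interaction_single(M[grid$i[k], ], G[grid$j[k], ],
                               E[grid$l[k], ], cvrt)
    beta[k] <- f$beta; t_stat[k] <- f$t; p_value[k] <- f$p
    r2[k] <- f$r_squared
  }
  tibble::tibble(outcome_id = rownames(M)[grid$i],
                 predictor_id = rownames(G)[grid$j],
                 env_id = rownames(E)[grid$l],
                 beta = beta, t_stat = t_stat, p_value = p_value,
                 r_squared = r2)
}
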