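#' Genomic inflation factor
#'
#' `lambda_GC`: the median of the 1-df chi-square quantiles implied by
#' the p-values, divided by the null median (`qchisq(0.5, 1)` ~ 0.455).
#' A calibrated null scan gives ~1; systematic inflation pushes it
#' above 1.
#'
#' @param p P-values in (0, 1].
#' @return A single number (NA for empty input).
#' @export
lambda_gc <- function(p) {
  if (length(p) == 0L) return(NA_real_)
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Observed-vs-expected quantiles of a p-value set
#'
#' Ranks the p-values and pairs each observed `-log10(p)` with the
#' uniform-null expectation `-log10((i - 0.5) / n)`.
#'
#' @param p P-values in (0, 1].
#' @return A tibble (`expected`, `observed`, `p`), ranked from most to
#'   least significant, with attribute `"lambda_gc"`.
#' @export
qq_data <- function(p) {
  if (length(p) == 0L) stop("no p-values supplied", call. = FALSE)
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(p)
  ps <- sort(p)
  out <- tibble::tibble(expected = -log10((seq_len(n) - 0.5) / n),
                        observed = -log10(ps),
                        p = ps)
  attr(out, "lambda_gc") <- lambda_gc(p)
  out
}

#' QQ plot of scan p-values
#'
#' Draws observed against expected `-log10(p)` with the identity
#' reference line and the genomic inflation factor in the subtitle.
#' When `out_path` is given the figure is also written to disk (PNG or
#' SVG, chosen by the file extension).
#'
#' @param p P-values in (0, 1], e.g. `records$p_value` from a scan.
#' @param out_path Optional image path.
#' @param title Plot title.
#' @param width,height,dpi Device parameters for the written file.
#' @return The ggplot object, invisibly; its `"qq_data"` attribute
#'   holds the [qq_data()] tibble.
#' @export
qq_plot <- function(p, out_path = NULL, title = "QQ plot",
                    width = 5, height = 5, dpi = 150) {
  qd <- qq_data(p)
  lam <- attr(qd, "lambda_gc")
  gg <- ggplot2::ggplot(qd, ggplot2::aes(x = .data$expected,
                                         y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50",
                         linetype = 2) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(title = title,
                  subtitle = sprintf("lambda[GC] = %.3f", lam),
                  x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_bw()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, gg, width = width, height = height,
                    dpi = dpi)
  }
  attr(gg, "qq_data") <- qd
  invisible(gg)
}

#' Genotype-segregation scatter plot
#'
#' Methylation (y axis, in percent) against environment (x axis), one
#' colour per genotype group with a least-squares line per group — the
#' visual check that a significant interaction reflects genuinely
#' different environment slopes across genotypes. Dosages 0/1/2 are
#' labelled AA (major homozygote), AB, BB; the labels are display-only.
#' Groups with fewer than 3 samples are drawn without a line.
#'
#' @param y Methylation row (beta values in \[0, 1\]).
#' @param g Genotype row, integral dosages in \{0, 1, 2\}.
#' @param e Environment row.
#' @param out_path Optional image path (PNG/SVG by extension).
#' @param title Plot title.
#' @param width,height,dpi Device parameters for the written file.
#' @return The ggplot object, invisibly; attribute `"group_fits"`
#'   holds the per-group slopes/intercepts actually drawn.
#' @export
segregation_plot <- function(y, g, e, out_path = NULL,
                             title = "Methylation by genotype group",
                             width = 6, height = 5, dpi = 150) {
  n <- length(y)
  stopifnot(length(g) == n, length(e) == n)
  if (any(is.na(g)) || any(g != round(g) | g < 0 | g > 2)) {
    stop("genotypes must be integral dosages 0/1/2 for plotting; ",
         "round fractional dosages first", call. = FALSE)
  }
  dat <- tibble::tibble(
    env = e, meth = 100 * y,
    genotype = factor(c("AA", "AB", "BB")[g + 1L],
                      levels = c("AA", "AB", "BB")))
  dat <- dat[!is.na(dat$meth) & !is.na(dat$env), ]
  dat$genotype <- droplevels(dat$genotype)
  fits <- dat |>
    dplyr::group_by(.data$genotype) |>
    dplyr::filter(dplyr::n() >= 3L) |>
    dplyr::summarise(
      intercept = unname(coef(lm(meth ~ env,
                                 data = dplyr::pick(dplyr::everything())))[1L]),
      slope = unname(coef(lm(meth ~ env,
                             data = dplyr::pick(dplyr::everything())))[2L]),
      .groups = "drop")
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$env, y = .data$meth,
                                          colour = .data$genotype)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$genotype)) +
    ggplot2::labs(title = title, x = "Environment",
                  y = "Methylation (%)", colour = "Genotype") +
    ggplot2::theme_bw()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, gg, width = width, height = height,
                    dpi = dpi)
  }
  attr(gg, "group_fits") <- fits
  invisible(gg)
}

#' Plot method for scan results
#'
#' `autoplot()` on a `gem_scan` draws the QQ plot of its p-values.
#'
#' @param object A `gem_scan` result.
#' @param ... Passed to [qq_plot()].
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.gem_scan <- function(object, ...) {
  s <- attr(object, "scan_summary")
  qq_plot(object$p_value, title = paste0(s$model, " p-values"), ...)
}
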