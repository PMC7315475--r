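# PRS ~ ancestry-fraction regression (ordinary least squares).

#' Regress PRS on a continental ancestry fraction
#'
#' Fits the unweighted ordinary-least-squares model
#' `PRS_i = alpha + beta * x_i + e_i`, where `x_i` is the individual's
#' fraction of one continental ancestry. The slope `beta` measures how
#' predicted risk changes per unit ancestry fraction.
#'
#' @param prs PRS tibble from [compute_prs()]. Individuals with undefined
#'   scores are dropped.
#' @param ancestry Ancestry tibble with `individual_id` and `f_African`,
#'   `f_European`, `f_NativeAmerican` (as from [read_ancestry_fractions()]).
#' @param component Which ancestry component to regress on.
#' @param scale Score scale: `"normalized"` (default) or `"count"`.
#' @return An object of class `prs_ancestry_fit`; see [tidy()] and
#'   [glance()] methods. `glance()` returns one row with `alpha`, `beta`,
#'   `se_beta`, `r2`, `t_stat`, `p_two_tailed`, `n`.
#' @export
fit_prs_ancestry <- function(prs, ancestry,
                             component = c("African", "European", "NativeAmerican"),
                             scale = c("normalized", "count")) {
  component <- match.arg(component)
  scale <- match.arg(scale)
  ycol <- if (scale == "normalized") "normalized_score" else "effect_allele_count"
  xcol <- paste0("f_", component)
  df <- dplyr::inner_join(prs, ancestry, by = "individual_id") |>
    dplyr::filter(.data$called_allele_count > 0L) |>
    dplyr::transmute(individual_id = .data$individual_id,
                     x = .data[[xcol]], y = .data[[ycol]])
  if (nrow(df) < 3) abort("fit_prs_ancestry: need at least 3 individuals")
  if (var(df$x) == 0) abort("fit_prs_ancestry: ancestry fractions are constant; slope undefined")
  fit <- lm(y ~ x, data = df)
  structure(
    list(fit = fit, data = df, component = component, scale = scale),
    class = "prs_ancestry_fit"
  )
}

#' @exportS3Method base::print
print.prs_ancestry_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<prs_ancestry_fit> PRS (%s) ~ f_%s: beta = %.4g (se %.3g), r2 = %.3f, P = %.3g, n = %d\n",
    x$scale, x$component, g$beta, g$se_beta, g$r2, g$p_two_tailed, g$n
  ))
  invisible(x)
}

#' @rdname fit_prs_ancestry
#' @param x A `prs_ancestry_fit` object.
#' @param ... Unused.
#' @export
tidy.prs_ancestry_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", paste0("f_", x$component)),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @rdname fit_prs_ancestry
#' @export
glance.prs_ancestry_fit <- function(x, ...) {
  s <- summary(x$fit)
  # a constant response has no variance to explain: define r2 = 0 there
  # (summary.lm divides two round-off zeros in that case)
  if (var(x$data$y) == 0 || is.nan(s$r.squared)) s$r.squared <- 0
  tibble(
    component = x$component,
    alpha = unname(coef(x$fit)[1]),
    beta = unname(coef(x$fit)[2]),
    se_beta = s$coefficients[2, 2],
    r2 = s$r.squared,
    t_stat = s$coefficients[2, 3],
    p_two_tailed = s$coefficients[2, 4],
    n = nrow(x$data)
  )
}

#' @rdname fit_prs_ancestry
#' @param object A `prs_ancestry_fit` object.
#' @param loess Overlay a local-regression smooth for visual comparison.
#' @export
autoplot.prs_ancestry_fit <- function(object, loess = FALSE, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "#2c7fb8") +
    ggplot2::labs(
      x = paste0("f_", object$component),
      y = paste0("PRS (", object$scale, ")")
    )
  if (loess) {
    p <- p + ggplot2::geom_smooth(method = "loess", formula = y ~ x,
                                  se = FALSE, color = "grey40",
                                  linetype = "dashed")
  }
  p
}
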