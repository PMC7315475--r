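# Null distributions of the between-population PRS difference.

#' Construct a null distribution of delta-PRS values
#'
#' @param samples Numeric vector of resampled delta-PRS values.
#' @param provenance How the null was built: `"permutation"` (random SNP
#'   sets), `"daf_matched"` (DAF-matched sets) or `"summary"` (only the
#'   mean/SD are known, e.g. taken from a published analysis).
#' @param scale delta-PRS scale the samples live on (`"count"` or
#'   `"normalized"`).
#' @param seed Seed used to generate the samples, if any.
#' @param set_size SNP-set size per draw, if applicable.
#' @return An object of class `null_distribution` with fields `samples`,
#'   `n_draws`, `mean`, `sd`, `provenance`, `scale`, `seed`, `set_size`.
#' @export
null_distribution <- function(samples, provenance = "permutation",
                              scale = "count", seed = NA_integer_,
                              set_size = NA_integer_) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  structure(
    list(
      samples = as.numeric(samples), n_draws = length(samples),
      mean = mean(samples), sd = sd(samples),
      provenance = provenance, scale = scale,
      seed = seed, set_size = set_size
    ),
    class = "null_distribution"
  )
}

#' @rdname null_distribution
#' @param mean,sd Published summary mean and standard deviation of a null
#'   delta-PRS distribution.
#' @param n_draws Number of draws behind the summary, if known.
#' @export
null_from_summary <- function(mean, sd, n_draws = NA_integer_, scale = "count") {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(
    list(
      samples = NULL, n_draws = n_draws, mean = mean, sd = sd,
      provenance = "summary", scale = scale,
      seed = NA_integer_, set_size = NA_integer_
    ),
    class = "null_distribution"
  )
}

#' @exportS3Method base::print
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: %s> %s draws on the %s scale: mean = %.4g, sd = %.4g\n",
    x$provenance,
    if (is.na(x$n_draws)) "?" else format(x$n_draws, big.mark = ","),
    x$scale, x$mean, x$sd
  ))
  invisible(x)
}

#' @rdname null_distribution
#' @param x,object A `null_distribution` object.
#' @param ... Unused.
#' @export
tidy.null_distribution <- function(x, ...) {
  if (is.null(x$samples)) abort("summary-only null distribution has no samples")
  tibble(draw = seq_along(x$samples), delta_prs = x$samples)
}

#' @rdname null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(
    provenance = x$provenance, scale = x$scale, n_draws = x$n_draws,
    mean = x$mean, sd = x$sd, set_size = x$set_size, seed = x$seed
  )
}

#' @rdname null_distribution
#' @param observed Optional observed delta-PRS to mark on the histogram.
#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$delta_prs)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", color = "grey40") +
    ggplot2::labs(x = sprintf("null ΔPRS (%s scale)", object$scale),
                  y = "draws")
  if (!is.null(observed)) {
    obs <- if (inherits(observed, "delta_prs")) observed$value else observed
    p <- p + ggplot2::geom_vline(xintercept = obs, color = "#d7301f",
                                 linewidth = 1)
  }
  p
}

# Per-SNP contribution of each effect-oriented SNP to the count-scale
# mean delta-PRS between two individual sets. Because the count-scale score
# is a sum over called SNPs, mean(A) - mean(B) for any SNP subset is the
# sum of these per-SNP differences (missing dosages contribute 0).
snp_count_diffs <- function(dosage, ids_a, ids_b) {
  zero_na_colmeans(dosage[ids_a, , drop = FALSE]) -
    zero_na_colmeans(dosage[ids_b, , drop = FALSE])
}

#' Permutation null from random SNP sets
#'
#' Builds the null distribution of the between-population delta-PRS by
#' repeatedly drawing random sets of catalog SNPs (uniformly, without
#' replacement within a set, independently across sets) and computing the
#' count-scale delta-PRS for each set using the catalog SNPs' own effect
#' alleles.
#'
#' @param catalog An `effect_dosages` object from [orient_dosages()] on the
#'   genome-wide catalog pool (each catalog SNP carries its own effect
#'   allele).
#' @param ids_a,ids_b Individual IDs of the two populations compared
#'   (rows of the catalog dosage matrix).
#' @param set_size SNPs per draw (the size of the trait SNP set).
#' @param n_draws Number of random sets (the analysis default in the field
#'   is 5e5; scale down for exploration).
#' @param seed Integer seed.
#' @return A [null_distribution] with provenance `"permutation"`.
#' @export
permutation_null <- function(catalog, ids_a, ids_b, set_size, n_draws, seed) {
  stopifnot(inherits(catalog, "effect_dosages"))
  n_cat <- ncol(catalog$dosage)
  if (set_size > n_cat) {
    abort(sprintf("permutation_null: set_size (%d) exceeds catalog size (%d)",
                  set_size, n_cat))
  }
  d <- snp_count_diffs(catalog$dosage, ids_a, ids_b)
  samples <- withr::with_seed(seed, {
    vapply(seq_len(n_draws),
           function(i) sum(d[sample.int(n_cat, set_size)]),
           numeric(1))
  })
  null_distribution(samples, provenance = "permutation", scale = "count",
                    seed = seed, set_size = set_size)
}

#' One-tailed empirical P value against a resampling null
#'
#' `P = (r + 1) / (n_draws + 1)` where `r` counts null samples at least as
#' extreme as the observed value in the tested direction. The +1 correction
#' counts the observed value as one more draw and avoids P = 0.
#'
#' @param observed Observed delta-PRS (numeric, or a `delta_prs` row).
#' @param null A [null_distribution] with samples.
#' @param direction `"greater"`, `"less"`, or `"auto"` (the side of the
#'   null mean the observed value falls on). State the direction a priori
#'   when the hypothesis is directional.
#' @return The empirical P value.
#' @export
empirical_p <- function(observed, null, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  obs <- if (inherits(observed, "delta_prs")) observed$value else observed
  stopifnot(inherits(null, "null_distribution"))
  if (is.null(null$samples)) {
    abort("empirical_p: null distribution has no samples (summary-only)")
  }
  if (direction == "auto") {
    direction <- if (obs >= null$mean) "greater" else "less"
  }
  r <- if (direction == "greater") sum(null$samples >= obs) else sum(null$samples <= obs)
  (r + 1) / (null$n_draws + 1)
}
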