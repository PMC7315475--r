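# Derived-allele-frequency matched resampling control for ancestry bias
# in between-population PRS comparisons.

#' Derived-allele frequencies in a named set of individuals
#'
#' DAF is the frequency of the non-ancestral allele among called alleles.
#' Only SNPs with a known ancestral state are included (the rest are
#' counted in a message); SNPs with zero called alleles in the set are
#' excluded with a warning.
#'
#' @param geno A [genotype_data] object with ancestral-allele annotation.
#' @param individuals Individual IDs defining the population (default: all).
#' @return A tibble with `id`, `daf`, `n_called_alleles`.
#' @export
compute_daf <- function(geno, individuals = NULL) {
  stopifnot(inherits(geno, "genotype_data"))
  g <- subset_genotypes(geno, individuals = individuals)
  known <- !is.na(g$variants$ancestral)
  if (any(!known)) {
    inform(sprintf("compute_daf: excluded %d SNP(s) with unknown ancestral state", sum(!known)))
  }
  if (!any(known)) abort("compute_daf: no SNPs with known ancestral state")
  dd <- derived_dosage(g)[, known, drop = FALSE]
  called <- colSums(!is.na(dd))
  none <- called == 0L
  if (any(none)) {
    warn(sprintf("compute_daf: excluded %d SNP(s) with zero called alleles", sum(none)))
  }
  tibble(
    id = g$variants$id[known],
    daf = unname(colSums(dd, na.rm = TRUE) / (2 * called)),
    n_called_alleles = as.integer(unname(2 * called))
  ) |> dplyr::filter(.data$n_called_alleles > 0L)
}

# Dosage of the derived allele (NA preserved); requires known ancestral.
derived_dosage <- function(geno) {
  dd <- geno$dosage
  anc_is_alt <- !is.na(geno$variants$ancestral) &
    geno$variants$ancestral == geno$variants$alt
  dd[, anc_is_alt] <- 2L - dd[, anc_is_alt, drop = FALSE]
  dd
}

#' Fraction of trait effect alleles that are derived
#'
#' @param oriented An `effect_dosages` object from [orient_dosages()];
#'   SNPs with unknown ancestral state are ignored.
#' @return Fraction in \[0, 1\].
#' @export
derived_effect_fraction <- function(oriented) {
  stopifnot(inherits(oriented, "effect_dosages"))
  flags <- oriented$snps$effect_is_derived
  if (all(is.na(flags))) abort("derived_effect_fraction: no SNP has a known ancestral state")
  mean(flags, na.rm = TRUE)
}

#' Bin the DAF distribution of a trait SNP set
#'
#' Histogram of the trait SNPs' derived-allele frequencies in the GWAS
#' source population, over half-open bins `[a, b)` of width `bin_width`
#' covering \[0, 1\] (final bin closed). This distribution parameterises
#' the DAF-matched resampling null.
#'
#' @param daf_table DAF tibble from [compute_daf()] on the source
#'   population.
#' @param trait_ids Variant IDs of the trait SNP set.
#' @param bin_width Bin width on \[0, 1\] (default 0.05, i.e. 20 bins).
#' @return An object of class `daf_distribution`: a tibble with `bin`,
#'   `lower`, `upper`, `count`, and attributes `bin_width`, `n_snps`.
#' @export
trait_daf_distribution <- function(daf_table, trait_ids, bin_width = 0.05) {
  stopifnot(bin_width > 0, bin_width <= 1)
  present <- trait_ids %in% daf_table$id
  if (!any(present)) abort("trait_daf_distribution: no trait SNP found in the DAF table")
  if (any(!present)) {
    warn(sprintf("trait_daf_distribution: %d trait SNP(s) absent from the DAF table (unknown ancestral state?)",
                 sum(!present)))
  }
  daf <- daf_table$daf[match(trait_ids[present], daf_table$id)]
  n_bins <- ceiling(1 / bin_width)
  bin <- daf_bin(daf, bin_width)
  counts <- tabulate(bin, nbins = n_bins)
  out <- tibble(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) * bin_width,
    upper = pmin(seq_len(n_bins) * bin_width, 1),
    count = counts
  )
  structure(out, class = c("daf_distribution", class(out)),
            bin_width = bin_width, n_snps = sum(counts))
}

# Half-open bins [a, b); the final bin is closed so DAF = 1 is included.
daf_bin <- function(daf, bin_width) {
  n_bins <- ceiling(1 / bin_width)
  pmin(findInterval(daf, (seq_len(n_bins) - 1) * bin_width), n_bins)
}

#' @rdname trait_daf_distribution
#' @param object A `daf_distribution` object.
#' @param ... Unused.
#' @export
autoplot.daf_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.92,
                      fill = "#2c7fb8") +
    ggplot2::labs(x = "derived allele frequency (source population)",
                  y = "trait SNPs")
}

#' Draw one DAF-matched SNP set
#'
#' For each occupied bin of the trait DAF distribution, draws the same
#' number of catalog SNPs uniformly from that source-population DAF bin
#' (without replacement within the set; sets are independent across draws).
#' Each sampled SNP's effect allele is set to its derived allele with
#' probability `derived_fraction`, else to its ancestral allele, preserving
#' the trait set's polarization mix.
#'
#' @param catalog_daf Tibble with `id` and `daf` (source-population DAF of
#'   each catalog-pool SNP), as from [compute_daf()] filtered to the pool.
#' @param trait_dist A [trait_daf_distribution()] object.
#' @param derived_fraction Probability that a sampled SNP's effect allele
#'   is derived (use [derived_effect_fraction()] of the trait set).
#' @param seed Integer seed.
#' @return A tibble with `id`, `bin`, `effect_is_derived`.
#' @export
daf_matched_sample <- function(catalog_daf, trait_dist, derived_fraction, seed) {
  pools <- daf_bin_pools(catalog_daf, trait_dist)
  withr::with_seed(seed, draw_matched_set(pools, derived_fraction,
                                          catalog_daf$id))
}

# Catalog indices per occupied trait bin, with occupancy validation.
daf_bin_pools <- function(catalog_daf, trait_dist) {
  stopifnot(inherits(trait_dist, "daf_distribution"))
  bw <- attr(trait_dist, "bin_width")
  cat_bin <- daf_bin(catalog_daf$daf, bw)
  occupied <- trait_dist[trait_dist$count > 0, ]
  pools <- lapply(seq_len(nrow(occupied)), function(i) {
    which(cat_bin == occupied$bin[i])
  })
  short <- lengths(pools) < occupied$count
  if (any(short)) {
    i <- which(short)[1]
    abort(sprintf(
      "daf_matched_sample: bin [%.2f,%.2f%s holds %d catalog SNP(s) but the trait set needs %d; use a larger catalog or wider bins",
      occupied$lower[i], occupied$upper[i],
      if (occupied$upper[i] >= 1) "]" else ")",
      lengths(pools)[i], occupied$count[i]
    ))
  }
  list(idx = pools, need = occupied$count, bin = occupied$bin)
}

draw_matched_set <- function(pools, derived_fraction, ids = NULL) {
  idx <- unlist(purrr::map2(pools$idx, pools$need, function(pool, k) {
    pool[sample.int(length(pool), k)]
  }))
  eff_der <- runif(length(idx)) < derived_fraction
  tibble(
    id = if (is.null(ids)) idx else ids[idx],
    bin = rep(pools$bin, pools$need),
    effect_is_derived = eff_der
  )
}

#' DAF-matched resampling null for the between-population delta-PRS
#'
#' Repeats [daf_matched_sample()] `n_draws` times and computes, for each
#' sampled set, the count-scale delta-PRS between the two compared
#' populations using the sampled SNPs' own genotypes and assigned effect
#' alleles. Matching on source-population DAF removes the component of the
#' between-population delta-PRS attributable to systematic
#' ancestral/derived frequency differences (drift and SNP ascertainment),
#' so the resulting null is centred where an unbiased trait set of the same
#' DAF profile would fall.
#'
#' @param geno A [genotype_data] object holding the compared populations'
#'   genotypes at (at least) the catalog-pool SNPs.
#' @param catalog_daf Source-population DAF tibble for the catalog pool
#'   (`id`, `daf`).
#' @param trait_dist A [trait_daf_distribution()] object.
#' @param ids_a,ids_b Individual IDs of the two compared populations.
#' @param derived_fraction Trait set's derived-effect fraction.
#' @param n_draws Number of resampled sets.
#' @param seed Integer seed.
#' @return A [null_distribution] with provenance `"daf_matched"`.
#' @export
daf_matched_null <- function(geno, catalog_daf, trait_dist, ids_a, ids_b,
                             derived_fraction, n_draws, seed) {
  stopifnot(inherits(geno, "genotype_data"))
  g <- subset_genotypes(geno, snps = catalog_daf$id)
  dd <- derived_dosage(g)
  # Per-SNP count-scale mean differences under each effect polarization.
  d_der <- snp_count_diffs(dd, ids_a, ids_b)
  ad <- 2L - dd
  d_anc <- snp_count_diffs(ad, ids_a, ids_b)
  pools <- daf_bin_pools(catalog_daf, trait_dist)
  samples <- withr::with_seed(seed, {
    matched_null_draws_cpp(pools$idx, as.integer(pools$need),
                           unname(d_der), unname(d_anc),
                           derived_fraction, as.integer(n_draws))
  })
  null_distribution(samples, provenance = "daf_matched", scale = "count",
                    seed = seed, set_size = sum(trait_dist$count))
}

#' Ancestry-corrected delta-PRS z-score
#'
#' Compares an observed between-population delta-PRS to a resampling null
#' and reports the corrected score
#' `z = (obs - null_mean) / null_sd`, the one-tailed empirical P (when the
#' null carries samples), and a secondary normal-theory one-tailed P
#' implied by `z`.
#'
#' @param observed Observed delta-PRS: a [delta_prs()] row or a bare
#'   number. When both the observed value and the null carry a scale label
#'   the two must agree.
#' @param null A [null_distribution].
#' @param direction Tail for the empirical P; see [empirical_p()].
#' @return A one-row tibble of class `correction_result` with columns
#'   `obs_delta_prs`, `null_mean`, `null_sd`, `corrected_z`,
#'   `empirical_p`, `p_normal_one_tailed`, `n_draws`, `seed`.
#' @export
corrected_delta_prs <- function(observed, null,
                                direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(null, "null_distribution"))
  if (inherits(observed, "delta_prs") && !is.na(null$scale) &&
        observed$scale != null$scale) {
    abort(sprintf("corrected_delta_prs: observed delta-PRS is on the %s scale but the null is on the %s scale",
                  observed$scale, null$scale))
  }
  obs <- if (inherits(observed, "delta_prs")) observed$value else observed
  if (is.na(null$sd) || null$sd <= 0) abort("corrected_delta_prs: null SD must be positive")
  z <- (obs - null$mean) / null$sd
  p_emp <- if (is.null(null$samples)) NA_real_ else empirical_p(obs, null, direction)
  out <- tibble(
    obs_delta_prs = obs,
    null_mean = null$mean,
    null_sd = null$sd,
    corrected_z = z,
    empirical_p = p_emp,
    p_normal_one_tailed = pnorm(-abs(z)),
    n_draws = null$n_draws,
    seed = null$seed
  )
  class(out) <- c("correction_result", class(out))
  out
}

#' @exportS3Method base::print
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "<correction_result> obs ΔPRS = %.4g | null mean = %.4g, sd = %.4g | corrected z = %.4g | empirical P = %s\n",
    x$obs_delta_prs, x$null_mean, x$null_sd, x$corrected_z,
    ifelse(is.na(x$empirical_p), "NA", format(x$empirical_p, digits = 3))
  ))
  invisible(x)
}

#' Run the full DAF-matched ancestry-bias control
#'
#' The five-step control in one call: (1) score the trait SNP set in both
#' populations and take the observed count-scale delta-PRS; (2) compute the
#' trait set's DAF distribution in the GWAS source population; (3/4) draw
#' DAF-matched random SNP sets from the catalog pool and build the null
#' delta-PRS distribution; (5) report the corrected z-score and empirical
#' P.
#'
#' @param geno A [genotype_data] object covering trait and catalog SNPs
#'   for all individuals involved.
#' @param trait_assoc Trait association tibble (id, effect_allele,
#'   other_allele, ...).
#' @param catalog_ids Variant IDs of the genome-wide catalog pool.
#' @param ids_a,ids_b Individual IDs of the two compared populations.
#' @param source_ids Individual IDs of the GWAS source population used for
#'   DAF matching.
#' @param bin_width DAF bin width (default 0.05).
#' @param n_draws Number of DAF-matched sets (default 5000).
#' @param seed Integer master seed; child seeds are derived with
#'   [split_seed()].
#' @param direction Tail for the empirical P.
#' @return A `correction_result` row (see [corrected_delta_prs()]).
#' @export
daf_correction <- function(geno, trait_assoc, catalog_ids, ids_a, ids_b,
                           source_ids, bin_width = 0.05, n_draws = 5000,
                           seed = 1L, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  oriented <- orient_dosages(geno, trait_assoc)
  prs_a <- compute_prs(subset_dosages(oriented, ids_a))
  prs_b <- compute_prs(subset_dosages(oriented, ids_b))
  obs <- delta_prs(prs_a, prs_b, scale = "count")

  daf_src <- compute_daf(geno, source_ids)
  trait_dist <- trait_daf_distribution(daf_src, oriented$snps$id, bin_width)
  frac <- derived_effect_fraction(oriented)
  catalog_daf <- daf_src[daf_src$id %in% setdiff(catalog_ids, oriented$snps$id), ]

  null <- daf_matched_null(geno, catalog_daf, trait_dist, ids_a, ids_b,
                           frac, n_draws, seed = split_seed(seed, 1))
  corrected_delta_prs(obs, null, direction)
}

# Restrict an effect_dosages object to a set of individuals.
subset_dosages <- function(oriented, individuals) {
  oriented$dosage[individuals, , drop = FALSE]
}
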