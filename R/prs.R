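# Unweighted polygenic risk scores and between-population differences.

#' Orient genotype dosages to trait effect alleles
#'
#' For each associated SNP found in the genotypes, converts alt-allele
#' dosages into effect-allele dosages: if the effect allele is the alt
#' allele the dosage is kept; if it is the ref allele the dosage is flipped
#' to `2 - dosage` (missing stays missing). Allele matching is exact on
#' A/C/G/T with no strand flipping — silently flipping strands (including
#' palindromic A/T and C/G SNPs) is a classic source of PRS error, so
#' unmatched SNPs are excluded and reported instead.
#'
#' @param geno A [genotype_data] object.
#' @param assoc Association tibble with columns `id`, `effect_allele`,
#'   `other_allele` (as from [read_association_table()]).
#' @return An object of class `effect_dosages`: list with `dosage`
#'   (individuals x matched SNPs effect-allele dosage matrix), `snps`
#'   (tibble of matched SNPs with `effect_is_derived` where the ancestral
#'   state is known) and `report` (per-association match status tibble).
#' @export
orient_dosages <- function(geno, assoc) {
  stopifnot(inherits(geno, "genotype_data"))
  v <- geno$variants
  idx <- match(assoc$id, v$id)
  status <- dplyr::case_when(
    is.na(idx) ~ "absent",
    assoc$effect_allele == v$alt[idx] ~ "effect_is_alt",
    assoc$effect_allele == v$ref[idx] ~ "effect_is_ref",
    TRUE ~ "allele_mismatch"
  )
  report <- tibble(id = assoc$id, status = status)
  matched <- status %in% c("effect_is_alt", "effect_is_ref")
  if (!any(matched)) {
    abort(c("no association SNPs could be matched to the genotypes",
            "i" = sprintf("%d absent, %d with mismatching alleles",
                          sum(status == "absent"), sum(status == "allele_mismatch"))))
  }
  n_excl <- sum(!matched)
  if (n_excl > 0) {
    inform(sprintf("orient_dosages: excluded %d of %d association SNP(s) (see report)",
                   n_excl, nrow(assoc)))
  }
  keep <- idx[matched]
  dos <- geno$dosage[, keep, drop = FALSE]
  flip <- status[matched] == "effect_is_ref"
  dos[, flip] <- 2L - dos[, flip, drop = FALSE]
  colnames(dos) <- v$id[keep]

  anc <- v$ancestral[keep]
  effect <- ifelse(flip, v$ref[keep], v$alt[keep])
  snps <- tibble(
    id = v$id[keep], chrom = v$chrom[keep], pos = v$pos[keep],
    effect_allele = effect,
    effect_is_derived = ifelse(is.na(anc), NA, effect != anc)
  )
  structure(list(dosage = dos, snps = snps, report = report),
            class = "effect_dosages")
}

#' @exportS3Method base::print
print.effect_dosages <- function(x, ...) {
  cat(sprintf("<effect_dosages> %d individuals x %d matched SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Compute unweighted polygenic risk scores
#'
#' Per individual, the score is the normalised sum of effect alleles:
#' `sum(G_i) / sum(A_i)`, where `G_i` in 0/1/2 is the effect-allele dosage
#' at SNP `i` and `A_i` is the number of called alleles at that SNP (2 for a
#' called diploid genotype, 0 for a missing call; half calls are treated as
#' missing). SNPs are equally weighted: effect sizes curated from
#' heterogeneous studies cannot be combined on a common scale.
#'
#' @param oriented An `effect_dosages` object from [orient_dosages()], or a
#'   bare effect-dosage matrix (individuals x SNPs, `NA` = missing).
#' @return A tibble with columns `individual_id`, `n_snps_used`,
#'   `effect_allele_count`, `called_allele_count`, `normalized_score`.
#'   Individuals with no called SNPs get `normalized_score = NA` and are
#'   excluded from population summaries downstream.
#' @export
compute_prs <- function(oriented) {
  dos <- if (inherits(oriented, "effect_dosages")) oriented$dosage else oriented
  stopifnot(is.matrix(dos))
  called <- !is.na(dos)
  n_used <- unname(rowSums(called))
  eff <- unname(rowSums(dos, na.rm = TRUE))
  tot <- 2L * n_used
  none <- tot == 0L
  if (any(none)) {
    warn(sprintf("compute_prs: %d individual(s) with no called SNPs; score undefined", sum(none)))
  }
  tibble(
    individual_id = rownames(dos) %||% as.character(seq_len(nrow(dos))),
    n_snps_used = as.integer(n_used),
    effect_allele_count = as.integer(eff),
    called_allele_count = as.integer(tot),
    normalized_score = ifelse(none, NA_real_, eff / tot)
  )
}

#' Between-population PRS difference
#'
#' Mean per-individual PRS difference between two populations, `A - B`.
#' The default `count` scale (mean effect-allele count) is the scale the
#' resampling-null machinery works on; the corrected z-score is invariant
#' to this choice as long as observed and null values share a scale, which
#' the pipeline enforces through the `scale` attribute carried here.
#'
#' @param prs_a,prs_b PRS tibbles from [compute_prs()] for the two
#'   populations. Individuals with undefined scores are excluded.
#' @param scale `"count"` (mean effect-allele count, default) or
#'   `"normalized"` (mean of `normalized_score`).
#' @return A one-row tibble of class `delta_prs` with columns `pop_a`,
#'   `pop_b`, `scale`, `value`, `n_a`, `n_b`.
#' @export
delta_prs <- function(prs_a, prs_b, scale = c("count", "normalized")) {
  scale <- match.arg(scale)
  a <- prs_a[prs_a$called_allele_count > 0L, ]
  b <- prs_b[prs_b$called_allele_count > 0L, ]
  if (nrow(a) == 0L || nrow(b) == 0L) abort("delta_prs: a population is empty after exclusions")
  col <- if (scale == "count") "effect_allele_count" else "normalized_score"
  out <- tibble(
    pop_a = attr(prs_a, "population") %||% "A",
    pop_b = attr(prs_b, "population") %||% "B",
    scale = scale,
    value = mean(a[[col]]) - mean(b[[col]]),
    n_a = nrow(a),
    n_b = nrow(b)
  )
  class(out) <- c("delta_prs", class(out))
  out
}
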