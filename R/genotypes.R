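#' Genotype container: individuals-by-SNPs alt-allele dosages
#'
#' A light container for biallelic SNP genotypes. `dosage` is an integer
#' matrix with one row per individual and one column per SNP, holding the
#' number of alternate-allele copies (0, 1, 2) or `NA` for a missing call.
#' `variants` is a tibble of per-SNP metadata; `ancestral` holds the
#' ancestral allele (matching `ref` or `alt`) or `NA` when unknown.
#'
#' @param dosage Integer matrix, individuals x SNPs; values in 0/1/2/NA.
#' @param variants Tibble with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `ancestral`.
#' @param individuals Character vector of individual IDs, one per row of
#'   `dosage`.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosage, variants, individuals) {
  variants <- as_tibble(variants)
  stopifnot(
    is.matrix(dosage),
    nrow(dosage) == length(individuals),
    ncol(dosage) == nrow(variants),
    all(c("id", "chrom", "pos", "ref", "alt", "ancestral") %in% names(variants))
  )
  if (anyDuplicated(variants$id)) {
    abort("duplicate variant IDs in genotype data")
  }
  rng <- suppressWarnings(range(dosage, na.rm = TRUE))
  if (is.finite(rng[1]) &&
        (rng[1] < 0 || rng[2] > 2 ||
           (is.double(dosage) && any(dosage %% 1 != 0, na.rm = TRUE)))) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  known <- !is.na(variants$ancestral)
  if (any(known & variants$ancestral != variants$ref &
            variants$ancestral != variants$alt)) {
    abort("ancestral allele must match ref or alt (or be NA)")
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(individuals, variants$id)
  structure(
    list(dosage = dosage, variants = variants, individuals = individuals),
    class = "genotype_data"
  )
}

#' @exportS3Method base::print
print.genotype_data <- function(x, ...) {
  n_anc <- sum(!is.na(x$variants$ancestral))
  cat(sprintf(
    "<genotype_data> %d individuals x %d SNPs (%d with known ancestral allele, %.2f%% missing calls)\n",
    length(x$individuals), nrow(x$variants), n_anc,
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @exportS3Method base::dim
dim.genotype_data <- function(x) dim(x$dosage)

#' Subset a genotype container by individuals and/or SNP IDs
#'
#' @param geno A [genotype_data] object.
#' @param individuals Character vector of individual IDs to keep (default all).
#' @param snps Character vector of variant IDs to keep, in the requested
#'   order (default all).
#' @return A [genotype_data] object.
#' @export
subset_genotypes <- function(geno, individuals = NULL, snps = NULL) {
  stopifnot(inherits(geno, "genotype_data"))
  ind <- individuals %||% geno$individuals
  ids <- snps %||% geno$variants$id
  missing_ind <- setdiff(ind, geno$individuals)
  missing_snp <- setdiff(ids, geno$variants$id)
  if (length(missing_ind)) abort(paste0("unknown individuals: ", toString(utils::head(missing_ind, 5))))
  if (length(missing_snp)) abort(paste0("unknown SNP IDs: ", toString(utils::head(missing_snp, 5))))
  keep <- match(ids, geno$variants$id)
  # already-validated parent: rebuild without re-running the checks
  structure(
    list(
      dosage = geno$dosage[match(ind, geno$individuals), keep, drop = FALSE],
      variants = geno$variants[keep, ],
      individuals = ind
    ),
    class = "genotype_data"
  )
}
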