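# File input/output: VCF genotypes, association tables, ancestry fractions.

#' Recognised GWAS cohort-ancestry labels
#' @export
cohort_ancestry_labels <- c(
  "African", "East Asian", "European", "Hispanic/Latino",
  "Native American", "Multi-ethnic", "Admixed American"
)

#' Read biallelic SNP genotypes from a VCF file
#'
#' Decodes GT fields to alternate-allele dosages (0/1/2, `NA` for missing or
#' half calls) and parses the `AA` INFO tag (1000 Genomes convention) into
#' the ancestral-allele column. Records that are not biallelic SNPs are
#' skipped with a message; an `AA` value matching neither allele leaves the
#' ancestral state unknown with a warning.
#'
#' @param path Path to a VCF 4.x file (plain or gzip).
#' @return A [genotype_data] object.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- is_snp_base(ref) & is_snp_base(alt)
  if (any(!snp)) {
    inform(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", sum(!snp)))
  }
  if (!any(snp)) abort("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  aa <- vcfR::extract.info(v, element = "AA")
  if (is.null(aa)) aa <- rep(NA_character_, nrow(fix))
  aa <- aa[snp]
  ref <- ref[snp]
  alt <- alt[snp]

  # 1000 Genomes AA values can carry extra annotation after '|'; keep the
  # allele part and compare case-insensitively.
  aa <- toupper(sub("\\|.*$", "", aa))
  aa[aa %in% c("", ".", "-", "N")] <- NA_character_
  mismatch <- !is.na(aa) & aa != ref & aa != alt
  if (any(mismatch)) {
    warn(sprintf(
      "read_vcf: AA tag matches neither allele at %d SNP(s); ancestral set to unknown",
      sum(mismatch)
    ))
    aa[mismatch] <- NA_character_
  }

  dosage <- t(decode_gt(gt))
  id <- fix[snp, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[snp, "CHROM"][no_id], ":", fix[snp, "POS"][no_id])

  genotype_data(
    dosage,
    tibble(
      id = id, chrom = fix[snp, "CHROM"], pos = as.integer(fix[snp, "POS"]),
      ref = ref, alt = alt, ancestral = aa
    ),
    colnames(gt)
  )
}

# GT strings -> alt-allele counts; anything other than two 0/1 alleles
# (missing, half calls) is NA.
decode_gt <- function(gt) {
  codes <- c(
    "0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
    "1/1" = 2L, "1|1" = 2L
  )
  out <- matrix(unname(codes[gt]), nrow = nrow(gt), dimnames = dimnames(gt))
  out
}

#' Write a genotype container to a plain-text VCF file
#'
#' Emits a minimal VCF 4.2 file with GT genotypes and the `AA` INFO tag for
#' SNPs whose ancestral allele is known. `read_vcf(write_vcf(x))` round-trips
#' dosages, IDs and ancestral annotation exactly.
#'
#' @param geno A [genotype_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_data"))
  v <- geno$variants
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(v), ncol = length(geno$individuals))
  called <- !is.na(geno$dosage)
  gt[t(called)] <- gt_code[t(geno$dosage)[t(called)] + 1L]
  info <- ifelse(is.na(v$ancestral), ".", paste0("AA=", v$ancestral))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$individuals), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trait-association table
#'
#' Reads a tab-separated table of trait-associated SNPs. Required columns:
#' `id`, `chrom`, `pos`, `effect_allele`, `other_allele`; optional:
#' `cohort_ancestry` (comma-separated labels from
#' [cohort_ancestry_labels]) and `weight` (accepted but unused by the
#' unweighted score). Duplicate IDs are collapsed to one row keeping the
#' union of ancestry labels; rows whose effect and other allele coincide are
#' rejected with a warning.
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble with one row per distinct associated SNP.
#' @export
read_association_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = "c", .default = readr::col_guess()))
  required <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) abort(paste0("association table missing column(s): ", toString(miss)))
  if (!"cohort_ancestry" %in% names(tbl)) tbl$cohort_ancestry <- NA_character_

  bad <- tbl$effect_allele == tbl$other_allele
  if (any(bad)) {
    warn(sprintf("read_association_table: rejected %d row(s) with identical effect and other allele", sum(bad)))
    tbl <- tbl[!bad, ]
  }
  labels <- unlist(strsplit(tbl$cohort_ancestry[!is.na(tbl$cohort_ancestry)], ",", fixed = TRUE))
  unknown <- setdiff(trimws(labels), cohort_ancestry_labels)
  if (length(unknown)) {
    warn(paste0("read_association_table: unrecognised cohort ancestry label(s): ", toString(unknown)))
  }

  n_dup <- sum(duplicated(tbl$id))
  if (n_dup > 0) inform(sprintf("read_association_table: collapsed %d duplicate ID(s)", n_dup))
  tbl |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("chrom", "pos", "effect_allele", "other_allele")), dplyr::first),
      cohort_ancestry = collapse_labels(.data$cohort_ancestry),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

collapse_labels <- function(x) {
  x <- unique(trimws(unlist(strsplit(x[!is.na(x)], ",", fixed = TRUE))))
  if (!length(x)) NA_character_ else paste(sort(x), collapse = ",")
}

#' Read per-individual continental ancestry fractions
#'
#' Reads a tab-separated table with columns `individual_id`, `f_African`,
#' `f_European`, `f_NativeAmerican`. Rows whose fractions do not sum to 1
#' within `tol` are excluded with a warning (no renormalisation is applied).
#'
#' @param path Path to a TSV file with a header line.
#' @param tol Tolerance on the sum-to-one constraint (default 1e-3, enough
#'   to accept fractions printed at two decimals).
#' @return A tibble of validated ancestry profiles.
#' @export
read_ancestry_fractions <- function(path, tol = 1e-3) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("individual_id", "f_African", "f_European", "f_NativeAmerican")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) abort(paste0("ancestry table missing column(s): ", toString(miss)))
  fr <- as.matrix(tbl[, c("f_African", "f_European", "f_NativeAmerican")])
  ok <- abs(rowSums(fr) - 1) <= tol & apply(fr >= 0 & fr <= 1, 1, all)
  if (any(!ok)) {
    warn(sprintf("read_ancestry_fractions: rejected %d row(s) violating the sum-to-1 constraint", sum(!ok)))
  }
  as_tibble(tbl[ok, required])
}
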