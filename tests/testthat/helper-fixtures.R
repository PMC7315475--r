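# Small in-code fixtures shared across test files.

# Hand-built genotype container: `dosage` is individuals x SNPs.
toy_geno <- function(dosage, ref = NULL, alt = NULL, ancestral = NULL,
                     pos = NULL, chrom = "1") {
  m <- ncol(dosage)
  ref <- ref %||% rep("A", m)
  alt <- alt %||% rep("G", m)
  ancestral <- ancestral %||% rep(NA_character_, m)
  genotype_data(
    dosage,
    tibble::tibble(
      id = sprintf("rs%d", seq_len(m)),
      chrom = rep(chrom, length.out = m),
      pos = pos %||% (100L * seq_len(m)),
      ref = ref, alt = alt, ancestral = ancestral
    ),
    sprintf("I%d", seq_len(nrow(dosage)))
  )
}

# Minimal VCF text with configurable records.
write_toy_vcf <- function(path, records, samples = c("S1", "S2", "S3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, info, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")
}

write_tsv_text <- function(lines, path) {
  writeLines(lines, path)
  path
}

`%||%` <- rlang::`%||%`

# Membership helper for simulated studies.
pop_ids <- function(study, pop) {
  study$membership$individual_id[study$membership$population == pop]
}
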