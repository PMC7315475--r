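# Synthetic admixed cohorts: Dirichlet admixture proportions over
# Balding-Nichols population allele frequencies, with explicit
# ancestral/derived polarization and an embeddable risk architecture.

#' Configuration for the synthetic admixed-cohort generator
#'
#' Defaults describe the study design the package targets: two admixed
#' cohorts with three-way continental ancestry (African / European / Native
#' American), one predominantly African (mean fractions 0.76/0.13/0.11) and
#' one predominantly European (0.07/0.75/0.18); continental-scale drift
#' F = 0.15 for each ancestral population; a genome-wide pool of 20,000
#' independent SNPs from which 100 trait SNPs are drawn; and a 56% derived /
#' 44% ancestral effect-allele mix for trait SNPs, matching the split
#' reported for curated GWAS risk alleles.
#'
#' @param n_snps Number of simulated SNPs (catalog pool + trait SNPs).
#' @param cohorts Named list; each element a list with `n` (individuals)
#'   and `alpha` (Dirichlet concentration over AFR/EUR/NAT). Dirichlet means
#'   `alpha/sum(alpha)` set the cohort's expected ancestry profile.
#' @param f_st Named drift coefficients in (0,1) for AFR, EUR, NAT.
#' @param n_risk_snps Number of trait-associated SNPs to embed.
#' @param risk_delta Between-population effect-allele frequency differential
#'   for embedded risk SNPs: the effect-allele frequency is shifted by
#'   `+risk_delta/2` in `risk_target_pops[1]` and `-risk_delta/2` in
#'   `risk_target_pops[2]` (so the embedded between-population difference is
#'   `risk_delta`). `0` gives a null simulation.
#' @param risk_target_pops The two ancestral populations carrying the shift.
#' @param derived_effect_fraction Probability that a trait SNP's effect
#'   allele is the derived allele (default 0.56).
#' @param ascertainment_power Exponent `g >= 0`: trait SNPs are sampled with
#'   weight proportional to `q_EUR^g`, the derived-allele frequency in the
#'   European ancestral population. `0` (default) samples uniformly; `2` is
#'   the package's ascertainment-bias emulation, concentrating trait SNPs on
#'   high source-population DAF the way array design and discovery power do.
#' @param prob_ref_ancestral Probability that the simulated reference allele
#'   is the ancestral state (default 0.8; real reference genomes mostly, but
#'   not always, carry the ancestral allele).
#' @param seed Master seed; all stages derive child seeds from it via
#'   [split_seed()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 20000,
                       cohorts = list(
                         AFRADM = list(n = 100, alpha = 10 * c(AFR = 0.76, EUR = 0.13, NAT = 0.11)),
                         EURADM = list(n = 100, alpha = 10 * c(AFR = 0.07, EUR = 0.75, NAT = 0.18))
                       ),
                       f_st = c(AFR = 0.15, EUR = 0.15, NAT = 0.15),
                       n_risk_snps = 100,
                       risk_delta = 0.1,
                       risk_target_pops = c("AFR", "EUR"),
                       derived_effect_fraction = 0.56,
                       ascertainment_power = 0,
                       prob_ref_ancestral = 0.8,
                       seed = 1L) {
  stopifnot(
    n_snps >= 1, n_risk_snps >= 0, n_risk_snps <= n_snps,
    abs(risk_delta) <= 1,
    derived_effect_fraction >= 0, derived_effect_fraction <= 1,
    ascertainment_power >= 0,
    prob_ref_ancestral >= 0, prob_ref_ancestral <= 1,
    all(names(f_st) == c("AFR", "EUR", "NAT")),
    all(f_st > 0 & f_st < 1),
    length(cohorts) >= 1, !is.null(names(cohorts)),
    all(risk_target_pops %in% c("AFR", "EUR", "NAT")),
    length(risk_target_pops) == 2, risk_target_pops[1] != risk_target_pops[2]
  )
  for (co in cohorts) {
    stopifnot(co$n >= 1, length(co$alpha) == 3, all(co$alpha > 0))
  }
  structure(
    list(
      n_snps = as.integer(n_snps), cohorts = cohorts, f_st = f_st,
      n_risk_snps = as.integer(n_risk_snps), risk_delta = risk_delta,
      risk_target_pops = risk_target_pops,
      derived_effect_fraction = derived_effect_fraction,
      ascertainment_power = ascertainment_power,
      prob_ref_ancestral = prob_ref_ancestral, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate population-differentiated allele frequencies
#'
#' Draws, for each SNP, a global (ancestral-population) derived-allele
#' frequency `p ~ Uniform(0.05, 0.95)` and, for each continental population
#' `k`, a Balding-Nichols frequency `q_k ~ Beta` with mean `p` and variance
#' `F_k * p * (1 - p)`. Reference/alternate bases and the ancestral state
#' are assigned so that derived-allele accounting is exact by construction.
#'
#' @param config A [sim_config()] object.
#' @param seed Seed for this stage (default: first child of `config$seed`).
#' @return A tibble with one row per SNP: `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `ancestral`, `p` and derived-allele frequencies `q_AFR`,
#'   `q_EUR`, `q_NAT`.
#' @export
simulate_frequencies <- function(config, seed = split_seed(config$seed, 4)[1]) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  withr::with_seed(seed, {
    p <- runif(n, 0.05, 0.95)
    q <- vapply(c("AFR", "EUR", "NAT"), function(k) {
      f <- config$f_st[[k]]
      shape <- (1 - f) / f
      rbeta(n, p * shape, (1 - p) * shape)
    }, numeric(n))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    # alt uniform over the three non-ref bases
    alt <- bases[(match(ref, bases) - 1L + sample.int(3, n, replace = TRUE)) %% 4L + 1L]
    anc_is_ref <- runif(n) < config$prob_ref_ancestral
  })
  tibble(
    id = sprintf("snp%05d", seq_len(n)),
    chrom = "1",
    pos = 1000L * seq_len(n),
    ref = ref,
    alt = alt,
    ancestral = ifelse(anc_is_ref, ref, alt),
    p = p,
    q_AFR = q[, "AFR"], q_EUR = q[, "EUR"], q_NAT = q[, "NAT"]
  )
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate genotypes for one admixed cohort
#'
#' Each individual's ancestry vector is drawn from the cohort's Dirichlet;
#' each of the two allele copies at each SNP independently picks an
#' ancestral population by those proportions and is then derived with that
#' population's frequency `q_k`. Equivalently, the dosage of the derived
#' allele is Binomial(2, f_i . q_j), which the generator draws directly.
#'
#' @param freqs Frequency table from [simulate_frequencies()] (possibly
#'   modified by [embed_risk_architecture()]).
#' @param config A [sim_config()] object.
#' @param cohort Name of the cohort in `config$cohorts`.
#' @param seed Seed for this stage.
#' @return List with `geno` (a [genotype_data]; AA annotation carries the
#'   simulated ancestral state) and `ancestry` (truth tibble with
#'   `individual_id`, `f_African`, `f_European`, `f_NativeAmerican`).
#' @export
simulate_cohort <- function(freqs, config, cohort, seed) {
  stopifnot(inherits(config, "sim_config"), cohort %in% names(config$cohorts))
  co <- config$cohorts[[cohort]]
  qmat <- t(as.matrix(freqs[, c("q_AFR", "q_EUR", "q_NAT")]))  # 3 x SNPs
  withr::with_seed(seed, {
    fr <- rdirichlet(co$n, co$alpha)                            # n x 3
    p_derived <- fr %*% qmat                                    # n x SNPs
    alt_is_derived <- freqs$ancestral == freqs$ref
    p_alt <- sweep_cols_complement(p_derived, !alt_is_derived)
    dosage <- matrix(
      rbinom(length(p_alt), 2L, as.vector(p_alt)),
      nrow = co$n
    )
  })
  ids <- sprintf("%s_%03d", cohort, seq_len(co$n))
  list(
    geno = genotype_data(
      dosage,
      freqs[, c("id", "chrom", "pos", "ref", "alt", "ancestral")],
      ids
    ),
    ancestry = tibble(
      individual_id = ids,
      f_African = fr[, 1], f_European = fr[, 2], f_NativeAmerican = fr[, 3]
    )
  )
}

# Replace columns j with 1 - x[, j] where flip[j] is TRUE.
sweep_cols_complement <- function(x, flip) {
  x[, flip] <- 1 - x[, flip, drop = FALSE]
  x
}

#' Embed a known risk architecture into a frequency table
#'
#' Selects `n_risk_snps` trait SNPs (uniformly, or weighted toward high
#' European-population DAF when `ascertainment_power > 0`), assigns each an
#' effect allele that is derived with probability
#' `derived_effect_fraction`, and shifts the effect-allele frequency by
#' `+risk_delta/2` in the first target ancestral population and
#' `-risk_delta/2` in the second, clipping to [0.01, 0.99] (clips are
#' counted in a message). For two unadmixed cohorts from the target
#' populations the expected mean effect-allele-count difference is
#' `2 * n_risk_snps * risk_delta` (each shifted SNP contributes an expected
#' dosage difference of `2 * risk_delta`).
#'
#' @param freqs Frequency table from [simulate_frequencies()].
#' @param config A [sim_config()] object.
#' @param seed Seed for this stage.
#' @return List with `assoc` (trait association tibble: `id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `cohort_ancestry`,
#'   `effect_polarity`) and `freqs` (the table with shifted frequencies).
#' @export
embed_risk_architecture <- function(freqs, config, seed) {
  stopifnot(inherits(config, "sim_config"), config$n_risk_snps <= nrow(freqs))
  qcols <- paste0("q_", config$risk_target_pops)
  withr::with_seed(seed, {
    w <- if (config$ascertainment_power > 0) freqs$q_EUR^config$ascertainment_power else NULL
    risk_idx <- sample.int(nrow(freqs), config$n_risk_snps, prob = w)
    effect_derived <- runif(config$n_risk_snps) < config$derived_effect_fraction
  })
  # Shift derived-allele frequencies: a derived effect allele moves q up in
  # target pop 1 and down in pop 2; an ancestral effect allele the reverse.
  if (config$risk_delta != 0) {
    shift <- ifelse(effect_derived, 1, -1) * config$risk_delta / 2
    q1 <- freqs[[qcols[1]]][risk_idx] + shift
    q2 <- freqs[[qcols[2]]][risk_idx] - shift
    n_clip <- sum(q1 < 0.01 | q1 > 0.99 | q2 < 0.01 | q2 > 0.99)
    if (n_clip > 0) {
      inform(sprintf("embed_risk_architecture: clipped %d out-of-range shifted frequencies", n_clip))
    }
    freqs[[qcols[1]]][risk_idx] <- pmin(pmax(q1, 0.01), 0.99)
    freqs[[qcols[2]]][risk_idx] <- pmin(pmax(q2, 0.01), 0.99)
  }

  derived_allele <- ifelse(freqs$ancestral[risk_idx] == freqs$ref[risk_idx],
                           freqs$alt[risk_idx], freqs$ref[risk_idx])
  ancestral_allele <- freqs$ancestral[risk_idx]
  assoc <- tibble(
    id = freqs$id[risk_idx],
    chrom = freqs$chrom[risk_idx],
    pos = freqs$pos[risk_idx],
    effect_allele = ifelse(effect_derived, derived_allele, ancestral_allele),
    other_allele = ifelse(effect_derived, ancestral_allele, derived_allele),
    cohort_ancestry = "European",
    effect_polarity = ifelse(effect_derived, "derived", "ancestral")
  ) |> dplyr::arrange(.data$pos)
  list(assoc = assoc, freqs = freqs)
}

#' Simulate a complete two-cohort study
#'
#' Orchestrates the generator: frequencies, embedded risk architecture,
#' one genotype cohort per configured population, and a catalog-pool
#' association table covering the non-trait SNPs (each catalog SNP gets its
#' own effect allele, derived with probability `derived_effect_fraction`,
#' emulating the polarization mix of a curated GWAS catalog). All
#' randomness derives from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return List with `geno` (all cohorts combined), `membership`
#'   (`individual_id`, `population`), `ancestry` (truth fractions),
#'   `trait_assoc`, `catalog_assoc`, and `freqs` (post-shift truth table).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$seed, 3 + length(config$cohorts))
  freqs <- simulate_frequencies(config, seed = seeds[1])
  risk <- embed_risk_architecture(freqs, config, seed = seeds[2])

  cohorts <- purrr::imap(names(config$cohorts), function(nm, i) {
    simulate_cohort(risk$freqs, config, nm, seed = seeds[3 + i])
  })
  genos <- purrr::map(cohorts, "geno")
  dosage <- do.call(rbind, purrr::map(genos, "dosage"))
  ids <- unlist(purrr::map(genos, "individuals"))
  geno <- genotype_data(dosage, genos[[1]]$variants, ids)
  membership <- tibble(
    individual_id = ids,
    population = rep(names(config$cohorts), purrr::map_int(config$cohorts, "n"))
  )
  ancestry <- purrr::list_rbind(purrr::map(cohorts, "ancestry"))

  catalog_ids <- setdiff(risk$freqs$id, risk$assoc$id)
  cat_rows <- match(catalog_ids, risk$freqs$id)
  withr::with_seed(seeds[3], {
    cat_derived <- runif(length(cat_rows)) < config$derived_effect_fraction
  })
  derived_allele <- ifelse(risk$freqs$ancestral[cat_rows] == risk$freqs$ref[cat_rows],
                           risk$freqs$alt[cat_rows], risk$freqs$ref[cat_rows])
  catalog_assoc <- tibble(
    id = catalog_ids,
    chrom = risk$freqs$chrom[cat_rows],
    pos = risk$freqs$pos[cat_rows],
    effect_allele = ifelse(cat_derived, derived_allele, risk$freqs$ancestral[cat_rows]),
    other_allele = ifelse(cat_derived, risk$freqs$ancestral[cat_rows], derived_allele),
    cohort_ancestry = "European",
    effect_polarity = ifelse(cat_derived, "derived", "ancestral")
  )

  list(
    geno = geno, membership = membership, ancestry = ancestry,
    trait_assoc = risk$assoc, catalog_assoc = catalog_assoc,
    freqs = risk$freqs, config = config
  )
}

#' Write a simulated study to disk in the package's file dialects
#'
#' Emits `cohort.vcf` (all individuals, AA-annotated), `ancestry.tsv`,
#' `trait_assoc.tsv`, `catalog_assoc.tsv` and `membership.tsv` under `dir`.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(study$geno, file.path(dir, "cohort.vcf"))
  readr::write_tsv(study$ancestry, file.path(dir, "ancestry.tsv"))
  readr::write_tsv(study$trait_assoc, file.path(dir, "trait_assoc.tsv"))
  readr::write_tsv(study$catalog_assoc, file.path(dir, "catalog_assoc.tsv"))
  readr::write_tsv(study$membership, file.path(dir, "membership.tsv"))
  invisible(dir)
}
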