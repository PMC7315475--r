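test_that("Balding-Nichols frequencies have the configured mean and variance", {
  cfg <- sim_config(n_snps = 10000, n_risk_snps = 0, seed = 11)
  fr <- simulate_frequencies(cfg)
  expect_true(all(fr$q_AFR >= 0 & fr$q_AFR <= 1))
  # empirical variance of q - p across SNPs close to F * E[p(1-p)]
  for (k in c("q_AFR", "q_EUR", "q_NAT")) {
    v_emp <- mean((fr[[k]] - fr$p)^2)
    v_exp <- 0.15 * mean(fr$p * (1 - fr$p))
    expect_lt(abs(v_emp - v_exp) / v_exp, 0.10)
  }
})

test_that("drift F -> 0 collapses population frequencies onto p", {
  cfg <- sim_config(n_snps = 2000, n_risk_snps = 0,
                    f_st = c(AFR = 1e-4, EUR = 1e-4, NAT = 1e-4), seed = 3)
  fr <- simulate_frequencies(cfg)
  expect_lt(max(abs(fr$q_AFR - fr$p)), 0.05)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_snps = 300, n_risk_snps = 20, risk_delta = 0.1, seed = 7)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$geno$dosage, st2$geno$dosage)
  expect_identical(st1$freqs, st2$freqs)
  expect_identical(st1$trait_assoc, st2$trait_assoc)
  expect_identical(st1$ancestry, st2$ancestry)
})

test_that("an unadmixed cohort is in Hardy-Weinberg proportions at q_AFR", {
  cfg <- sim_config(
    n_snps = 50, n_risk_snps = 0,
    cohorts = list(PURE = list(n = 500, alpha = c(AFR = 1e6, EUR = 1e-6, NAT = 1e-6))),
    seed = 5
  )
  fr <- simulate_frequencies(cfg)
  co <- simulate_cohort(fr, cfg, "PURE", seed = 42)
  expect_true(all(abs(rowSums(as.matrix(co$ancestry[, -1])) - 1) < 1e-12))
  expect_gt(min(co$ancestry$f_African), 0.999)
  # derived-allele dosage mean ~ 2 q_AFR, genotype classes ~ HWE
  derived_is_alt <- fr$ancestral == fr$ref
  dd <- co$geno$dosage
  dd[, !derived_is_alt] <- 2L - dd[, !derived_is_alt]
  q <- fr$q_AFR
  se <- sqrt(2 * q * (1 - q) / 500)
  expect_true(all(abs(colMeans(dd) - 2 * q) < 4.5 * se))
  # heterozygosity close to 2q(1-q) on average
  expect_lt(abs(mean(colMeans(dd == 1L) - 2 * q * (1 - q))), 0.01)
})

test_that("admixed mean dosage matches the closed-form 2 * sum_k fbar_k q_k", {
  cfg <- sim_config(
    n_snps = 60, n_risk_snps = 0,
    cohorts = list(ADM = list(n = 500, alpha = c(AFR = 6, EUR = 3, NAT = 1))),
    seed = 9
  )
  fr <- simulate_frequencies(cfg)
  co <- simulate_cohort(fr, cfg, "ADM", seed = 21)
  fbar <- colMeans(as.matrix(co$ancestry[, c("f_African", "f_European", "f_NativeAmerican")]))
  q_derived <- as.matrix(fr[, c("q_AFR", "q_EUR", "q_NAT")])
  exp_derived <- 2 * as.vector(q_derived %*% fbar)
  derived_is_alt <- fr$ancestral == fr$ref
  exp_alt <- ifelse(derived_is_alt, exp_derived, 2 - exp_derived)
  obs <- colMeans(co$geno$dosage)
  se <- apply(co$geno$dosage, 2, stats::sd) / sqrt(500)
  expect_true(all(abs(obs - exp_alt) < 4.5 * se))
})

test_that("risk embedding shifts effect-allele frequencies by +/- delta/2", {
  cfg <- sim_config(n_snps = 2000, n_risk_snps = 200, risk_delta = 0.1, seed = 13)
  fr <- simulate_frequencies(cfg)
  emb <- embed_risk_architecture(fr, cfg, seed = 31)
  idx <- match(emb$assoc$id, fr$id)
  derived <- emb$assoc$effect_polarity == "derived"
  # effect-allele frequency difference between target populations grows by
  # delta relative to the pre-shift table (exactly, unless clipped)
  d_before <- ifelse(derived, fr$q_AFR[idx] - fr$q_EUR[idx],
                     (1 - fr$q_AFR[idx]) - (1 - fr$q_EUR[idx]))
  d_after <- ifelse(derived, emb$freqs$q_AFR[idx] - emb$freqs$q_EUR[idx],
                    (1 - emb$freqs$q_AFR[idx]) - (1 - emb$freqs$q_EUR[idx]))
  unclipped <- emb$freqs$q_AFR[idx] > 0.01 & emb$freqs$q_AFR[idx] < 0.99 &
    emb$freqs$q_EUR[idx] > 0.01 & emb$freqs$q_EUR[idx] < 0.99
  expect_gt(mean(unclipped), 0.8)
  expect_equal(d_after[unclipped] - d_before[unclipped],
               rep(0.1, sum(unclipped)), tolerance = 1e-12)
  # delta = 0 leaves the table untouched
  cfg0 <- sim_config(n_snps = 500, n_risk_snps = 50, risk_delta = 0, seed = 13)
  fr0 <- simulate_frequencies(cfg0)
  emb0 <- embed_risk_architecture(fr0, cfg0, seed = 31)
  expect_identical(emb0$freqs, fr0)
})

test_that("embedded differential gives expected count difference 2*n*delta in unadmixed cohorts", {
  cfg <- sim_config(
    n_snps = 400, n_risk_snps = 400, risk_delta = 0.1,
    cohorts = list(
      A = list(n = 300, alpha = c(AFR = 1e6, EUR = 1e-6, NAT = 1e-6)),
      B = list(n = 300, alpha = c(AFR = 1e-6, EUR = 1e6, NAT = 1e-6))
    ),
    seed = 17
  )
  st <- suppressMessages(simulate_study(cfg))
  oriented <- orient_dosages(st$geno, st$trait_assoc)
  d <- delta_prs(compute_prs(oriented$dosage[pop_ids(st, "A"), ]),
                 compute_prs(oriented$dosage[pop_ids(st, "B"), ]))
  # conditional expectation given the realised frequency table
  idx <- match(st$trait_assoc$id, st$freqs$id)
  derived <- st$trait_assoc$effect_polarity == "derived"
  q_diff <- st$freqs$q_AFR[idx] - st$freqs$q_EUR[idx]
  exp_cond <- 2 * sum(ifelse(derived, q_diff, -q_diff))
  # unconditional closed form: 2 * n_risk * delta (clipping makes it a shade
  # smaller; drift noise of the realised q's gives the sum an SD of about
  # 2 * sqrt(n * 2F * E[p(1-p)]) ~ 9.4, so allow 3 SD around 80)
  expect_lt(abs(exp_cond - 2 * 400 * 0.1), 28)
  # sampling error of the mean count difference across 300 + 300 genomes
  se <- sqrt(sum(
    2 * st$freqs$q_AFR[idx] * (1 - st$freqs$q_AFR[idx]) / 300 +
      2 * st$freqs$q_EUR[idx] * (1 - st$freqs$q_EUR[idx]) / 300
  ))
  expect_lt(abs(d$value - exp_cond), 4 * se)
})

test_that("derived effect-allele fraction defaults to the 56% GWAS mix", {
  cfg <- sim_config(n_snps = 1500, n_risk_snps = 1000, risk_delta = 0, seed = 19)
  fr <- simulate_frequencies(cfg)
  emb <- embed_risk_architecture(fr, cfg, seed = 23)
  frac <- mean(emb$assoc$effect_polarity == "derived")
  expect_lt(abs(frac - 0.56), 3 * sqrt(0.56 * 0.44 / 1000))
  # and the association table is oriented to the simulated ref/alt alleles
  idx <- match(emb$assoc$id, fr$id)
  expect_true(all(
    (emb$assoc$effect_allele == fr$ref[idx] & emb$assoc$other_allele == fr$alt[idx]) |
      (emb$assoc$effect_allele == fr$alt[idx] & emb$assoc$other_allele == fr$ref[idx])
  ))
})

test_that("write_study emits re-readable files in the package dialects", {
  cfg <- sim_config(n_snps = 40, n_risk_snps = 10, risk_delta = 0.1,
                    cohorts = list(
                      A = list(n = 5, alpha = c(AFR = 6, EUR = 3, NAT = 1)),
                      B = list(n = 5, alpha = c(AFR = 1, EUR = 6, NAT = 3))
                    ), seed = 29)
  st <- suppressMessages(simulate_study(cfg))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  g <- read_vcf(file.path(dir, "cohort.vcf"))
  expect_equal(unname(g$dosage), unname(st$geno$dosage))
  expect_equal(g$variants$ancestral, st$geno$variants$ancestral)
  anc <- read_ancestry_fractions(file.path(dir, "ancestry.tsv"))
  expect_equal(nrow(anc), 10)
  assoc <- read_association_table(file.path(dir, "trait_assoc.tsv"))
  expect_equal(sort(assoc$id), sort(st$trait_assoc$id))
})
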