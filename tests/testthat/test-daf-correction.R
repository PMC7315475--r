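test_that("derived allele frequency respects the ancestral polarization", {
  # one SNP each polarization, genotypes 0/1/2 across three individuals
  g <- toy_geno(cbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(0L, 1L, 2L)),
                ref = c("A", "A", "A"), alt = c("G", "G", "G"),
                ancestral = c("A", "G", NA))
  daf <- suppressMessages(compute_daf(g))
  expect_equal(daf$id, c("rs1", "rs2"))     # unknown ancestral excluded
  expect_equal(daf$daf, c(0.5, 0.5))        # complement symmetry at 0.5
  # asymmetric check: derived = alt with dosages (2,2,1) -> DAF 5/6
  g2 <- toy_geno(cbind(c(2L, 2L, 1L)), ancestral = "A")
  expect_equal(compute_daf(g2)$daf, 5 / 6)
  # ancestral = alt flips the accounting: derived count = 2 - dosage
  g3 <- toy_geno(cbind(c(2L, 2L, 1L)), ancestral = "G")
  expect_equal(compute_daf(g3)$daf, 1 / 6)
  # zero called alleles excluded with a warning
  g4 <- toy_geno(cbind(c(NA, NA, NA), c(0L, 1L, 0L)), ancestral = c("A", "A"))
  expect_warning(daf4 <- compute_daf(g4), "zero called")
  expect_equal(daf4$id, "rs2")
})

test_that("sample DAF estimates track the simulator's truth frequencies", {
  cfg <- sim_config(
    n_snps = 10, n_risk_snps = 0,
    cohorts = list(P = list(n = 400, alpha = c(AFR = 1e6, EUR = 1e-6, NAT = 1e-6))),
    seed = 31
  )
  fr <- simulate_frequencies(cfg)
  co <- simulate_cohort(fr, cfg, "P", seed = 8)
  daf <- compute_daf(co$geno)
  q <- fr$q_AFR[match(daf$id, fr$id)]
  se <- sqrt(q * (1 - q) / (2 * 400))
  expect_true(all(abs(daf$daf - q) < 4 * se))
})

test_that("trait DAF histograms bin on half-open intervals covering [0,1]", {
  daf_tbl <- tibble::tibble(id = sprintf("s%d", 1:6),
                            daf = c(0, 0.049, 0.05, 0.5, 0.999, 1))
  d <- trait_daf_distribution(daf_tbl, daf_tbl$id, bin_width = 0.05)
  expect_equal(sum(d$count), 6)
  expect_equal(d$count[d$bin == 1], 2)    # [0, 0.05) holds 0 and 0.049
  expect_equal(d$count[d$bin == 2], 1)    # [0.05, 0.10)
  expect_equal(d$count[d$bin == 11], 1)   # [0.50, 0.55)
  expect_equal(d$count[d$bin == 20], 2)   # [0.95, 1] closed on the right
  expect_equal(d$lower[1], 0)
  expect_equal(d$upper[20], 1)
  # all mass in one bin when every trait SNP has the same DAF
  d5 <- trait_daf_distribution(daf_tbl[4, ], "s4", bin_width = 0.05)
  expect_equal(sum(d5$count > 0), 1)
  # empty intersection is fatal
  expect_error(trait_daf_distribution(daf_tbl, "nope"), "no trait SNP")
})

test_that("hand-binned counts match trait_daf_distribution", {
  set.seed(2)
  daf <- round(runif(20), 3)
  tbl <- tibble::tibble(id = sprintf("s%d", 1:20), daf = daf)
  d <- trait_daf_distribution(tbl, tbl$id, bin_width = 0.1)
  hand <- table(factor(pmin(floor(daf / 0.1) + 1, 10), levels = 1:10))
  expect_equal(d$count, as.integer(hand))
})

test_that("DAF-matched draws reproduce the trait histogram bin-for-bin", {
  set.seed(3)
  catalog <- tibble::tibble(id = sprintf("c%d", 1:500), daf = runif(500))
  trait <- tibble::tibble(id = sprintf("t%d", 1:40), daf = runif(40))
  dist <- trait_daf_distribution(trait, trait$id, bin_width = 0.1)
  for (s in 1:5) {
    set <- daf_matched_sample(catalog, dist, derived_fraction = 0.56, seed = s)
    expect_equal(nrow(set), 40)
    expect_false(anyDuplicated(set$id) > 0)  # without replacement within a set
    got <- table(factor(set$bin, levels = dist$bin))
    expect_equal(as.integer(got), dist$count)
    # sampled SNPs really fall in the bins they claim
    daf_of <- catalog$daf[match(set$id, catalog$id)]
    expect_equal(pmin(floor(daf_of / 0.1) + 1, 10), set$bin)
  }
  # polarization mix over many sets approaches the requested fraction
  fr <- purrr::map_dbl(1:400, function(s) {
    mean(daf_matched_sample(catalog, dist, 0.56, seed = 1000 + s)$effect_is_derived)
  })
  expect_lt(abs(mean(fr) - 0.56), 3 * sqrt(0.56 * 0.44 / (400 * 40)))
  # a bin with too few catalog SNPs is fatal and names the bin
  skinny <- dplyr::filter(catalog, daf >= 0.2 | daf < 0.1)
  expect_error(daf_matched_sample(skinny, dist, 0.56, seed = 1),
               "\\[0\\.10,0\\.20\\)")
})

test_that("bin width 1 reduces matching to uniform sampling from the catalog", {
  catalog <- tibble::tibble(id = sprintf("c%d", 1:50), daf = runif(50))
  trait <- tibble::tibble(id = sprintf("t%d", 1:8), daf = runif(8))
  dist <- trait_daf_distribution(trait, trait$id, bin_width = 1)
  set <- daf_matched_sample(catalog, dist, 0.5, seed = 4)
  expect_equal(nrow(set), 8)
  expect_true(all(set$bin == 1))
})

test_that("matched-null decomposition equals the full PRS route on a forced set", {
  # catalog engineered so each occupied bin pool exactly equals the demand:
  # every draw must return the same unique set, making the null degenerate
  # and directly comparable to orient_dosages + compute_prs + delta_prs
  set.seed(6)
  dos <- matrix(sample(c(0L, 1L, 2L, NA), 10 * 6, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), nrow = 10)
  dos[is.na(dos[, 2]), 2] <- 0L
  anc_is_ref <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  g <- toy_geno(dos, ref = rep("A", 6), alt = rep("G", 6),
                ancestral = ifelse(anc_is_ref, "A", "G"))
  ids_a <- sprintf("I%d", 1:5)
  ids_b <- sprintf("I%d", 6:10)
  daf_all <- compute_daf(g)
  trait_dist <- trait_daf_distribution(daf_all, g$variants$id, bin_width = 1)
  catalog_daf <- daf_all
  for (frac in c(1, 0)) {
    null <- daf_matched_null(g, catalog_daf, trait_dist, ids_a, ids_b,
                             derived_fraction = frac, n_draws = 20, seed = 12)
    # every draw is the same set; summation order may differ by last-bit
    expect_lt(null$sd, 1e-12)
    # reference route: all six SNPs with derived (frac=1) or ancestral
    # (frac=0) effect alleles, through the PRS equation
    eff <- if (frac == 1) ifelse(anc_is_ref, "G", "A") else ifelse(anc_is_ref, "A", "G")
    assoc <- tibble::tibble(id = g$variants$id, effect_allele = eff,
                            other_allele = ifelse(eff == "A", "G", "A"))
    o <- orient_dosages(g, assoc)
    direct <- delta_prs(compute_prs(o$dosage[ids_a, ]), compute_prs(o$dosage[ids_b, ]))
    expect_equal(mean(null$samples), direct$value, tolerance = 1e-12)
  }
})

test_that("corrected delta-PRS is the z-score against the null", {
  # identity and centring properties
  n0 <- null_from_summary(mean = 0, sd = 1)
  expect_equal(corrected_delta_prs(1.7, n0)$corrected_z, 1.7)
  n1 <- null_from_summary(mean = -0.5, sd = 2)
  expect_equal(corrected_delta_prs(-0.5, n1)$corrected_z, 0)
  # z is exactly (obs - mean) / sd
  r <- corrected_delta_prs(3, null_from_summary(1, 0.8))
  expect_equal(r$corrected_z, (3 - 1) / 0.8)
  expect_true(is.na(r$empirical_p))
  # degenerate null is fatal
  expect_error(corrected_delta_prs(1, null_distribution(rep(2, 10))), "positive")
  # a count-scale observation cannot be compared to a normalized-scale null
  pa <- compute_prs(rbind(I1 = c(2L, 1L), I2 = c(1L, 1L)))
  pb <- compute_prs(rbind(J1 = c(0L, 1L), J2 = c(1L, 0L)))
  obs_n <- delta_prs(pa, pb, scale = "normalized")
  expect_error(corrected_delta_prs(obs_n, null_distribution(rnorm(50), scale = "count")),
               "scale")
})

test_that("the corrected z-score is invariant to affine rescaling of PRS", {
  set.seed(9)
  obs <- 2.3
  samples <- rnorm(2000, mean = 0.4, sd = 1.7)
  z0 <- corrected_delta_prs(obs, null_distribution(samples))$corrected_z
  # scaling every individual PRS by c (and shifting by b, which cancels in
  # the between-population difference) scales obs and null identically
  for (c_scale in c(0.01, 3, 250)) {
    z1 <- corrected_delta_prs(c_scale * obs,
                              null_distribution(c_scale * samples))$corrected_z
    expect_equal(z1, z0, tolerance = 1e-12)
  }
})

test_that("empirical and normal-theory P values are reported together", {
  set.seed(10)
  null <- null_distribution(rnorm(999))
  r <- corrected_delta_prs(1.2, null, direction = "greater")
  expect_equal(r$empirical_p, (sum(null$samples >= 1.2) + 1) / 1000)
  expect_equal(r$p_normal_one_tailed, pnorm(-abs(r$corrected_z)))
})
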