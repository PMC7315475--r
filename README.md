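# admixprs

Ancestry-aware polygenic risk score (PRS) analysis for admixed cohorts.

Unweighted PRS comparisons between populations with different continental
ancestry profiles — e.g. an Afro-descendant and a Mestizo cohort, or
European-American versus Mexican-American samples — are confounded by the
make-up of GWAS discovery cohorts: genotyping arrays and discovery power
both favour variants that are common in Europeans, and populations differ
systematically in the frequencies of ancestral versus derived alleles
through drift alone. A raw between-population PRS difference (ΔPRS)
therefore mixes true risk differentials with ancestry artefacts.

`admixprs` implements the full analysis chain for quantifying and
correcting that bias:

- **Scoring.** For each individual, the unweighted score over a trait SNP
  set is `PRS = Σᵢ Gᵢ / Σᵢ Aᵢ`, with `Gᵢ ∈ {0,1,2}` the effect-allele
  dosage at SNP *i* and `Aᵢ` the number of called alleles (2 or 0 for hard
  diploid calls). `ΔPRS` between two cohorts is reported on the
  effect-allele-count or normalized scale.
- **LD pruning.** Greedy windowed pruning of the trait set by pairwise
  dosage r² (default: 2000-SNP windows, r² > 0.1 pruned).
- **Ancestry regression.** OLS of PRS on per-individual continental
  ancestry fractions (`PRS_i = α + β·x_i + ε_i`), with broom-style
  `tidy()`/`glance()` output.
- **Permutation null.** ΔPRS for random catalog SNP sets of the same size
  as the trait set, giving an empirical null for the observed relative
  risk.
- **DAF-matched correction.** The ancestry-bias control: bin the trait
  set's derived-allele-frequency (DAF) distribution in the GWAS source
  population, resample catalog SNP sets matched to it bin-for-bin
  (preserving the trait set's ancestral/derived effect-allele mix), build
  the null ΔPRS distribution, and report the corrected score
  `corr.ΔPRS = (obsΔPRS − μ_null) / σ_null` with a one-tailed empirical P.
- **Synthetic cohorts.** A generator of admixed cohorts (Dirichlet
  ancestry proportions over Balding–Nichols population frequencies with
  explicit ancestral/derived polarization and an embeddable risk
  differential of known size) so the whole pipeline can be exercised and
  calibrated without external genotype panels.

Inputs are standard files: VCF genotypes (ancestral alleles via the `AA`
INFO tag, 1000 Genomes convention), tab-separated association tables and
ancestry-fraction tables.

## Worked example

```r
library(admixprs)

# A two-cohort synthetic study: 100 African-admixed and 100
# European-admixed genomes, 20,000 unlinked SNPs, 100 trait SNPs carrying
# an embedded effect-allele frequency differential of 0.1.
st    <- simulate_study(sim_config(risk_delta = 0.1, seed = 424))
afr   <- subset(st$membership, population == "AFRADM")$individual_id
eur   <- subset(st$membership, population == "EURADM")$individual_id

# Observed count-scale delta-PRS
o   <- orient_dosages(st$geno, st$trait_assoc)
obs <- delta_prs(compute_prs(o$dosage[afr, ]), compute_prs(o$dosage[eur, ]))
obs$value
#> [1] 15.99

# Ancestry slope: predicted risk rises with African ancestry
glance(fit_prs_ancestry(compute_prs(o), st$ancestry, "African"))[, c("beta", "r2", "p_two_tailed")]
#> # A tibble: 1 × 3
#>    beta    r2 p_two_tailed
#>   <dbl> <dbl>        <dbl>
#> 1 0.114 0.636     2.29e-45

# DAF-matched correction (source population: the European-admixed cohort)
daf_correction(st$geno, st$trait_assoc, st$catalog_assoc$id,
               ids_a = afr, ids_b = eur, source_ids = eur,
               n_draws = 5000, seed = 7, direction = "greater")
#> <correction_result> obs ΔPRS = 15.99 | null mean = -0.0731, sd = 3.095 |
#>   corrected z = 5.19 | empirical P = 2e-04
```

The corrected z of 5.2 says the African-admixed cohort carries an excess
of trait effect alleles that DAF-matched random SNP sets cannot explain —
the embedded differential is recovered. Under a null simulation
(`risk_delta = 0`) the same pipeline returns |z| ≲ 2.

## Documentation

The methods vignette (`vignettes/ancestry-bias-correction.Rmd`) describes
the model, the DAF-matching protocol and its tunable parameters, the
synthetic-cohort generator, and the package's calibration evidence.
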