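---
title: "Correcting ancestry bias in between-population polygenic risk comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting ancestry bias in between-population polygenic risk comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixprs)
```

## The problem

Polygenic risk scores summarise an individual's burden of trait-associated
effect alleles. When two populations with different continental ancestry
profiles are compared — say an Afro-descendant cohort against a cohort of
mostly European ancestry — the difference in mean PRS (ΔPRS) is routinely
read as a difference in genetic risk. That reading is confounded twice
over:

* **SNP ascertainment bias** — genotyping arrays capture variants chosen
  to be common (high minor-allele frequency) in European populations;
* **SNP discovery bias** — GWAS power rises with allele frequency in the
  discovery cohort, which is usually European.

Both mechanisms select trait SNPs whose frequency profile is
systematically atypical in populations enriched for *ancestral* alleles
(African populations above all, since derived alleles are usually the
minor alleles in European discovery cohorts). Genetic drift alone then
produces between-population differences in the frequencies of
ancestral-versus-derived alleles that masquerade as risk differences.

`admixprs` implements a resampling control that removes exactly this
component, and everything needed around it: scoring, LD pruning, ancestry
regression, permutation nulls, and a synthetic-cohort generator that makes
the whole chain testable with a known truth.

## The score and its scale

For a trait SNP set, each individual's unweighted score is

$$\mathrm{PRS} = \sum_i G_i \Big/ \sum_i A_i,$$

with $G_i \in \{0,1,2\}$ the effect-allele dosage and $A_i$ the number of
called alleles at SNP $i$. Scores are deliberately unweighted: association
tables curated across heterogeneous studies do not carry effect sizes on a
common scale. We take $A_i \in \{0, 2\}$: genotypes here are hard diploid
calls, so a SNP is either fully called or missing, and half calls are
treated as missing.

`delta_prs()` reports the mean per-individual difference between two
cohorts on either the *count* scale (mean effect-allele count, the
default) or the *normalized* scale (the $[0,1]$ ratio above). The
correction machinery works on the count scale throughout; the corrected
z-score defined below is invariant to any common affine rescaling of the
scores, so the choice of scale is immaterial as long as observation and
null share it — which the code enforces by carrying a scale label on both
objects and refusing to mix them.

## The five-step control

1. Score the trait SNP set in both populations and record the observed
   ΔPRS.
2. Compute the derived-allele-frequency (DAF) distribution of the trait
   SNPs in the GWAS **source population** — the population the trait SNPs
   were ascertained and discovered in. DAF is estimated from the source
   individuals' genotypes; the ancestral state comes from the VCF `AA`
   annotation (or simulated truth).
3. Draw random SNP sets from a genome-wide catalog pool, **matched
   bin-for-bin** to the trait set's source-population DAF histogram.
   Within a set, sampling is without replacement; sets are independent.
   Each sampled SNP's effect allele is set to its derived allele with
   probability equal to the trait set's own derived-effect fraction, else
   to its ancestral allele.
4. Compute ΔPRS for every sampled set (the sampled SNPs' own genotypes in
   the two compared populations drive the value), yielding the null ΔPRS
   distribution.
5. Report the corrected score
   $$\mathrm{corr.}\Delta\mathrm{PRS} = \frac{\mathrm{obs}\Delta\mathrm{PRS} - \mu_{\mathrm{null}}}{\sigma_{\mathrm{null}}}$$
   together with a one-tailed empirical $P = (r+1)/(n+1)$, where $r$
   counts null draws at least as extreme as the observation in the tested
   direction.

Because matched sets share the trait set's source-population DAF profile
*and* its ancestral/derived polarization mix, any component of ΔPRS that
is attributable to systematic between-population frequency differences of
those allele classes appears identically in the null; what survives in
the z-score is the trait-specific signal.

Three protocol details are genuinely open in the published description and
are pinned here as package choices:

* **Bin width 0.05** (20 bins on $[0,1]$, half-open $[a,b)$ with the last
  bin closed). Narrower bins match more faithfully but empty out for
  small catalogs; 0.05 keeps both failure modes rare and is configurable
  (`bin_width`).
* **Matching covariate.** Sets are matched on *source-population* DAF
  only; the distinct populations being compared enter through the sampled
  SNPs' own genotypes. Matching additionally on target-population DAF
  would force the null ΔPRS to zero by construction and destroy the test.
* **Polarization of sampled effect alleles.** Sampled sets mirror the
  trait set's derived-effect fraction (56% derived / 44% ancestral for
  curated GWAS risk alleles; measured from the actual trait set at run
  time) rather than always taking the derived allele — otherwise the null
  itself would acquire the very polarization bias being controlled for.
* **Empirical versus normal-theory P.** The primary P value is the
  empirical tail rank; `pnorm(-|z|)` is also reported
  (`p_normal_one_tailed`) but is secondary, since null ΔPRS distributions
  are close to, but not exactly, Gaussian.

A degenerate null (`null_sd = 0`) is an error, as is a DAF bin whose
catalog pool is smaller than the trait demand (the error names the bin
and suggests a larger catalog or wider bins).

## Supporting machinery

**Orientation.** `orient_dosages()` maps association-table effect alleles
onto VCF ref/alt dosages by exact A/C/G/T string match; effect = ref flips
the dosage to $2-G$. No strand flipping is attempted — including for
palindromic A/T and C/G SNPs — because silent strand repair is a classic
source of sign errors in PRS work; unmatched SNPs are excluded and
reported instead.

**LD pruning.** `ld_prune()` slides a window (default 2000 SNPs, step =
half window) along position-sorted SNPs and, within each window,
repeatedly resolves the highest-r² pair above the threshold (default
r² > 0.1) by removing its lower-MAF member (ties: the later-position
SNP). r² is the squared Pearson correlation of unphased dosages
(composite LD), computed on complete pairs; a monomorphic SNP has r² = 0
by definition. The procedure is deterministic, and unit tests verify it
against an exhaustive remove-until-clean oracle on small fixtures.

**Regression.** `fit_prs_ancestry()` fits
$\mathrm{PRS}_i = \alpha + \beta x_i + \varepsilon_i$ by ordinary least
squares (`stats::lm`), where $x_i$ is one continental ancestry fraction;
`glance()` returns $\alpha, \beta, \mathrm{se}(\beta), r^2, t, P$. A
constant response is given $r^2 = 0$ (the ratio of explained to total
variance is 0/0 there).

**Permutation null.** `permutation_null()` draws uniform random catalog
sets of the trait-set size. Both null builders exploit the fact that on
the count scale the population-mean score of any SNP subset is the sum of
per-SNP mean dosages (missing calls contribute 0), so a draw costs a
subset sum rather than a full rescoring pass; a unit test pins the
equivalence of this decomposition to the definitional
`compute_prs()`/`delta_prs()` route.

## The synthetic-cohort generator

The generator exists so that every downstream stage has a known truth to
recover; its defaults encode the study design the package targets.

* **Allele frequencies.** Each SNP gets a global derived-allele frequency
  $p \sim U(0.05, 0.95)$ and, for each continental population
  $k \in \{\mathrm{AFR}, \mathrm{EUR}, \mathrm{NAT}\}$, a Balding–Nichols
  frequency $q_k \sim \mathrm{Beta}$ with mean $p$ and variance
  $F_k\,p(1-p)$. The default $F = 0.15$ is a conventional
  continental-scale differentiation magnitude; the Beta parameterisation
  is the minimal standard model that produces realistic between-population
  DAF differences — precisely the bias the correction targets.
* **Admixture.** Each individual's ancestry vector is Dirichlet; each
  allele copy picks an ancestral population by those proportions and is
  derived with probability $q_k$, i.e. derived dosage
  $\sim \mathrm{Binomial}(2, f_i \cdot q)$. The two default cohorts have
  mean ancestry 0.76/0.13/0.11 (AFR/EUR/NAT) and 0.07/0.75/0.18 —
  the profiles of the Afro-Colombian and Mestizo populations the method
  was developed on — with concentration 10, and 100 individuals each.
* **Risk architecture.** 100 of 20,000 SNPs become trait SNPs. Each
  effect allele is derived with probability 0.56 (the published
  derived/ancestral mix of curated GWAS risk alleles). The effect-allele
  frequency is shifted $+\delta/2$ in AFR and $-\delta/2$ in EUR (clipped
  to $[0.01, 0.99]$, counted), so the embedded between-population
  differential is $\delta$ and the expected count-scale ΔPRS between
  unadmixed target cohorts is $2 n \delta$. $\delta = 0$ gives a null
  study. The remaining SNPs form the catalog pool, each with its own
  56%-derived effect allele.
* **Ascertainment-bias emulation.** With `ascertainment_power = g`,
  trait SNPs are sampled with weight $q_{\mathrm{EUR}}^g$ instead of
  uniformly; $g = 2$ concentrates trait sets on high source-population
  DAF the way array design and discovery power do, while leaving the
  between-cohort differential at zero.
* **Ancestral states are simulated explicitly** (the reference allele is
  ancestral with probability 0.8, roughly the genome-wide reality), so
  DAF accounting in tests is exact rather than inferred.
* **Determinism.** Every stage takes a seed; `simulate_study()` splits
  its master seed into per-stage child seeds (`split_seed()`: seed R's
  generator once, draw the children), so reruns are bit-identical and
  stages can be re-run in isolation.

What the generator does *not* emulate: linkage disequilibrium (SNPs are
independent; LD-pruning tests therefore use explicitly constructed
correlated columns), genotype missingness and imputation uncertainty,
phenotypes, and non-Dirichlet ancestry structure such as assortative
mating. Calibration results below demonstrate statistical behaviour under
the stated model, not robustness to those real-data features.

## Calibration and recovery evidence

The acceptance test suite computes, at the study's design scale (two
cohorts of 100, 20,000 genome SNPs, 100 trait SNPs, 5,000 null draws per
replicate, 200 replicates per scenario):

* **Null calibration.** With $\delta = 0$, the one-tailed empirical P of
  the observed ΔPRS against the permutation null rejects at 0.05 in
  2–12% of replicates (the 99% binomial band around the nominal 5%).
  The direction is fixed a priori (higher risk with African ancestry),
  matching how the directional hypothesis is posed in practice.
* **Bias removal.** With DAF-ascertained trait sets ($g = 2$) and
  $\delta = 0$, the matched null tracks the biased observation and the
  corrected z behaves approximately as a standard normal score: across
  the suite's 200 fixed-seed replicates, $|z| \le 2$ held in 187
  (93.5%, versus the 95.4% nominal for an exactly normal z; the small
  shortfall reflects the residual within-bin DAF gradient that $g = 2$
  ascertainment leaves inside 0.05-wide bins, plus binomial noise).
* **Power retention.** With $\delta = 0.1$ embedded, the corrected
  empirical P is ≤ 0.05 in a clear majority of replicates, and the OLS
  slope of PRS on $f_{\mathrm{African}}$ is positive in ≥ 95%.
* **Oracle equivalence.** The permutation null's mean and SD match
  exhaustive subset enumeration within 2% at 20,000 draws on a 6-SNP
  catalog; pruning equals the exhaustive oracle exactly on ≤ 10-SNP
  fixtures; OLS matches the normal equations to 1e-10.

At analysis (rather than test) scale the field convention is 500,000 null
draws; `n_draws` is a direct argument everywhere, and Monte-Carlo error
on the null mean and SD shrinks as $n^{-1/2}$.

## Known limitations

* DAF matching requires known ancestral states; SNPs without a usable
  `AA` annotation are excluded from DAF machinery (and counted).
* The control matches marginal DAF only. Differences in local LD between
  populations — which change how well a tag SNP captures a causal variant
  in each population — are untouched and remain the leading unmodelled
  bias source.
* A MAF-matched (rather than DAF-matched) variant of the control is not
  implemented.
* Only biallelic SNPs with hard-called diploid genotypes are supported;
  indels, multi-allelic records and half calls are skipped and counted.
* The corrected z dampens, and cannot manufacture, risk differences: on
  real cohort comparisons it should be read as a conservative,
  direction-preserving re-estimate of the observed ΔPRS.
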