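# Internal helpers shared across modules.

#' Derive independent child seeds from one master seed
#'
#' All stochastic stages in the package draw their randomness from a single
#' integer seed. When a pipeline stage needs several independent streams
#' (e.g. frequencies, then one cohort per population), it derives child seeds
#' with this function: the master seed seeds R's generator once and `n`
#' integers are drawn from it. Child seeds are kept below 2^31 so they remain
#' valid R integer seeds.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 1L)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Column means of a dosage matrix with missing dosages contributing 0.
# On the allele-count PRS scale an individual's score is the sum of effect
# dosages over called SNPs, so a missing dosage contributes 0 to the sum and
# the population mean count decomposes into per-SNP means with NA -> 0.
zero_na_colmeans <- function(m) {
  m[is.na(m)] <- 0
  colMeans(m)
}

is_snp_base <- function(x) x %in% c("A", "C", "G", "T")
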