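# Windowed pairwise-r2 linkage-disequilibrium pruning.

#' Pairwise r-squared between two dosage vectors
#'
#' Squared Pearson correlation of genotype dosages (composite-genotype LD,
#' appropriate for unphased hard calls), computed over individuals with
#' both SNPs called. A monomorphic SNP gives r2 = 0 by definition; fewer
#' than two complete pairs gives `NA` with a warning.
#'
#' @param x,y Numeric dosage vectors of equal length (`NA` = missing).
#' @return A value in \[0, 1\], or `NA` if undefined.
#' @export
pairwise_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) {
    warn("pairwise_r2: fewer than 2 complete pairs; r2 undefined")
    return(NA_real_)
  }
  x <- x[ok]
  y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  cor(x, y)^2
}

# Pairwise r2 matrix over columns; NA (monomorphic or too few complete
# pairs) treated as 0 = "pair not considered".
r2_matrix <- function(m) {
  r2 <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  diag(r2) <- 0
  r2
}

#' Prune SNPs to an approximately independent set by windowed pairwise r2
#'
#' Greedy windowed pruning over SNPs sorted by (chromosome, position):
#' within each window of `window_size` SNPs, while any retained pair has
#' r2 above `r2_threshold`, the pair with the largest r2 is resolved
#' (ties: the pair earliest in position order) by removing its lower-MAF
#' member (MAF tie: the later-position SNP); the window then slides by
#' `window_step`. The output is deterministic, and within every window no
#' retained pair exceeds the threshold.
#'
#' @param geno A [genotype_data] object; r2 and MAF are computed on all of
#'   its individuals (pool the populations being analysed before pruning).
#' @param snps Optional character vector restricting pruning to these
#'   variant IDs (e.g. a trait-association set).
#' @param window_size Window size in SNPs (default 2000).
#' @param r2_threshold Pairs above this r2 are pruned (default 0.1).
#' @param window_step Slide in SNPs (default half the window).
#' @return A tibble of the considered SNPs in (chrom, pos) order with
#'   columns `id`, `chrom`, `pos`, `maf`, `retained`.
#' @export
ld_prune <- function(geno, snps = NULL, window_size = 2000, r2_threshold = 0.1,
                     window_step = ceiling(window_size / 2)) {
  stopifnot(inherits(geno, "genotype_data"), window_size >= 2,
            r2_threshold > 0, r2_threshold <= 1, window_step >= 1)
  ids <- snps %||% geno$variants$id
  g <- subset_genotypes(geno, snps = ids)
  ord <- order(g$variants$chrom, g$variants$pos)
  v <- g$variants[ord, ]
  dos <- g$dosage[, ord, drop = FALSE]
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)

  retained <- rep(TRUE, nrow(v))
  for (chr in unique(v$chrom)) {
    in_chr <- which(v$chrom == chr)
    m <- length(in_chr)
    starts <- unique(pmin(seq(1L, m, by = window_step), max(1L, m - window_size + 1L)))
    for (s in starts) {
      win <- in_chr[s:min(s + window_size - 1L, m)]
      act <- win[retained[win]]
      if (length(act) < 2) next
      drop <- prune_window(dos[, act, drop = FALSE], maf[act], v$pos[act],
                           r2_threshold)
      retained[act[drop]] <- FALSE
    }
  }
  tibble(id = v$id, chrom = v$chrom, pos = v$pos, maf = unname(maf),
         retained = retained)
}

# Indices (into the supplied columns) of SNPs to REMOVE so that no
# remaining pair has r2 > threshold; deterministic greedy resolution.
prune_window <- function(dos, maf, pos, r2_threshold) {
  keep <- seq_len(ncol(dos))
  r2 <- r2_matrix(dos)
  removed <- integer(0)
  repeat {
    sub <- r2[keep, keep, drop = FALSE]
    over <- which(sub > r2_threshold, arr.ind = TRUE)
    over <- over[over[, 1] < over[, 2], , drop = FALSE]
    if (nrow(over) == 0) break
    vals <- sub[over]
    best <- which(vals == max(vals))
    # tie-break: earliest pair in (i, j) order
    pick <- over[best[order(over[best, 1], over[best, 2])][1], ]
    i <- keep[pick[1]]
    j <- keep[pick[2]]
    drop_idx <- if (maf[i] < maf[j]) i
                else if (maf[j] < maf[i]) j
                else if (pos[i] > pos[j]) i else j
    removed <- c(removed, drop_idx)
    keep <- setdiff(keep, drop_idx)
  }
  removed
}
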