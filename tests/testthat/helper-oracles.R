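# Independent oracles used by the unit and acceptance suites. These are
# deliberately naive re-derivations (loops, enumeration, closed forms) and
# never call the code paths they check.

# Exhaustive remove-until-clean pruning with the pinned resolution rule
# (highest r2 pair first, earliest pair on ties; drop the lower-MAF member,
# later position on MAF ties). Returns retained column indices.
oracle_prune <- function(dos, maf, pos, thr) {
  keep <- seq_len(ncol(dos))
  repeat {
    worst <- NULL
    worst_r2 <- thr
    for (a in seq_along(keep)) {
      for (b in seq_along(keep)) {
        if (a >= b) next
        x <- dos[, keep[a]]
        y <- dos[, keep[b]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2) next
        if (var(x[ok]) == 0 || var(y[ok]) == 0) next
        r2 <- cor(x[ok], y[ok])^2
        if (r2 > worst_r2 + 1e-15) {
          worst <- c(keep[a], keep[b])
          worst_r2 <- r2
        }
      }
    }
    if (is.null(worst)) break
    i <- worst[1]
    j <- worst[2]
    drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j
            else if (pos[i] > pos[j]) i else j
    keep <- setdiff(keep, drop)
  }
  keep
}

# All size-k subsets of a catalog, delta-PRS computed through the full PRS
# route (orientation already applied by the caller via an effect-dosage
# matrix). Returns the exact enumeration of the permutation-null support.
oracle_enumerate_null <- function(eff_dosage, ids_a, ids_b, k) {
  subsets <- utils::combn(ncol(eff_dosage), k)
  apply(subsets, 2, function(cols) {
    sub <- eff_dosage[, cols, drop = FALSE]
    pa <- compute_prs(sub[ids_a, , drop = FALSE])
    pb <- compute_prs(sub[ids_b, , drop = FALSE])
    delta_prs(pa, pb)$value
  })
}
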