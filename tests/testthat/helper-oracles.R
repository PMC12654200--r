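# independent re-walk of the FCBF predicate: feature f survives iff its SU with
# the class exceeds delta and no kept feature predicts it at least as well
brute_fcbf <- function(bins, su_class, wn, delta = 0) {
  ord <- order(-su_class, wn)
  ord <- ord[su_class[ord] > delta]
  kept <- integer(0)
  for (f in ord) {
    red <- FALSE
    for (g in kept)
      if (symmetrical_uncertainty(bins[, g], bins[, f]) >= su_class[f]) red <- TRUE
    if (!red) kept <- c(kept, f)
  }
  sort(wn[kept])
}

# O(n^3) Ward oracle via the Lance-Williams ward.D2 update
brute_ward <- function(d) {
  n <- nrow(d); sizes <- rep(1, n)
  active <- seq_len(n); id <- -seq_len(n)  # hclust merge convention
  d <- as.matrix(d); heights <- numeric(0); merges <- NULL
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i < j && d[active[i], active[j]] < bv) {
        bv <- d[active[i], active[j]]; best <- c(i, j)
      }
    }
    ai <- active[best[1]]; aj <- active[best[2]]
    heights <- c(heights, bv)
    merges <- rbind(merges, sort(c(id[ai], id[aj])))
    for (k in active) {
      if (k == ai || k == aj) next
      d[ai, k] <- d[k, ai] <- sqrt(
        ((sizes[ai] + sizes[k]) * d[k, ai]^2 +
         (sizes[aj] + sizes[k]) * d[k, aj]^2 -
         sizes[k] * d[ai, aj]^2) / (sizes[ai] + sizes[aj] + sizes[k]))
    }
    sizes[ai] <- sizes[ai] + sizes[aj]
    id[ai] <- step
    active <- setdiff(active, aj)
  }
  list(heights = heights, merges = merges)
}
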