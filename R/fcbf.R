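#' FCBF configuration
#'
#' @param delta Symmetrical-uncertainty relevance threshold in `[0, 1)`;
#'   features with `SU(f, class) <= delta` are dropped before the redundancy
#'   pass. 0 (the canonical FCBF default) keeps any positive-SU feature.
#' @param discretizer `"median_split"` (default; deterministic and stable at
#'   small n), `"equal_frequency_k"` (k quantile bins), or `"mdl"`
#'   (Fayyad-Irani entropy cuts; features with no accepted cut collapse to a
#'   single bin and get SU 0).
#' @param k_bins Bin count for `"equal_frequency_k"`.
#' @return An `fcbf_config` list.
#' @export
fcbf_config <- function(delta = 0,
                        discretizer = c("median_split", "equal_frequency_k", "mdl"),
                        k_bins = 2L) {
  stopifnot(delta >= 0, delta < 1, k_bins >= 2)
  structure(list(delta = delta, discretizer = match.arg(discretizer),
                 k_bins = as.integer(k_bins)),
            class = "fcbf_config")
}

entropy_bits <- function(x) {
  p <- tabulate(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Symmetrical uncertainty between two discrete variables
#'
#' `SU = 2 I(X;Y) / (H(X) + H(Y))` with base-2 entropies estimated from the
#' empirical joint frequencies; 0 when `H(X) + H(Y) = 0` (both constant).
#' SU is symmetric and lies in `[0, 1]`, reaching 1 for a bijective
#' dependence.
#'
#' @param x,y Integer/factor vectors of equal length >= 2.
#' @return SU in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  x <- as.integer(factor(x)); y <- as.integer(factor(y))
  hx <- entropy_bits(x); hy <- entropy_bits(y)
  if (hx + hy == 0) return(0)
  hxy <- entropy_bits(x + max(x) * (y - 1L))
  mi <- hx + hy - hxy
  2 * mi / (hx + hy)
}

#' Supervised discretization of one feature
#'
#' @param values Numeric feature vector (>= 2 samples).
#' @param labels Class labels (required by the `"mdl"` discretizer).
#' @param config An [fcbf_config()].
#' @return Integer bin codes (1-based). A constant feature (or an MDL run
#'   with no accepted cut) yields a single bin, hence downstream SU 0.
#' @export
discretize <- function(values, labels = NULL, config = fcbf_config()) {
  stopifnot(length(values) >= 2)
  switch(config$discretizer,
    median_split = as.integer(values > stats::median(values)) + 1L,
    equal_frequency_k = {
      br <- unique(stats::quantile(values, probs = seq(0, 1, length.out = config$k_bins + 1L),
                                   type = 7, names = FALSE))
      if (length(br) < 2L) rep(1L, length(values))
      else as.integer(cut(values, br, include.lowest = TRUE))
    },
    mdl = {
      if (is.null(labels)) stop("mdl discretization requires labels", call. = FALSE)
      cuts <- mdl_cuts(values, as.integer(factor(labels)))
      if (length(cuts) == 0L) rep(1L, length(values))
      else as.integer(cut(values, c(-Inf, cuts, Inf)))
    })
}

# Fayyad-Irani recursive entropy-MDL cut search
mdl_cuts <- function(values, labels) {
  ord <- order(values)
  rec <- function(v, l) {
    n <- length(v)
    if (n < 2L) return(numeric(0))
    ent <- function(ll) entropy_bits(ll)
    base_ent <- ent(l)
    # candidate cuts at midpoints between distinct adjacent values
    uv <- unique(v)
    if (length(uv) < 2L) return(numeric(0))
    cand <- (uv[-1] + uv[-length(uv)]) / 2
    best <- NULL; best_gain <- -Inf
    for (cp in cand) {
      left <- l[v <= cp]; right <- l[v > cp]
      e <- (length(left) * ent(left) + length(right) * ent(right)) / n
      gain <- base_ent - e
      if (gain > best_gain) {
        best_gain <- gain; best <- cp
        best_parts <- list(left = left, right = right)
      }
    }
    k <- length(unique(l))
    k1 <- length(unique(best_parts$left)); k2 <- length(unique(best_parts$right))
    delta <- log2(3^k - 2) -
      (k * base_ent - k1 * ent(best_parts$left) - k2 * ent(best_parts$right))
    if (best_gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    c(rec(v[v <= best], l[v <= best]), best, rec(v[v > best], l[v > best]))
  }
  sort(rec(values[ord], labels[ord]))
}

#' Fast Correlation-Based Filter feature selection
#'
#' From-scratch FCBF over spectral features: (1) discretize each feature and
#' compute its symmetrical uncertainty with the class; (2) rank decreasing,
#' dropping `SU <= delta`; (3) walk the ranked list keeping the head and
#' removing every later feature `f_j` with
#' `SU(f_kept, f_j) >= SU(f_j, class)` (redundancy: `f_j` is at least as
#' predictable from an already-kept feature as from the class), repeating
#' from the next survivor. SU ties are broken by ascending wavenumber, so
#' the result is deterministic and invariant to column order.
#'
#' @param features Numeric matrix (samples x features) with wavenumber
#'   column names.
#' @param labels Class labels (two classes, >= 2 samples each).
#' @param config An [fcbf_config()].
#' @return Data frame `selected` with columns `wavenumber` and `su_to_class`
#'   in decreasing SU order.
#' @export
fcbf_select <- function(features, labels, config = fcbf_config()) {
  features <- as.matrix(features)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; FCBF needs two", call. = FALSE)
  if (min(table(labels)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  wn <- as.numeric(colnames(features))
  if (anyNA(wn)) stop("features need numeric wavenumber column names", call. = FALSE)

  bins <- apply(features, 2L, discretize, labels = labels, config = config)
  su_class <- apply(bins, 2L, symmetrical_uncertainty, y = labels)

  keep <- which(su_class > config$delta)
  if (length(keep) == 0L)
    return(data.frame(wavenumber = numeric(0), su_to_class = numeric(0)))
  ord <- keep[order(-su_class[keep], wn[keep])]

  alive <- rep(TRUE, length(ord))
  i <- 1L
  while (i <= length(ord)) {
    if (alive[i]) {
      fi <- ord[i]
      j <- i + 1L
      while (j <= length(ord)) {
        if (alive[j]) {
          fj <- ord[j]
          if (symmetrical_uncertainty(bins[, fi], bins[, fj]) >= su_class[fj])
            alive[j] <- FALSE
        }
        j <- j + 1L
      }
    }
    i <- i + 1L
  }
  sel <- ord[alive]
  data.frame(wavenumber = wn[sel], su_to_class = unname(su_class[sel]))
}
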