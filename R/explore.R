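#' Pairwise cosine distance matrix
#'
#' `d(i, j) = 1 - cos(x_i, x_j)`: 0 for identical shapes, 1 for orthogonal
#' rows, 2 for antiparallel ones.
#'
#' @param set A [spectra_set()] with no zero-norm rows.
#' @return Symmetric matrix with zero diagonal and donor-id dimnames.
#' @export
cosine_distance_matrix <- function(set) {
  nrm <- sqrt(rowSums(set$matrix^2))
  if (any(nrm == 0)) stop("zero-norm row", call. = FALSE)
  xn <- set$matrix / nrm
  d <- 1 - tcrossprod(xn)
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(set$meta$donor_id, set$meta$donor_id)
  d
}

#' Metric MDS by classical scaling + SMACOF stress majorization
#'
#' Initializes with classical (Torgerson) scaling of the double-centered
#' squared-distance matrix, then refines with SMACOF majorization updates
#' until the relative stress change drops below `tol` or `max_iter`
#' iterations. Fully deterministic; `seed` is accepted only so callers can
#' record one seed per analysis stage.
#'
#' @param d Symmetric distance matrix.
#' @param dims Embedding dimension (default 2).
#' @param seed Recorded, unused (no random restarts).
#' @param max_iter,tol Majorization stopping rule.
#' @return List: `points` (n x dims), `stress` (raw stress), `stress_trace`
#'   (non-increasing across iterations), `iterations`.
#' @export
mds_embed <- function(d, dims = 2L, seed = 1L, max_iter = 300L, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (all(d == 0)) {
    pts <- matrix(0, n, dims)
    rownames(pts) <- rownames(d)
    return(list(points = pts, stress = 0, stress_trace = 0, iterations = 0L))
  }
  cs <- stats::cmdscale(d, k = dims)
  x <- matrix(0, n, dims)
  x[, seq_len(ncol(cs))] <- cs

  stress_of <- function(x) {
    dx <- as.matrix(stats::dist(x))
    sum((d[upper.tri(d)] - dx[upper.tri(dx)])^2)
  }
  trace <- stress_of(x)
  for (it in seq_len(max_iter)) {
    dx <- as.matrix(stats::dist(x))
    ratio <- ifelse(dx > 0, d / pmax(dx, .Machine$double.xmin), 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- b %*% x / n
    s <- stress_of(x)
    trace <- c(trace, s)
    prev <- trace[length(trace) - 1L]
    if (prev == 0 || (prev - s) / max(prev, .Machine$double.xmin) < tol) break
  }
  rownames(x) <- rownames(d)
  list(points = x, stress = trace[length(trace)], stress_trace = trace,
       iterations = length(trace) - 1L)
}

#' Ward hierarchical clustering on a distance matrix
#'
#' Agglomerative clustering with Ward's criterion via the Lance-Williams
#' `ward.D2` update applied to the supplied distances (here typically cosine
#' distances, which are not Euclidean — the linkage is still well defined
#' and merge heights are monotone non-decreasing).
#'
#' @param d Symmetric distance matrix.
#' @return An [stats::hclust] object.
#' @export
ward_cluster <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 items", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

# Hilbert-Noda transformation matrix: N[j,k] = 1/(pi (k - j)), 0 on diagonal
noda_matrix <- function(m) {
  jk <- outer(seq_len(m), seq_len(m), function(j, k) k - j)
  n <- 1 / (pi * jk)
  n[jk == 0] <- 0
  n
}

#' Generalized 2D correlation spectroscopy maps
#'
#' Dynamic spectra are the rows minus the mean spectrum, taken in the order
#' of a declared perturbation sequence (default: group blocks, DBD first,
#' then donor id — the maps depend on the ordering, so it is explicit and
#' returned). The synchronous map is `t(Yd) Yd / (m - 1)` (its diagonal is
#' the per-wavenumber sample variance); the asynchronous map is
#' `t(Yd) N Yd / (m - 1)` with the Hilbert-Noda matrix `N`, capturing
#' out-of-phase co-variation.
#'
#' @param set A preprocessed, windowed [spectra_set()] with >= 2 rows.
#' @param order Optional integer row ordering (the perturbation sequence).
#' @return List: `grid`, `sync`, `async`, `order` (row indices used).
#' @export
twodcos_maps <- function(set, order = NULL) {
  m <- nrow(set$matrix)
  if (m < 2L) stop("need at least 2 spectra", call. = FALSE)
  if (is.null(order))
    order <- order(match(set$meta$group, c("DBD", "DCD", "UNKNOWN")),
                   set$meta$donor_id)
  yd <- set$matrix[order, , drop = FALSE]
  yd <- sweep(yd, 2L, colMeans(yd))
  sync <- crossprod(yd) / (m - 1)
  async <- t(yd) %*% noda_matrix(m) %*% yd / (m - 1)
  async <- (async - t(async)) / 2  # enforce exact antisymmetry
  diag(async) <- 0
  list(grid = set$grid, sync = sync, async = async, order = order)
}
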