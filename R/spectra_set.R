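#' Single FTIR spectrum
#'
#' Container for one absorbance trace on an ascending wavenumber axis plus
#' donor/replicate/group metadata. Group labels are mapped case-insensitively
#' to `"DCD"` / `"DBD"`; anything else becomes `"UNKNOWN"` (tolerated by QC
#' and unsupervised stages, rejected by supervised ones).
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, length >= 2.
#' @param absorbance Numeric vector of absorbance values, same length as
#'   `wavenumbers`, all finite.
#' @param donor_id,replicate_id Opaque identifier strings.
#' @param group Group label; one of `"DCD"`, `"DBD"`, `"UNKNOWN"`
#'   (case-insensitive).
#' @return An object of class `ftir_spectrum`: a list with fields
#'   `wavenumbers`, `absorbance`, `donor_id`, `replicate_id`, `group`.
#' @export
#' @examples
#' s <- ftir_spectrum(seq(900, 1800, by = 2), rnorm(451, 0.5, 0.01), "D1", "r1", "DCD")
ftir_spectrum <- function(wavenumbers, absorbance, donor_id = "",
                          replicate_id = "", group = "UNKNOWN") {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) < 2L)
    stop("spectrum needs at least 2 points", call. = FALSE)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance differ in length", call. = FALSE)
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  if (!all(is.finite(absorbance)))
    stop("absorbance contains non-finite values", call. = FALSE)
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         donor_id = as.character(donor_id),
         replicate_id = as.character(replicate_id),
         group = normalize_group(group)),
    class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> donor=%s rep=%s group=%s | %d points, %.6g-%.6g cm^-1\n",
              x$donor_id, x$replicate_id, x$group, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

normalize_group <- function(g) {
  g <- toupper(as.character(g))
  g[!(g %in% c("DCD", "DBD"))] <- "UNKNOWN"
  g
}

#' Axis-aligned collection of spectra
#'
#' The pipeline's universal currency: an `n_spectra x n_points` absorbance
#' matrix whose columns all live on one shared, strictly increasing
#' wavenumber grid, with per-row donor/replicate/group metadata.
#'
#' @param grid Shared wavenumber axis (cm^-1), strictly increasing.
#' @param matrix Numeric matrix, `nrow = nrow(meta)`, `ncol = length(grid)`.
#' @param meta Data frame with columns `donor_id`, `replicate_id`, `group`
#'   (one row per spectrum); `(donor_id, replicate_id)` pairs must be unique.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, matrix, meta) {
  grid <- as.numeric(grid)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with >= 2 points", call. = FALSE)
  if (ncol(matrix) != length(grid))
    stop("matrix column count does not match grid length", call. = FALSE)
  need <- c("donor_id", "replicate_id", "group")
  if (!all(need %in% names(meta)))
    stop("meta must have columns donor_id, replicate_id, group", call. = FALSE)
  if (nrow(meta) != nrow(matrix))
    stop("meta rows do not match matrix rows", call. = FALSE)
  if (!all(is.finite(matrix)))
    stop("absorbance matrix contains non-finite values", call. = FALSE)
  meta$donor_id <- as.character(meta$donor_id)
  meta$replicate_id <- as.character(meta$replicate_id)
  meta$group <- normalize_group(meta$group)
  key <- paste(meta$donor_id, meta$replicate_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (donor_id, replicate_id) pairs", call. = FALSE)
  rownames(matrix) <- NULL
  rownames(meta) <- NULL
  structure(list(grid = grid, matrix = matrix, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points, %.6g-%.6g cm^-1\n",
              nrow(x$matrix), length(x$grid), min(x$grid), max(x$grid)))
  tb <- table(x$meta$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$grid, x$matrix[i, , drop = FALSE], x$meta[i, , drop = FALSE])
}

#' Extract one row of a spectra set as a spectrum
#' @param set A `spectra_set`.
#' @param i Row index.
#' @return An `ftir_spectrum`.
#' @export
set_spectrum <- function(set, i) {
  m <- set$meta[i, ]
  ftir_spectrum(set$grid, set$matrix[i, ], m$donor_id, m$replicate_id, m$group)
}

#' Named spectral window
#'
#' Closed wavenumber interval `[lo, hi]`. The four canonical analysis
#' windows are fixed: fingerprint 900-1800, Amide I 1600-1700, primary
#' off-band 1800-1900, fallback off-band 2000-2200 cm^-1.
#'
#' @param lo,hi Window bounds in cm^-1, `lo < hi`. Ignored when a named
#'   canonical window is requested.
#' @param name One of `"fingerprint"`, `"amide_i"`, `"offband_primary"`,
#'   `"offband_fallback"`, `"custom"`.
#' @return List with `lo`, `hi`, `name` (class `spectral_window`).
#' @export
#' @examples
#' spectral_window(name = "fingerprint")
#' spectral_window(1000, 1500)
spectral_window <- function(lo = NULL, hi = NULL, name = "custom") {
  fixed <- list(fingerprint = c(900, 1800), amide_i = c(1600, 1700),
                offband_primary = c(1800, 1900), offband_fallback = c(2000, 2200))
  name <- match.arg(name, c(names(fixed), "custom"))
  if (name != "custom") {
    lo <- fixed[[name]][1]; hi <- fixed[[name]][2]
  }
  if (is.null(lo) || is.null(hi) || !(lo < hi))
    stop("window requires lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi, name = name), class = "spectral_window")
}

#' Align spectra onto a common wavenumber grid
#'
#' Linearly interpolates each spectrum onto a shared target grid. No
#' extrapolation is ever performed: the target grid is restricted to the
#' overlap of all source axes.
#'
#' @param spectra A list of [ftir_spectrum()] objects (or a `spectra_set`,
#'   returned unchanged apart from optional re-gridding).
#' @param target_grid Optional target axis. Default: the common overlap range
#'   of all source axes, sampled at the first spectrum's spacing.
#' @return A `spectra_set` on the (possibly restricted) target grid.
#' @export
align_axes <- function(spectra, target_grid = NULL) {
  if (inherits(spectra, "spectra_set"))
    spectra <- lapply(seq_len(nrow(spectra$matrix)), set_spectrum, set = spectra)
  stopifnot(length(spectra) >= 1L)
  lo <- max(vapply(spectra, function(s) min(s$wavenumbers), 0))
  hi <- min(vapply(spectra, function(s) max(s$wavenumbers), 0))
  if (!(lo < hi)) stop("spectra have empty common wavenumber overlap", call. = FALSE)
  if (is.null(target_grid)) {
    step <- stats::median(diff(spectra[[1L]]$wavenumbers))
    target_grid <- seq(lo, hi, by = step)
  } else {
    target_grid <- as.numeric(target_grid)
    target_grid <- target_grid[target_grid >= lo & target_grid <= hi]
    if (length(target_grid) < 2L)
      stop("target grid has empty overlap with the spectra", call. = FALSE)
  }
  mat <- t(vapply(spectra, function(s)
    stats::approx(s$wavenumbers, s$absorbance, xout = target_grid, rule = 1)$y,
    numeric(length(target_grid))))
  meta <- data.frame(
    donor_id = vapply(spectra, `[[`, "", "donor_id"),
    replicate_id = vapply(spectra, `[[`, "", "replicate_id"),
    group = vapply(spectra, `[[`, "", "group"),
    stringsAsFactors = FALSE)
  spectra_set(target_grid, mat, meta)
}

#' Aggregate technical replicates to donor-level spectra
#'
#' Averages replicate rows per donor (arithmetic mean, pointwise). All
#' downstream QC, unsupervised and supervised analyses run on these
#' donor-level spectra so that technical replicates cannot leak information
#' across cross-validation folds.
#'
#' @param set A `spectra_set` (aligned).
#' @return A `spectra_set` with one row per donor; `replicate_id` is set to
#'   the sentinel `"mean"`. Donor order follows first appearance.
#' @export
aggregate_replicates <- function(set) {
  donors <- unique(set$meta$donor_id)
  rows <- lapply(donors, function(d) {
    idx <- which(set$meta$donor_id == d)
    g <- unique(set$meta$group[idx])
    if (length(g) != 1L)
      stop(sprintf("donor '%s' has conflicting group labels", d), call. = FALSE)
    list(y = colMeans(set$matrix[idx, , drop = FALSE]), group = g)
  })
  spectra_set(set$grid,
              do.call(rbind, lapply(rows, `[[`, "y")),
              data.frame(donor_id = donors, replicate_id = "mean",
                         group = vapply(rows, `[[`, "", "group"),
                         stringsAsFactors = FALSE))
}

#' Restrict a spectra set to a spectral window
#'
#' Keeps grid columns with `lo <= wavenumber <= hi` (closed interval),
#' optionally widened by up to `margin_points` extra columns per side where
#' the grid allows. The margin absorbs the edge loss of Savitzky-Golay
#' derivative filtering so the derivative still covers the full window.
#'
#' @param set A `spectra_set`.
#' @param window A [spectral_window()].
#' @param margin_points Non-negative integer count of extra columns per side.
#' @return The windowed `spectra_set`.
#' @export
extract_window <- function(set, window, margin_points = 0L) {
  stopifnot(inherits(window, "spectral_window"), margin_points >= 0)
  inside <- which(set$grid >= window$lo & set$grid <= window$hi)
  if (length(inside) == 0L)
    stop(sprintf("window [%g, %g] selects no grid points", window$lo, window$hi),
         call. = FALSE)
  lo <- max(1L, min(inside) - as.integer(margin_points))
  hi <- min(length(set$grid), max(inside) + as.integer(margin_points))
  idx <- lo:hi
  spectra_set(set$grid[idx], set$matrix[, idx, drop = FALSE], set$meta)
}
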