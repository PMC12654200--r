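# indices of the lower convex hull (Andrew monotone chain); x strictly increasing
lower_hull_indices <- function(x, y) {
  n <- length(x)
  h <- integer(n); top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      j <- h[top]; k <- h[top - 1L]
      # pop j when it lies on or above segment k -> i
      if ((x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k]) <= 0) {
        top <- top - 1L
      } else break
    }
    top <- top + 1L
    h[top] <- i
  }
  h[seq_len(top)]
}

# rubber-band baseline: lower convex hull, linearly interpolated between vertices
rubberband_baseline_vec <- function(grid, y) {
  idx <- lower_hull_indices(grid, y)
  stats::approx(grid[idx], y[idx], xout = grid)$y
}

#' Rubber-band (convex hull) baseline correction
#'
#' Subtracts the lower convex hull of the `(wavenumber, absorbance)` point
#' set, linearly interpolated between hull vertices, from the spectrum. The
#' corrected spectrum is zero at hull contact points and non-negative
#' elsewhere up to floating-point rounding. The operation is idempotent.
#'
#' @param spectrum An [ftir_spectrum()] (>= 3 points advisable).
#' @return The corrected `ftir_spectrum`.
#' @export
rubberband_correct <- function(spectrum) {
  b <- rubberband_baseline_vec(spectrum$wavenumbers, spectrum$absorbance)
  out <- spectrum
  out$absorbance <- spectrum$absorbance - b
  out
}

# SG middle-row convolution coefficients; ts folds in the grid spacing so the
# result is a true derivative with respect to wavenumber
sg_coeffs <- function(window_points, poly_order, deriv_order, h) {
  f <- signal::sgolay(p = poly_order, n = window_points, m = deriv_order, ts = h)
  unclass(f)[(window_points + 1L) %/% 2L, ]
}

savgol_vec <- function(y, co) {
  n <- length(co)
  drop(stats::embed(y, n) %*% rev(co))  # interior points only
}

#' Savitzky-Golay derivative of a spectrum
#'
#' Classic SG least-squares polynomial derivative filter (default:
#' second-order polynomial, 15-point window) scaled by the grid spacing so
#' values are derivatives with respect to wavenumber (per cm^-1, or per
#' cm^-2 for the second order). The `(window_points-1)/2` points at each
#' edge are dropped: the output grid shrinks. Extract the region with a
#' matching point margin ([extract_window()]) when full window coverage is
#' needed.
#'
#' @param spectrum An [ftir_spectrum()] on a uniformly spaced grid.
#' @param deriv_order 1 or 2.
#' @param window_points Odd filter length, > `poly_order`, <= spectrum length.
#' @param poly_order Local polynomial order.
#' @return The derivative `ftir_spectrum` on the shrunken grid.
#' @export
savgol_derivative <- function(spectrum, deriv_order, window_points = 15L,
                              poly_order = 2L) {
  stopifnot(deriv_order %in% 1:2)
  n <- length(spectrum$wavenumbers)
  if (window_points %% 2L != 1L || window_points <= poly_order)
    stop("window_points must be odd and exceed poly_order", call. = FALSE)
  if (window_points > n)
    stop("window_points exceeds spectrum length", call. = FALSE)
  d <- diff(spectrum$wavenumbers)
  h <- mean(d)
  if (max(abs(d - h)) > 1e-9 * abs(h))
    stop("grid must be uniformly spaced for Savitzky-Golay filtering",
         call. = FALSE)
  hw <- (window_points - 1L) %/% 2L
  co <- sg_coeffs(window_points, poly_order, deriv_order, h)
  out <- spectrum
  out$wavenumbers <- spectrum$wavenumbers[(hw + 1L):(n - hw)]
  out$absorbance <- savgol_vec(spectrum$absorbance, co)
  out
}

#' Vector normalization
#'
#' Scales the absorbance vector to unit Euclidean norm over the current
#' window, removing pathlength/concentration effects. With
#' `center_first = TRUE` the mean is subtracted before scaling (vendor
#' "SNV-like" variant); the default is the plain L2 normalization.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param center_first Subtract the mean before scaling?
#' @return The normalized `ftir_spectrum` (norm 1 within 1e-12).
#' @export
vector_normalize <- function(spectrum, center_first = FALSE) {
  y <- spectrum$absorbance
  if (center_first) y <- y - mean(y)
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("cannot vector-normalize a zero spectrum", call. = FALSE)
  out <- spectrum
  out$absorbance <- y / nrm
  out
}

#' Preprocessing pipeline specification
#'
#' Encodes one row of the preprocessing ladder applied per spectral region:
#' an ordered list of steps from `rubberband_bc`, `vector_norm`,
#' `sg_deriv_1`, `sg_deriv_2` (at most one derivative), plus a flag for
#' downstream FCBF feature selection. The six canonical pipelines, by slug:
#' `bc`, `vn`, `d1`, `d1+vn`, `d2`, `d2+fcbf`.
#'
#' @param region `"fingerprint"` or `"amide_i"`.
#' @param steps Character vector of step names, or a canonical slug via
#'   [pipeline_from_slug()].
#' @param fcbf Apply FCBF feature selection downstream?
#' @return A `pipeline_spec` list with `region`, `steps`, `fcbf`, `label`.
#' @export
pipeline_spec <- function(region, steps, fcbf = FALSE) {
  region <- match.arg(region, c("fingerprint", "amide_i"))
  ok <- c("rubberband_bc", "vector_norm", "sg_deriv_1", "sg_deriv_2")
  if (length(steps) == 0L || !all(steps %in% ok))
    stop("steps must be a non-empty subset of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  if (sum(steps %in% c("sg_deriv_1", "sg_deriv_2")) > 1L)
    stop("at most one derivative step", call. = FALSE)
  structure(list(region = region, steps = steps, fcbf = isTRUE(fcbf),
                 label = pipeline_label(steps, fcbf)),
            class = "pipeline_spec")
}

pipeline_label <- function(steps, fcbf) {
  lab <- c(rubberband_bc = "Rubber band BC", vector_norm = "VN",
           sg_deriv_1 = "1st derivative", sg_deriv_2 = "2nd derivative")
  base <- paste(lab[steps], collapse = " + ")
  if (isTRUE(fcbf)) paste0(base, " + FCBF") else base
}

#' Canonical pipeline slugs
#' @return Character vector of the six canonical pipeline slugs.
#' @export
canonical_pipelines <- function() c("bc", "vn", "d1", "d1+vn", "d2", "d2+fcbf")

#' Build a pipeline spec from its canonical slug
#' @param region `"fingerprint"` or `"amide_i"`.
#' @param slug One of [canonical_pipelines()].
#' @return A [pipeline_spec()].
#' @export
pipeline_from_slug <- function(region, slug) {
  defs <- list("bc" = list("rubberband_bc", FALSE),
               "vn" = list("vector_norm", FALSE),
               "d1" = list("sg_deriv_1", FALSE),
               "d1+vn" = list(c("sg_deriv_1", "vector_norm"), FALSE),
               "d2" = list("sg_deriv_2", FALSE),
               "d2+fcbf" = list("sg_deriv_2", TRUE))
  if (!slug %in% names(defs))
    stop("unknown pipeline slug: ", slug, call. = FALSE)
  pipeline_spec(region, defs[[slug]][[1L]], defs[[slug]][[2L]])
}

#' Apply a preprocessing pipeline to every spectrum of a set
#'
#' Steps run in listed order on each row of the (already windowed) set. A
#' derivative step shrinks the shared grid by 7 points per side; extract the
#' region with `margin_points = 7` beforehand to retain full window
#' coverage.
#'
#' @param set A [spectra_set()].
#' @param spec A [pipeline_spec()].
#' @return The preprocessed `spectra_set`.
#' @export
apply_pipeline <- function(set, spec) {
  stopifnot(inherits(spec, "pipeline_spec"))
  for (si in seq_along(spec$steps)) {
    step <- spec$steps[si]
    res <- tryCatch(switch(step,
      rubberband_bc = {
        mat <- t(apply(set$matrix, 1L, function(y)
          y - rubberband_baseline_vec(set$grid, y)))
        spectra_set(set$grid, mat, set$meta)
      },
      vector_norm = {
        nrm <- sqrt(rowSums(set$matrix^2))
        if (any(nrm == 0)) stop("zero-norm row", call. = FALSE)
        spectra_set(set$grid, set$matrix / nrm, set$meta)
      },
      sg_deriv_1 = sg_deriv_set(set, 1L),
      sg_deriv_2 = sg_deriv_set(set, 2L)),
      error = function(e)
        stop(sprintf("pipeline step %d (%s): %s", si, step, conditionMessage(e)),
             call. = FALSE))
    set <- res
  }
  set
}

sg_deriv_set <- function(set, deriv_order, window_points = 15L, poly_order = 2L) {
  n <- length(set$grid)
  d <- diff(set$grid); h <- mean(d)
  if (max(abs(d - h)) > 1e-9 * abs(h))
    stop("grid must be uniformly spaced for Savitzky-Golay filtering",
         call. = FALSE)
  if (window_points > n)
    stop("window_points exceeds spectrum length", call. = FALSE)
  hw <- (window_points - 1L) %/% 2L
  co <- sg_coeffs(window_points, poly_order, deriv_order, h)
  mat <- t(apply(set$matrix, 1L, savgol_vec, co = co))
  spectra_set(set$grid[(hw + 1L):(n - hw)], mat, set$meta)
}

#' Windowed, preprocessed region for one pipeline
#'
#' Convenience wrapper used by the evaluation grid: extracts the pipeline's
#' region (with a 7-point margin when a derivative step is present) and
#' applies the steps.
#'
#' @param set A donor-level [spectra_set()] on the full acquisition grid.
#' @param spec A [pipeline_spec()].
#' @return The preprocessed `spectra_set` covering the region window.
#' @export
prepare_region <- function(set, spec) {
  margin <- if (any(spec$steps %in% c("sg_deriv_1", "sg_deriv_2"))) 7L else 0L
  apply_pipeline(extract_window(set, spectral_window(name = spec$region), margin),
                 spec)
}
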