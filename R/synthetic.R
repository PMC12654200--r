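#' Gaussian band profile
#'
#' Standard band model used by the cohort generator:
#' `amplitude * exp(-4*log(2) * (nu - center)^2 / fwhm^2)`, so the peak
#' height equals `amplitude` and the full width at half maximum is `fwhm`.
#'
#' @param grid Wavenumber axis (cm^-1).
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param amplitude Peak absorbance.
#' @return Numeric vector on `grid`.
#' @export
gaussian_band <- function(grid, center, fwhm, amplitude) {
  stopifnot(fwhm > 0)
  amplitude * exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
}

#' Specification of one synthetic absorption band
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param amplitude_dbd,amplitude_dcd Group-mean peak absorbances (>= 0).
#'   Equal values give a band with no donor-type effect.
#' @param amplitude_cv Between-donor coefficient of variation of the band
#'   amplitude (lognormal, >= 0).
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, fwhm, amplitude_dbd, amplitude_dcd,
                      amplitude_cv = 0.05) {
  stopifnot(fwhm > 0, amplitude_dbd >= 0, amplitude_dcd >= 0, amplitude_cv >= 0)
  structure(list(center = center, fwhm = fwhm,
                 amplitude_dbd = amplitude_dbd, amplitude_dcd = amplitude_dcd,
                 amplitude_cv = amplitude_cv),
            class = "band_spec")
}

#' Default band table for the synthetic cohort
#'
#' Four discriminant bands (DCD-elevated) at 1202, 1342, 1413 cm^-1 in the
#' fingerprint region and 1673 cm^-1 in Amide I — the wavenumber
#' neighbourhoods where donor-type signal is injected — plus shared
#' background bands emulating the protein/lipid/carbohydrate/phosphate
#' content of a dried biofluid film (Amide I at 1650 dominating, Amide II,
#' CH deformations, C-O/PO2- stretches, and broad O-H/C-H structure above
#' 1800).
#'
#' @param null When `TRUE`, the discriminant DCD amplitudes are set equal to
#'   the DBD ones, yielding a cohort with zero injected group effect (the
#'   negative control for null-behavior checks).
#' @return List of [band_spec()] objects.
#' @export
default_bands <- function(null = FALSE) {
  bands <- list(
    # discriminant bands: DCD mean amplitude elevated over DBD
    band_spec(1202, 16, 0.050, 0.100, 0.08),
    band_spec(1342, 18, 0.060, 0.110, 0.08),
    band_spec(1413, 18, 0.070, 0.120, 0.08),
    band_spec(1673, 20, 0.100, 0.150, 0.08),
    # shared background bands (no group effect)
    band_spec(1030, 60, 0.350, 0.350, 0.05),
    band_spec(1080, 40, 0.250, 0.250, 0.05),
    band_spec(1240, 50, 0.220, 0.220, 0.05),
    band_spec(1310, 45, 0.180, 0.180, 0.05),
    band_spec(1455, 35, 0.180, 0.180, 0.05),
    band_spec(1550, 45, 0.300, 0.300, 0.05),
    band_spec(1650, 50, 0.850, 0.850, 0.05),
    band_spec(1740, 30, 0.100, 0.100, 0.05),
    band_spec(2930, 80, 0.150, 0.150, 0.05),
    band_spec(3300, 300, 0.400, 0.400, 0.05))
  if (null)
    bands <- lapply(bands, function(b) { b$amplitude_dcd <- b$amplitude_dbd; b })
  bands
}

#' Generative recipe for a synthetic FTIR cohort
#'
#' Defaults mirror the study conditions the pipeline targets: a 400-4000
#' cm^-1 grid at 2 cm^-1 spacing, 5 DCD + 5 DBD donors, and technical
#' replicates per donor. Noise and artifact levels are set to what a
#' well-behaved HTS transmission acquisition of a dried film typically
#' shows: absorbance noise a few millesimal of the strongest band, sparse
#' single-point spikes, mild baseline drift and pathlength variation.
#'
#' @param grid_lo,grid_hi,grid_step Wavenumber grid (cm^-1).
#' @param bands List of [band_spec()]; default [default_bands()].
#' @param baseline_poly_coeffs_sd Per-degree SDs (absorbance) of a random
#'   per-donor polynomial baseline drift in the scaled coordinate
#'   `t = (nu - mid)/halfspan` in `[-1, 1]`; length = degree + 1.
#' @param noise_sd SD of i.i.d. Gaussian per-point replicate noise
#'   (absorbance).
#' @param spike_rate Expected (Poisson) number of single-point spikes per
#'   replicate spectrum.
#' @param spike_amplitude Absolute spike height (absorbance); sign random.
#' @param pathlength_cv Coefficient of variation of the per-donor lognormal
#'   pathlength scale factor.
#' @param n_dcd,n_dbd Donor counts per group.
#' @param replicates_per_donor Technical replicates per donor.
#' @param seed Integer; fully determines the cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(grid_lo = 400, grid_hi = 4000, grid_step = 2,
                             bands = default_bands(),
                             baseline_poly_coeffs_sd = c(0.01, 0.005, 0.002),
                             noise_sd = 0.002,
                             spike_rate = 1,
                             spike_amplitude = 0.05,
                             pathlength_cv = 0.03,
                             n_dcd = 5, n_dbd = 5,
                             replicates_per_donor = 3,
                             seed = 1L) {
  stopifnot(grid_step > 0, grid_lo < grid_hi,
            n_dcd >= 1, n_dbd >= 1, replicates_per_donor >= 1,
            noise_sd >= 0, spike_rate >= 0, spike_amplitude >= 0,
            pathlength_cv >= 0, all(baseline_poly_coeffs_sd >= 0))
  if (!all(vapply(bands, inherits, TRUE, "band_spec")))
    stop("bands must be a list of band_spec objects", call. = FALSE)
  structure(list(grid_lo = grid_lo, grid_hi = grid_hi, grid_step = grid_step,
                 bands = bands,
                 baseline_poly_coeffs_sd = baseline_poly_coeffs_sd,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude,
                 pathlength_cv = pathlength_cv,
                 n_dcd = n_dcd, n_dbd = n_dbd,
                 replicates_per_donor = replicates_per_donor,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a synthetic cohort configuration from YAML or JSON
#'
#' Scalar fields override the [synthetic_config()] defaults; `bands`, when
#' present, must be a list of records with the [band_spec()] fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_file <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$bands))
    raw$bands <- lapply(seq_len(NROW(raw$bands)), function(i) {
      b <- if (is.data.frame(raw$bands)) as.list(raw$bands[i, ]) else raw$bands[[i]]
      do.call(band_spec, b)
    })
  do.call(synthetic_config, raw)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate a synthetic FTIR cohort with known ground truth
#'
#' Per donor: band amplitudes are drawn as group mean x lognormal(CV =
#' `amplitude_cv`), a polynomial baseline and a lognormal pathlength scale
#' are drawn; biology is per-donor. Per replicate: (bands + baseline) x
#' pathlength + Gaussian noise + Poisson-count single-grid-point spikes of
#' +/- `spike_amplitude` at uniform random grid positions. The returned
#' `truth` records every drawn value; the whole cohort is reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `set` (a [spectra_set()], one row per donor x
#'   replicate) and `truth` (list: `bands` data frame of per-donor drawn
#'   amplitudes, `baseline_coeffs`, `pathlength`, `spikes` data frame with
#'   one row per injected spike, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  grid <- seq(config$grid_lo, config$grid_hi, by = config$grid_step)
  np <- length(grid)
  donors <- c(sprintf("DCD%02d", seq_len(config$n_dcd)),
              sprintf("DBD%02d", seq_len(config$n_dbd)))
  groups <- rep(c("DCD", "DBD"), c(config$n_dcd, config$n_dbd))
  nb <- length(config$bands)
  tmid <- (config$grid_lo + config$grid_hi) / 2
  thalf <- (config$grid_hi - config$grid_lo) / 2
  tt <- (grid - tmid) / thalf

  band_rows <- list(); spike_rows <- list()
  base_coef <- list(); pathlen <- numeric(length(donors))
  mats <- list(); meta <- list()
  shapes <- vapply(config$bands,
                   function(b) gaussian_band(grid, b$center, b$fwhm, 1),
                   numeric(np))

  for (di in seq_along(donors)) {
    g <- groups[di]
    means <- vapply(config$bands, function(b)
      if (g == "DCD") b$amplitude_dcd else b$amplitude_dbd, 0)
    cvs <- vapply(config$bands, `[[`, 0, "amplitude_cv")
    amps <- means * vapply(seq_len(nb), function(k) rlnorm_cv(1, cvs[k]), 0)
    coefs <- stats::rnorm(length(config$baseline_poly_coeffs_sd)) *
      config$baseline_poly_coeffs_sd
    baseline <- drop(outer(tt, seq_along(coefs) - 1, `^`) %*% coefs)
    pl <- rlnorm_cv(1, config$pathlength_cv)
    clean <- drop(shapes %*% amps + baseline) * pl

    band_rows[[di]] <- data.frame(
      donor_id = donors[di], group = g,
      center = vapply(config$bands, `[[`, 0, "center"),
      amplitude = amps, stringsAsFactors = FALSE)
    base_coef[[donors[di]]] <- coefs
    pathlen[di] <- pl

    for (ri in seq_len(config$replicates_per_donor)) {
      y <- clean + stats::rnorm(np, 0, config$noise_sd)
      nsp <- stats::rpois(1, config$spike_rate)
      if (nsp > 0) {
        pos <- sample.int(np, nsp, replace = TRUE)
        sgn <- sample(c(-1, 1), nsp, replace = TRUE)
        y[pos] <- y[pos] + sgn * config$spike_amplitude
        spike_rows[[length(spike_rows) + 1L]] <- data.frame(
          donor_id = donors[di], replicate_id = sprintf("r%d", ri),
          index = pos, wavenumber = grid[pos], sign = sgn,
          stringsAsFactors = FALSE)
      }
      mats[[length(mats) + 1L]] <- y
      meta[[length(meta) + 1L]] <- data.frame(
        donor_id = donors[di], replicate_id = sprintf("r%d", ri), group = g,
        stringsAsFactors = FALSE)
    }
  }

  names(pathlen) <- donors
  truth <- list(
    bands = do.call(rbind, band_rows),
    baseline_coeffs = base_coef,
    pathlength = pathlen,
    spikes = if (length(spike_rows))
      do.call(rbind, spike_rows)
    else data.frame(donor_id = character(), replicate_id = character(),
                    index = integer(), wavenumber = numeric(), sign = numeric()),
    config = config)
  list(set = spectra_set(grid, do.call(rbind, mats), do.call(rbind, meta)),
       truth = truth)
}
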