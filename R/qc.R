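#' Quality-control configuration
#'
#' Windows and thresholds for the four spectral QC metrics. The windows are
#' the fixed canonical ones (Amide I 1600-1700, off-band 1800-1900 with
#' 2000-2200 fallback, fingerprint 900-1800 cm^-1) unless overridden.
#'
#' @param amide_window,offband_primary,offband_fallback,fingerprint
#'   [spectral_window()] objects.
#' @param spike_z_threshold Robust z-score threshold for spike flagging
#'   (default 6).
#' @param min_offband_points Minimum grid points required for an off-band
#'   noise window before falling back (default 10).
#' @param spike_merge_runs Count maximal runs of consecutive flagged points
#'   instead of individual points?
#' @return A `qc_config` list.
#' @export
qc_config <- function(amide_window = spectral_window(name = "amide_i"),
                      offband_primary = spectral_window(name = "offband_primary"),
                      offband_fallback = spectral_window(name = "offband_fallback"),
                      fingerprint = spectral_window(name = "fingerprint"),
                      spike_z_threshold = 6,
                      min_offband_points = 10L,
                      spike_merge_runs = FALSE) {
  stopifnot(spike_z_threshold > 0, min_offband_points >= 1)
  structure(list(amide_window = amide_window, offband_primary = offband_primary,
                 offband_fallback = offband_fallback, fingerprint = fingerprint,
                 spike_z_threshold = spike_z_threshold,
                 min_offband_points = as.integer(min_offband_points),
                 spike_merge_runs = isTRUE(spike_merge_runs)),
            class = "qc_config")
}

in_window <- function(grid, w) grid >= w$lo & grid <= w$hi

#' Amide I signal-to-noise ratio
#'
#' Signal is the maximum rubber-band-corrected absorbance in the Amide I
#' window (the correction is computed on the full available spectrum, since
#' the off-band noise window lies outside Amide I). Noise is the sample SD
#' (n-1 denominator) of the corrected absorbance in the primary off-band
#' window; if that window holds fewer than `min_offband_points` grid points
#' the fallback window is used, and if both are insufficient the SD of the
#' whole corrected spectrum serves as a last resort.
#'
#' @param spectrum An [ftir_spectrum()] covering the Amide I window.
#' @param config A [qc_config()].
#' @return List with `value` (SNR) and `noise_source` (one of
#'   `"offband_primary"`, `"offband_fallback"`, `"global_sd"`).
#' @export
snr_amide_i <- function(spectrum, config = qc_config()) {
  corrected <- rubberband_correct(spectrum)
  g <- corrected$wavenumbers; y <- corrected$absorbance
  sel <- in_window(g, config$amide_window)
  if (!any(sel)) stop("spectrum does not cover the Amide I window", call. = FALSE)
  signal <- max(y[sel])
  src <- NULL
  for (cand in c("offband_primary", "offband_fallback")) {
    pts <- which(in_window(g, config[[cand]]))
    if (length(pts) >= config$min_offband_points) {
      noise <- stats::sd(y[pts]); src <- cand; break
    }
  }
  if (is.null(src)) {
    noise <- stats::sd(y); src <- "global_sd"
  }
  if (noise == 0)
    stop("off-band noise is exactly zero; SNR undefined (degenerate input)",
         call. = FALSE)
  list(value = signal / noise, noise_source = src)
}

#' Spike artifact count
#'
#' First differences of the absorbance within the fingerprint window are
#' converted to robust z-scores `z = (d - median(d)) / (1.4826 * MAD(d))`;
#' points with `|z| > spike_z_threshold` are flagged. The default count is
#' the number of flagged points; with `spike_merge_runs = TRUE` maximal runs
#' of consecutive flagged points are counted instead (one per injected
#' single-point spike, which produces a +/- pair of adjacent large
#' differences). `MAD(d) = 0` returns 0 by convention.
#'
#' @param spectrum An [ftir_spectrum()] covering the fingerprint window.
#' @param config A [qc_config()].
#' @return Integer count.
#' @export
spike_count <- function(spectrum, config = qc_config()) {
  sel <- in_window(spectrum$wavenumbers, config$fingerprint)
  if (sum(sel) < 3L) stop("fingerprint window not covered", call. = FALSE)
  d <- diff(spectrum$absorbance[sel])
  s <- stats::mad(d, constant = 1.4826)
  if (s == 0) return(0L)
  z <- (d - stats::median(d)) / s
  flag <- abs(z) > config$spike_z_threshold
  if (!config$spike_merge_runs) return(sum(flag))
  r <- rle(flag)
  sum(r$values)
}

#' Cosine similarity to the cohort median fingerprint
#'
#' The cohort median spectrum is the pointwise median across donors within
#' the fingerprint window. Each donor's windowed spectrum and the median are
#' scaled to unit Euclidean norm; the metric is their dot product, a
#' scale-invariant measure of spectral shape coherence.
#'
#' @param set A donor-level [spectra_set()] (>= 2 donors).
#' @param config A [qc_config()].
#' @return Named numeric vector (one value in `[-1, 1]` per donor).
#' @export
cosine_fp <- function(set, config = qc_config()) {
  if (nrow(set$matrix) < 2L) stop("need at least 2 donors", call. = FALSE)
  sel <- in_window(set$grid, config$fingerprint)
  if (!any(sel)) stop("fingerprint window not covered", call. = FALSE)
  w <- set$matrix[, sel, drop = FALSE]
  med <- apply(w, 2L, stats::median)
  nm <- sqrt(sum(med^2))
  nr <- sqrt(rowSums(w^2))
  if (nm == 0 || any(nr == 0))
    stop("zero-norm fingerprint window", call. = FALSE)
  out <- drop(w %*% (med / nm)) / nr
  names(out) <- set$meta$donor_id
  out
}

#' Baseline area fraction
#'
#' Trapezoidal area under the rubber-band baseline over the fingerprint
#' window divided by the trapezoidal area under the raw spectrum there,
#' reported as a percentage — a drift index near 0 for flat baselines and
#' near 100 for spectra dominated by broad background.
#'
#' @param spectrum An [ftir_spectrum()] covering the fingerprint window.
#' @param config A [qc_config()].
#' @return Percentage (numeric scalar).
#' @export
baseline_area_fraction <- function(spectrum, config = qc_config()) {
  sel <- in_window(spectrum$wavenumbers, config$fingerprint)
  if (sum(sel) < 2L) stop("fingerprint window not covered", call. = FALSE)
  g <- spectrum$wavenumbers[sel]; y <- spectrum$absorbance[sel]
  b <- rubberband_baseline_vec(g, y)
  trap <- function(v) sum(diff(g) * (v[-1] + v[-length(v)]) / 2)
  raw <- trap(y)
  if (raw <= 0) stop("non-positive raw spectral area", call. = FALSE)
  100 * trap(b) / raw
}

#' Per-donor QC table
#'
#' All four QC metrics for every donor of a donor-level set, ordered by
#' donor id (deterministic, row-order invariant).
#'
#' @param set A donor-level [spectra_set()] (post [aggregate_replicates()]).
#' @param config A [qc_config()].
#' @return Data frame with columns `donor_id`, `group`, `snr_amide_i`,
#'   `snr_noise_source`, `spike_count`, `cosine_fp`,
#'   `baseline_area_fraction`.
#' @export
qc_table <- function(set, config = qc_config()) {
  ord <- order(set$meta$donor_id)
  set <- set[ord]
  cf <- cosine_fp(set, config)
  rows <- lapply(seq_len(nrow(set$matrix)), function(i) {
    sp <- set_spectrum(set, i)
    snr <- tryCatch(snr_amide_i(sp, config), error = function(e)
      stop(sprintf("donor '%s': %s", sp$donor_id, conditionMessage(e)),
           call. = FALSE))
    data.frame(donor_id = sp$donor_id, group = sp$group,
               snr_amide_i = snr$value, snr_noise_source = snr$noise_source,
               spike_count = spike_count(sp, config),
               cosine_fp = unname(cf[i]),
               baseline_area_fraction = baseline_area_fraction(sp, config),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group comparison of QC metrics
#'
#' For each QC metric: median [IQR] and mean +/- SD per group, the
#' Mann-Whitney U statistic with DCD as the first sample (ties counted 0.5),
#' the exact two-sided p-value by enumeration over group assignments, and
#' the rank-biserial effect size `r = 1 - 2U/(n1*n2)`.
#'
#' @param records A [qc_table()] data frame (both groups non-empty).
#' @param metrics Metric columns to compare.
#' @return Data frame, one row per metric: group summaries, `u`, `p_value`,
#'   `rank_biserial_r`.
#' @export
qc_group_compare <- function(records,
                             metrics = c("snr_amide_i", "spike_count",
                                         "cosine_fp", "baseline_area_fraction")) {
  a_idx <- records$group == "DCD"; b_idx <- records$group == "DBD"
  if (!any(a_idx) || !any(b_idx))
    stop("both DCD and DBD groups must be present", call. = FALSE)
  summ <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2], iqr_lo = q[1], iqr_hi = q[3],
      mean = mean(v), sd = stats::sd(v))
  }
  rows <- lapply(metrics, function(m) {
    a <- records[[m]][a_idx]; b <- records[[m]][b_idx]
    u <- mann_whitney_u(a, b)
    sa <- summ(a); sb <- summ(b)
    data.frame(metric = m,
               dcd_median = sa["median"], dcd_iqr_lo = sa["iqr_lo"],
               dcd_iqr_hi = sa["iqr_hi"], dcd_mean = sa["mean"], dcd_sd = sa["sd"],
               dbd_median = sb["median"], dbd_iqr_lo = sb["iqr_lo"],
               dbd_iqr_hi = sb["iqr_hi"], dbd_mean = sb["mean"], dbd_sd = sb["sd"],
               u = u, p_value = exact_mwu_p(a, b),
               rank_biserial_r = rank_biserial(u, length(a), length(b)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
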