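# per-donor QC metrics of the reference 5 DCD / 5 DBD cohort: fixed inputs
# for the exact-statistics checks
ref_qc_snr_dcd <- c(204.725, 67.697, 58.219, 77.158, 80.408)
ref_qc_snr_dbd <- c(81.152, 4.364, 20.737, 67.108, 85.07)
ref_qc_spike_dcd <- c(57, 12, 6, 4, 53)
ref_qc_spike_dbd <- c(34, 12, 36, 6, 8)
ref_qc_cosine_dcd <- c(0.859, 0.998, 1, 0.994, 0.987)
ref_qc_cosine_dbd <- c(0.992, 0.942, 0.953, 0.998, 0.998)

# small spectra_set from a matrix, grid 900..1800 by default
toy_set <- function(mat, grid = seq(900, by = 2, length.out = ncol(mat)),
                    groups = rep("UNKNOWN", nrow(mat)),
                    donors = sprintf("D%02d", seq_len(nrow(mat)))) {
  spectra_set(grid, mat,
              data.frame(donor_id = donors, replicate_id = "r1",
                         group = groups, stringsAsFactors = FALSE))
}

# single smooth band spectrum covering all QC windows
band_spectrum <- function(amp = 1, center = 1650, fwhm = 50,
                          grid = seq(400, 4000, by = 2), noise_sd = 0,
                          offset = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- gaussian_band(grid, center, fwhm, amp) + offset
  if (noise_sd > 0) y <- y + rnorm(length(grid), 0, noise_sd)
  ftir_spectrum(grid, y, "D01", "r1", "DCD")
}

# O(n^3) greatest-convex-minorant oracle: baseline at x_i is the minimum over
# all chords (j <= i <= k) of the chord value at x_i
brute_lower_hull <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    best <- y[i]
    for (j in seq_len(i)) for (k in i:n) {
      if (j == k) next
      v <- y[j] + (y[k] - y[j]) * (x[i] - x[j]) / (x[k] - x[j])
      best <- min(best, v)
    }
    best
  }, 0)
}
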