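test_that("Amide I SNR recovers the constructed signal-to-noise ratio", {
  sp <- band_spectrum(amp = 1, noise_sd = 0.01, seed = 101)
  res <- snr_amide_i(sp)
  expect_identical(res$noise_source, "offband_primary")
  expect_lt(abs(res$value - 100) / 100, 0.15)
  # scale invariance
  sp2 <- sp; sp2$absorbance <- 2 * sp$absorbance
  expect_equal(snr_amide_i(sp2)$value, res$value, tolerance = 1e-9)
})

test_that("SNR noise window ladder follows the minimum-point rule", {
  mk <- function(grid) {
    set.seed(55)
    ftir_spectrum(grid, gaussian_band(grid, 1650, 50, 1) +
                    rnorm(length(grid), 0, 0.01), "D", "r1", "DCD")
  }
  expect_identical(snr_amide_i(mk(seq(900, 1916, 2)))$noise_source,
                   "offband_primary")
  # primary reduced below 10 points, fallback intact
  expect_identical(snr_amide_i(mk(c(seq(900, 1810, 2), seq(2000, 2200, 2))))$noise_source,
                   "offband_fallback")
  # both off-band windows below 10 points
  expect_identical(snr_amide_i(mk(seq(900, 1816, 2)))$noise_source, "global_sd")
  flat <- ftir_spectrum(seq(900, 2300, 2), rep(1, 701), "D", "r1", "DCD")
  expect_error(snr_amide_i(flat), "undefined")
})

test_that("spike detector counts robust-z exceedances and merged runs", {
  # a broad smooth band keeps the whole first-difference distribution on one
  # scale, so nothing stands out as a spike
  smooth <- band_spectrum(amp = 1, center = 1350, fwhm = 500)
  expect_identical(spike_count(smooth), 0L)
  const <- ftir_spectrum(seq(900, 1800, 2), rep(2, 451), "D", "r1", "DCD")
  expect_identical(spike_count(const), 0L)

  set.seed(77)
  g <- seq(400, 4000, 2)
  y <- 0.5 + rnorm(length(g), 0, 0.002)
  at <- c(which(g == 1100), which(g == 1400), which(g == 1700))
  y[at] <- y[at] + 0.2  # 100x noise SD
  sp <- ftir_spectrum(g, y, "D", "r1", "DCD")
  expect_identical(spike_count(sp, qc_config(spike_merge_runs = TRUE)), 3L)

  # flagged-point count equals a direct recount of |z| > 6
  d <- diff(y[g >= 900 & g <= 1800])
  z <- (d - median(d)) / (1.4826 * mad(d, constant = 1))
  expect_identical(spike_count(sp), sum(abs(z) > 6))
})

test_that("merge-run spike counting recovers injected truth on 100 spectra", {
  # gentle broad bands so the only sharp features are the injected spikes
  bands <- list(band_spec(1200, 500, 0.4, 0.4, 0.05),
                band_spec(1650, 300, 0.6, 0.6, 0.05),
                band_spec(3300, 400, 0.3, 0.3, 0.05))
  cfg <- synthetic_config(bands = bands,
                          n_dcd = 50, n_dbd = 50, replicates_per_donor = 1,
                          noise_sd = 0.002, spike_rate = 3,
                          spike_amplitude = 0.1, seed = 88)  # 50x noise SD
  co <- generate_cohort(cfg)
  conf <- qc_config(spike_merge_runs = TRUE)
  fp <- co$set$grid >= 900 & co$set$grid <= 1800
  key <- paste(co$truth$spikes$donor_id, co$truth$spikes$replicate_id)
  ok <- 0
  for (i in seq_len(nrow(co$set$matrix))) {
    truth_n <- sum(key == paste(co$set$meta$donor_id[i], co$set$meta$replicate_id[i]) &
                     co$truth$spikes$wavenumber >= 900 &
                     co$truth$spikes$wavenumber <= 1800)
    got <- spike_count(set_spectrum(co$set, i), conf)
    if (got == truth_n) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("cosine similarity to the cohort median behaves geometrically", {
  base <- gaussian_band(seq(900, 1800, 2), 1300, 60, 1) + 0.1
  m <- rbind(base, base, base, base)
  expect_equal(unname(cosine_fp(toy_set(m))), rep(1, 4), tolerance = 1e-12)
  # scaled copy of the median shape still scores 1
  m5 <- rbind(base, base, base, 5 * base)
  expect_equal(unname(cosine_fp(toy_set(m5))[4]), 1, tolerance = 1e-12)
  # constructed orthogonal donor scores 0
  u <- rep(1, 451)
  v <- c(rep(c(1, -1), 225), 0)
  ortho <- toy_set(rbind(u, u, u, u, v))
  expect_equal(unname(cosine_fp(ortho)[5]), 0, tolerance = 1e-12)
})

test_that("baseline area fraction matches closed-form areas", {
  g <- seq(900, 1800, 2)
  ramp <- ftir_spectrum(g, 0.2 + 5e-4 * (g - 900), "D", "r1", "DCD")
  expect_equal(baseline_area_fraction(ramp), 100, tolerance = 1e-9)
  peak <- ftir_spectrum(g, gaussian_band(g, 1350, 30, 1), "D", "r1", "DCD")
  expect_lt(baseline_area_fraction(peak), 0.5)
  # peak of trapezoidal area A on constant offset c: 100 * cL / (cL + A)
  c0 <- 0.1
  y <- gaussian_band(g, 1350, 20, 1)
  trap <- function(v) sum(diff(g) * (v[-1] + v[-length(v)]) / 2)
  sp <- ftir_spectrum(g, y + c0, "D", "r1", "DCD")
  expect_equal(baseline_area_fraction(sp),
               100 * c0 * 900 / (c0 * 900 + trap(y)), tolerance = 1e-9)
})

test_that("qc_table is complete, ordered, and row-order invariant", {
  co <- generate_cohort(synthetic_config(seed = 33))
  don <- aggregate_replicates(co$set)
  qc <- qc_table(don)
  expect_identical(nrow(qc), 10L)
  expect_identical(qc$donor_id, sort(don$meta$donor_id))
  perm <- sample(10)
  expect_equal(qc_table(don[perm]), qc, tolerance = 1e-12)
  # per-donor spike column equals direct computation
  i <- 4L
  row <- which(don$meta$donor_id == qc$donor_id[i])
  expect_identical(qc$spike_count[i], spike_count(set_spectrum(don, row)))
  # all four metrics invariant under uniform rescaling of the cohort
  don2 <- don; don2$matrix <- don$matrix * 3.7
  expect_equal(qc_table(don2)[, -(1:2)], qc[, -(1:2)], tolerance = 1e-9)
})

test_that("group comparison reproduces the reference-cohort QC statistics", {
  qc <- data.frame(
    donor_id = sprintf("D%02d", 1:10),
    group = rep(c("DCD", "DBD"), each = 5),
    snr_amide_i = c(ref_qc_snr_dcd, ref_qc_snr_dbd),
    spike_count = c(ref_qc_spike_dcd, ref_qc_spike_dbd),
    cosine_fp = c(ref_qc_cosine_dcd, ref_qc_cosine_dbd),
    baseline_area_fraction = 0.01, stringsAsFactors = FALSE)
  cmp <- qc_group_compare(qc, metrics = c("snr_amide_i", "spike_count"))
  snr <- cmp[cmp$metric == "snr_amide_i", ]
  expect_equal(snr$u, 16)
  expect_equal(snr$p_value, 0.5476, tolerance = 1e-4)
  expect_equal(snr$rank_biserial_r, -0.28, tolerance = 1e-12)
  expect_equal(snr$dcd_mean, 97.64, tolerance = 1e-3)
  expect_equal(snr$dcd_sd, 60.49, tolerance = 1e-3)
  spikes <- cmp[cmp$metric == "spike_count", ]
  expect_equal(spikes$u, 13)
  expect_equal(spikes$rank_biserial_r, -0.04, tolerance = 1e-12)

  # exchanging the group labels flips r and preserves p
  qc2 <- qc; qc2$group <- rep(c("DBD", "DCD"), each = 5)
  cmp2 <- qc_group_compare(qc2, metrics = "snr_amide_i")
  expect_equal(cmp2$rank_biserial_r, -snr$rank_biserial_r)
  expect_equal(cmp2$p_value, snr$p_value)

  # identical groups sit at the null center
  qc3 <- qc; qc3$snr_amide_i <- rep(1:5, 2)
  cmp3 <- qc_group_compare(qc3, metrics = "snr_amide_i")
  expect_equal(cmp3$u, 12.5)
  expect_equal(cmp3$rank_biserial_r, 0)
})
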