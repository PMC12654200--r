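test_that("rubber-band correction matches the brute-force convex minorant", {
  set.seed(31)
  g <- seq(1000, 1196, 4)
  y <- gaussian_band(g, 1100, 30, 1) + 0.002 * (g - 1000) + 0.1 +
    rnorm(length(g), 0, 0.01)
  sp <- ftir_spectrum(g, y, "A", "r1", "DCD")
  out <- rubberband_correct(sp)
  expect_equal(out$absorbance, y - brute_lower_hull(g, y), tolerance = 1e-12)
  expect_gte(min(out$absorbance), -1e-12)
  # idempotent
  expect_lt(max(abs(rubberband_correct(out)$absorbance - out$absorbance)), 1e-12)
})

test_that("rubber-band correction zeroes convex inputs, keeps flat-hull peaks", {
  g <- seq(900, 1800, 2)
  line <- ftir_spectrum(g, 0.3 + 1e-4 * g, "A", "r1", "DCD")
  expect_lt(max(abs(rubberband_correct(line)$absorbance)), 1e-12)
  peak <- ftir_spectrum(g, gaussian_band(g, 1350, 40, 1), "A", "r1", "DCD")
  expect_lt(max(abs(rubberband_correct(peak)$absorbance - peak$absorbance)), 1e-12)
})

test_that("Savitzky-Golay equals an independent local least-squares fit", {
  set.seed(7)
  g <- seq(1000, 1098, 2)
  y <- sin(g / 40) + rnorm(length(g), 0, 0.05)
  sp <- ftir_spectrum(g, y, "A", "r1", "DCD")
  for (m in 1:2) {
    out <- savgol_derivative(sp, m)
    # oracle: quadratic fit over each 15-point window, derivative at center
    oracle <- vapply(8:(length(g) - 7), function(i) {
      idx <- (i - 7):(i + 7)
      fit <- lm(y[idx] ~ poly(g[idx], 2, raw = TRUE))
      if (m == 1) unname(coef(fit)[2] + 2 * coef(fit)[3] * g[i])
      else unname(2 * coef(fit)[3])
    }, 0)
    expect_equal(out$absorbance, oracle, tolerance = 1e-8)
    expect_identical(length(out$wavenumbers), length(g) - 14L)
  }
})

test_that("Savitzky-Golay is exact on polynomials of the fit order", {
  g <- seq(900, 1100, 2)
  const <- ftir_spectrum(g, rep(0.4, length(g)), "A", "r1", "DCD")
  expect_lt(max(abs(savgol_derivative(const, 1)$absorbance)), 1e-12)
  expect_lt(max(abs(savgol_derivative(const, 2)$absorbance)), 1e-12)
  quad <- ftir_spectrum(g, g^2, "A", "r1", "DCD")
  expect_lt(max(abs(savgol_derivative(quad, 2)$absorbance - 2)), 1e-9)
  expect_lt(max(abs(savgol_derivative(quad, 1)$absorbance -
                    2 * g[8:(length(g) - 7)])), 1e-9)
  # analytic first derivative of a sine tracked within its truncation error
  y <- sin(0.05 * g)
  sine <- ftir_spectrum(g, y, "A", "r1", "DCD")
  d1 <- savgol_derivative(sine, 1)
  expect_lt(max(abs(d1$absorbance - 0.05 * cos(0.05 * d1$wavenumbers))), 5e-3)

  irregular <- ftir_spectrum(c(g[-3], 5000), c(y[-3], 0), "A", "r1", "DCD")
  expect_error(savgol_derivative(irregular, 1), "uniformly spaced")
  expect_error(savgol_derivative(sine, 1, window_points = 14), "odd")
})

test_that("vector normalization scales to unit norm and kills scale factors", {
  sp <- ftir_spectrum(1:2, c(3, 4), "A", "r1", "DCD")
  expect_equal(vector_normalize(sp)$absorbance, c(0.6, 0.8))
  set.seed(12)
  for (i in 1:20) {
    y <- rnorm(80)
    s <- ftir_spectrum(seq_len(80), y, "A", "r1", "DCD")
    v <- vector_normalize(s)
    expect_equal(sqrt(sum(v$absorbance^2)), 1, tolerance = 1e-12)
    s2 <- s; s2$absorbance <- 7.3 * y
    expect_equal(vector_normalize(s2)$absorbance, v$absorbance)
  }
  zero <- ftir_spectrum(1:3, c(0, 0, 0), "A", "r1", "DCD")
  expect_error(vector_normalize(zero), "zero")
})

test_that("pipelines compose stepwise, trim derivative edges, stay row-order invariant", {
  co <- generate_cohort(synthetic_config(seed = 17))
  don <- aggregate_replicates(co$set)
  fp <- extract_window(don, spectral_window(name = "fingerprint"))

  d2 <- apply_pipeline(fp, pipeline_spec("fingerprint", "sg_deriv_2"))
  expect_identical(ncol(d2$matrix), ncol(fp$matrix) - 14L)

  combo <- apply_pipeline(fp, pipeline_spec("fingerprint",
                                            c("sg_deriv_1", "vector_norm")))
  step1 <- apply_pipeline(fp, pipeline_spec("fingerprint", "sg_deriv_1"))
  step2 <- apply_pipeline(step1, pipeline_spec("fingerprint", "vector_norm"))
  expect_equal(combo$matrix, step2$matrix, tolerance = 1e-14)

  perm <- sample(nrow(fp$matrix))
  shuffled <- apply_pipeline(fp[perm], pipeline_spec("fingerprint", "sg_deriv_2"))
  expect_equal(shuffled$matrix[order(perm), ], d2$matrix, tolerance = 0)

  # rows differing only by a constant collapse under any VN-terminated pipeline
  scaled <- fp
  scaled$matrix <- fp$matrix * seq(1, 3, length.out = nrow(fp$matrix))
  a <- apply_pipeline(fp, pipeline_spec("fingerprint", c("sg_deriv_1", "vector_norm")))
  b <- apply_pipeline(scaled, pipeline_spec("fingerprint", c("sg_deriv_1", "vector_norm")))
  expect_equal(a$matrix, b$matrix, tolerance = 1e-12)

  expect_error(pipeline_spec("fingerprint", c("sg_deriv_1", "sg_deriv_2")),
               "one derivative")
  expect_error(pipeline_spec("fingerprint", character(0)), "non-empty")
})

test_that("prepare_region keeps full window coverage for derivative pipelines", {
  co <- generate_cohort(synthetic_config(seed = 2))
  don <- aggregate_replicates(co$set)
  prep <- prepare_region(don, pipeline_from_slug("fingerprint", "d2"))
  expect_equal(range(prep$grid), c(900, 1800))
  prep_a <- prepare_region(don, pipeline_from_slug("amide_i", "d1+vn"))
  expect_equal(range(prep_a$grid), c(1600, 1700))
})
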