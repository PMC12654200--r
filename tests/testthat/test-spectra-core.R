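test_that("constructors enforce the core invariants", {
  expect_error(ftir_spectrum(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
  expect_error(ftir_spectrum(1:3, c(0, NA, 0)), "non-finite")
  expect_error(ftir_spectrum(1:3, 1:2), "length")
  s <- ftir_spectrum(1:3, 1:3, group = "dcd")
  expect_identical(s$group, "DCD")
  expect_identical(ftir_spectrum(1:3, 1:3, group = "control")$group, "UNKNOWN")

  m <- matrix(0, 2, 5)
  meta <- data.frame(donor_id = c("A", "A"), replicate_id = c("r1", "r1"),
                     group = "DBD")
  expect_error(spectra_set(seq(900, 908, 2), m, meta), "duplicate")
  meta$replicate_id <- c("r1", "r2")
  expect_s3_class(spectra_set(seq(900, 908, 2), m, meta), "spectra_set")
})

test_that("spectra CSV round trip is the identity and the reader validates", {
  co <- generate_cohort(synthetic_config(n_dcd = 2, n_dbd = 2,
                                         replicates_per_donor = 2, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(co$set, path)
  back <- read_spectra_csv(path)
  expect_equal(back$grid, co$set$grid, tolerance = 1e-12)
  expect_lt(max(abs(back$matrix - co$set$matrix)), 1e-12)
  expect_identical(back$meta, co$set$meta)

  # header with 3 rows on a 900..1800 step-2 grid parses to 451 points
  g <- seq(900, 1800, 2)
  small <- toy_set(matrix(rnorm(3 * length(g)), 3), grid = g)
  write_spectra_csv(small, path)
  expect_identical(dim(read_spectra_csv(path)$matrix), c(3L, 451L))

  lines <- readLines(path)
  hdr <- strsplit(lines[1], ",")[[1]]
  bad <- paste(c(hdr[1:3], rev(hdr[-(1:3)])), collapse = ",")
  writeLines(c(bad, lines[-1]), path)
  expect_error(read_spectra_csv(path), "ascending")

  write_spectra_csv(small, path)
  lines <- readLines(path)
  lines[3] <- sub("^(D02,r1,UNKNOWN,)[^,]+", "\\1oops", lines[3])
  writeLines(lines, path)
  expect_error(read_spectra_csv(path), "row 2")
})

test_that("align_axes interpolates linearly, never extrapolates, idempotent", {
  # already aligned input is returned unchanged
  g <- seq(1000, 1100, 2)
  s1 <- ftir_spectrum(g, sin(g / 30), "A", "r1", "DCD")
  s2 <- ftir_spectrum(g, cos(g / 30), "B", "r1", "DBD")
  al <- align_axes(list(s1, s2))
  expect_equal(al$grid, g)
  expect_equal(al$matrix[1, ], sin(g / 30))
  expect_equal(align_axes(al)$matrix, al$matrix)

  # linear data reproduced exactly on a coarser grid
  fine <- ftir_spectrum(seq(1000, 1100, 1), seq(1000, 1100, 1), "A", "r1", "DCD")
  al2 <- align_axes(list(fine), target_grid = seq(1000, 1100, 2))
  expect_equal(al2$matrix[1, ], seq(1000, 1100, 2), tolerance = 1e-12)

  # quadratic interpolation error bounded by h^2 max|y''| / 8
  a <- 3e-3
  src_grid <- seq(1000, 1200, 4)
  quad <- function(v) a * (v - 1100)^2
  sp <- ftir_spectrum(src_grid, quad(src_grid), "A", "r1", "DCD")
  tgt <- seq(1002, 1198, 4)  # midpoints of source intervals
  al3 <- align_axes(list(sp), target_grid = tgt)
  expect_lte(max(abs(al3$matrix[1, ] - quad(tgt))), 4^2 * 2 * a / 8 + 1e-12)

  far <- ftir_spectrum(seq(3000, 3100, 2), rep(1, 51), "B", "r1", "DCD")
  expect_error(align_axes(list(s1, far)), "overlap")
})

test_that("replicate aggregation averages per donor and commutes with windowing", {
  co <- generate_cohort(synthetic_config(seed = 5))
  don <- aggregate_replicates(co$set)
  expect_identical(nrow(don$matrix), 10L)
  expect_true(all(don$meta$replicate_id == "mean"))
  d1 <- which(co$set$meta$donor_id == don$meta$donor_id[1])
  expect_equal(don$matrix[1, ], colMeans(co$set$matrix[d1, ]))

  w <- spectral_window(name = "fingerprint")
  expect_equal(extract_window(don, w)$matrix,
               aggregate_replicates(extract_window(co$set, w))$matrix)

  bad <- co$set
  bad$meta$group[1] <- "DBD"
  expect_error(aggregate_replicates(bad), "conflicting group")
})

test_that("window extraction uses closed bounds and truncates margins", {
  g <- seq(400, 4000, 2)
  set <- toy_set(matrix(0, 1, length(g)), grid = g)
  expect_identical(ncol(extract_window(set, spectral_window(name = "amide_i"))$matrix), 51L)
  expect_identical(ncol(extract_window(set, spectral_window(name = "fingerprint"))$matrix), 451L)
  expect_identical(ncol(extract_window(set, spectral_window(name = "fingerprint"),
                                       margin_points = 7)$matrix), 465L)
  # margin truncated at the grid edge
  near_edge <- extract_window(set, spectral_window(410, 430), margin_points = 7)
  expect_equal(near_edge$grid[1], 400)
  expect_error(extract_window(set, spectral_window(5000, 5100)), "no grid points")
})
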