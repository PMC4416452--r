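test_that("splice correction uses SWIR1 as reference and restores planted distortions", {
  grid <- 350:2500
  # piecewise-constant spectrum: VNIR 0.40, SWIR1 0.44, SWIR2 0.44
  m <- matrix(ifelse(grid <= 1000, 0.40, 0.44), 1, length(grid))
  set <- spectra_set(m, grid, "a")
  out <- correct_sensor_jumps(set)
  f <- attr(out, "jump_factors")
  expect_equal(unname(f[1, "f_vnir"]), 1.1)
  expect_equal(unname(out$matrix[1, grid <= 1000]), rep(0.44, sum(grid <= 1000)))

  # spectrum already continuous at the splices (flat there): factors 1,
  # values unchanged
  truth <- 0.4 + 0.2 * exp(-(grid - 700)^2 / (2 * 30^2)) -
    0.1 * exp(-(grid - 1400)^2 / (2 * 50^2)) +
    0.05 * exp(-(grid - 2100)^2 / (2 * 40^2))
  cont <- spectra_set(matrix(truth, 1), grid, "a")
  out2 <- correct_sensor_jumps(cont)
  expect_equal(unname(attr(out2, "jump_factors")[1, ]), c(1, 1),
               tolerance = 1e-10)
  expect_equal(out2$matrix, cont$matrix, tolerance = 1e-10)

  # planted multiplicative distortions are removed; oracle is the
  # pre-distortion curve (locally flat at the splices, so the single-ratio
  # factors recover it everywhere)
  distorted <- truth
  distorted[grid <= 1000] <- distorted[grid <= 1000] * 0.95
  distorted[grid >= 1801] <- distorted[grid >= 1801] * 1.06
  dset <- spectra_set(matrix(distorted, 1), grid, "a")
  rec <- correct_sensor_jumps(dset)
  expect_lt(max(abs(rec$matrix[1, ] - truth)), 1e-6)
  # SWIR1 is bit-identical
  swir1 <- grid > 1000 & grid < 1801
  expect_identical(unname(rec$matrix[1, swir1]), distorted[swir1])
  # continuity at the splices under the stated convention
  expect_equal(unname(rec$matrix[1, grid == 1000]),
               unname(rec$matrix[1, grid == 1001]), tolerance = 1e-12)

  # degenerate reference band
  z <- cont$matrix
  z[1, grid == 1000] <- 0
  expect_error(correct_sensor_jumps(spectra_set(z, grid, "a")), "undefined")
})

test_that("SNV standardizes every spectrum to mean 0, sample SD 1", {
  # [0, 1, 2] -> [-1, 0, 1] pins down the n-1 divisor
  s <- suppressWarnings(spectra_set(matrix(c(0, 1, 2), 1), 400:402, "a"))
  expect_equal(unname(snv_transform(s)$matrix[1, ]), c(-1, 0, 1))

  # affine invariance: snv(a x + b) == snv(x), a > 0
  set.seed(7)
  x <- runif(2151)
  s1 <- spectra_set(matrix(x, 1), 350:2500, "a")
  s2 <- suppressWarnings(
    spectra_set(matrix(3.2 * x + 0.4, 1), 350:2500, "a"))
  expect_equal(snv_transform(s1)$matrix, snv_transform(s2)$matrix,
               tolerance = 1e-12)

  out <- snv_transform(s1)$matrix[1, ]
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(stats::sd(out) - 1), 1e-12)

  expect_error(snv_transform(spectra_set(matrix(0.5, 1, 2151), 350:2500, "a")),
               "constant")
})

test_that("Savitzky-Golay derivative is exact on low-order polynomials", {
  grid <- 400:500
  d_lin <- savgol_first_derivative(suppressWarnings(
    spectra_set(matrix(3 * (grid - 400) / 100, 1), grid, "a")))
  expect_lt(max(abs(d_lin$matrix - 3 / 100)), 1e-10)

  quad <- suppressWarnings(
    spectra_set(matrix(((grid - 450) / 100)^2, 1), grid, "a"))
  d_quad <- savgol_first_derivative(quad)
  inner <- d_quad$wavelengths
  expect_lt(max(abs(d_quad$matrix[1, ] - 2 * (inner - 450) / 100^2)), 1e-10)

  # edges dropped: 4 points per side
  expect_equal(d_quad$wavelengths, 404:496)
  expect_error(savgol_first_derivative(
    spectra_set(matrix(0.1 * (1:5), 1), 401:405, "a")), "shorter")
})

test_that("SG differentiation suppresses noise relative to finite differences", {
  set.seed(11)
  reps <- 50
  v <- t(replicate(reps, {
    x <- rnorm(200)
    sg <- savgol_first_derivative(
      suppressWarnings(spectra_set(matrix(x - min(x), 1), 1:200 + 399, "a")))
    fd <- diff(x)                      # 2-point finite difference, unit step
    c(var_sg = stats::var(sg$matrix[1, ]), var_fd = stats::var(fd))
  }))
  # oracle: both estimators computed directly on the same draws
  expect_true(all(v[, "var_sg"] < v[, "var_fd"]))
})

test_that("model-range restriction keeps the inclusive 400-1800 nm window", {
  set <- smooth_raw_set(n = 2)
  out <- subset_model_range(set)
  expect_equal(ncol(out$matrix), 1401)
  expect_equal(range(out$wavelengths), c(400, 1800))

  # derivative-state axis intersects cleanly
  d <- savgol_first_derivative(snv_transform(set))
  expect_equal(range(d$wavelengths), c(354, 2496))
  expect_equal(range(subset_model_range(d)$wavelengths), c(400, 1800))

  expect_error(subset_model_range(set, preprocess_config(
    model_range = c(2600, 2700))), "intersect|within")
})

test_that("pipeline enforces operator order and flags absorption features", {
  set <- smooth_raw_set(n = 2)
  out <- preprocess_pipeline(set)
  expect_identical(out$state, "first_derivative")
  expect_true(all(out$wavelengths >= 400 & out$wavelengths <= 1800))
  expect_length(attr(out, "processing_log"), 4L)
  # state machine forbids re-derivation
  expect_error(preprocess_pipeline(out), "state|derivative")

  # planted Gaussian dips show up as derivative zero-crossings at the centers
  grid <- 350:2500
  curve <- 0.5 * (1 - 0.3 * exp(-(grid - 700)^2 / (2 * 15^2))) *
    (1 - 0.2 * exp(-(grid - 1200)^2 / (2 * 25^2)))
  pset <- spectra_set(matrix(curve, 1), grid, "a")
  proc <- preprocess_pipeline(pset)
  dv <- proc$matrix[1, ]
  wl <- proc$wavelengths
  for (center in c(700, 1200)) {
    w <- which(wl >= center - 3 & wl <= center + 3)
    expect_true(any(diff(sign(dv[w])) != 0),
                label = paste("zero crossing near", center))
  }
})

test_that("config validation rejects impossible filters", {
  expect_error(preprocess_config(sg_half_window = 1, sg_poly_order = 3),
               "poly_order")
  expect_error(preprocess_config(model_range = c(1800, 400)), "increasing")
})
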