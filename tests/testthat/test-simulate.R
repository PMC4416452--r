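test_that("generation is seed-deterministic and noise-free spectra are exact", {
  g1 <- generate_greenhouse_dataset(seed = 3)
  g2 <- generate_greenhouse_dataset(seed = 3)
  expect_identical(g1$spectra$matrix, g2$spectra$matrix)
  expect_identical(g1$records, g2$records)
  expect_false(identical(generate_greenhouse_dataset(seed = 4)$spectra$matrix,
                         g1$spectra$matrix))

  # zero noise, zero jumps: spectrum equals the closed-form generating curve
  cfg <- sim_config()
  traits <- list(species = "A. unedo", delta15N = 5, n_content = 1.1,
                 gwc = 1.1, sla = 6)
  r1 <- simulate_leaf_spectrum(traits, cfg, noise = FALSE)
  r2 <- simulate_leaf_spectrum(traits, cfg, noise = FALSE)
  expect_identical(r1, r2)
  expect_true(all(r1 > 0 & r1 < 1))
})

test_that("isotope sensitivity concentrates spectral differences at planted centers", {
  cfg <- sim_config()
  base_traits <- list(species = "H. rosa-sinensis", delta15N = 0,
                      n_content = 2.2, gwc = 2.4, sla = 16)
  hi_traits <- base_traits
  hi_traits$delta15N <- 20
  r0 <- simulate_leaf_spectrum(base_traits, cfg, noise = FALSE)
  r20 <- simulate_leaf_spectrum(hi_traits, cfg, noise = FALSE)
  d <- abs(r20 - r0)
  grid <- cfg$grid
  ft <- cfg$features
  iso <- ft[ft$iso_sensitivity > 0, ]
  # oracle: the generating curves differ only where an isotope-sensitive
  # Gaussian has support, so the difference peaks at a planted center ...
  peak <- grid[which.max(d)]
  expect_true(any(abs(peak - iso$center) <= 2 * iso$width))
  # ... and vanishes beyond the features' support
  far <- rep(TRUE, length(grid))
  for (i in seq_len(nrow(iso)))
    far <- far & abs(grid - iso$center[i]) > 8 * iso$width[i]
  expect_gt(max(d), 1e-4)
  expect_lt(max(d[far]), 1e-5 * max(d))

  # no isotope sensitivity: spectra identical across delta15N
  cfg0 <- sim_config(features = default_features(iso_sensitivity = 0))
  expect_identical(simulate_leaf_spectrum(base_traits, cfg0, noise = FALSE),
                   simulate_leaf_spectrum(hi_traits, cfg0, noise = FALSE))
})

test_that("greenhouse design matches the labeling layout", {
  gh <- greenhouse_fixture()
  rec <- gh$records
  # 16 / 12 / 11 plants x 9 leaves
  expect_equal(sum(rec$species == "H. halimifolium"), 16 * 9)
  expect_equal(sum(rec$species == "H. rosa-sinensis"), 12 * 9)
  expect_equal(sum(rec$species == "A. unedo"), 11 * 9)
  expect_equal(sort(unique(rec$leaf_type)), c("mature", "stressed", "young"))
  # smallest species is allocated to the 0 / 20 treatments only
  expect_equal(sort(unique(rec$treatment[rec$species == "A. unedo"])), c(0, 20))
  expect_equal(sort(unique(rec$treatment[rec$species != "A. unedo"])),
               c(0, 10, 20))
  # labeling-induced within-species ranges span roughly 16-19 permil
  for (sp in unique(rec$species)) {
    rng <- diff(range(rec$delta15N[rec$species == sp]))
    expect_gt(rng, 12)
    expect_lt(rng, 26)
  }
  # failed uptake: mature A. unedo indistinguishable between treatments
  au <- rec[rec$species == "A. unedo" & rec$leaf_type == "mature", ]
  expect_gt(stats::wilcox.test(delta15N ~ treatment, data = au)$p.value, 0.01)
})

test_that("greenhouse isotope signature is independent of the other traits", {
  gh <- greenhouse_fixture()
  tab <- check_covariate_independence(gh$records)
  expect_equal(nrow(tab), 9L)
  expect_true(all(abs(tab$rho) < 0.3))

  # shuffled isotope values: correlation collapses to zero
  rec <- gh$records
  set.seed(1)
  rec$delta15N <- sample(rec$delta15N)
  tab2 <- check_covariate_independence(rec)
  expect_true(all(abs(tab2$rho) < 0.3))

  # copying N% into the isotope column forces perfect rank correlation
  rec2 <- gh$records
  rec2$delta15N <- rec2$n_content
  tab3 <- check_covariate_independence(rec2)
  expect_equal(tab3$rho[tab3$covariate == "n_content"], rep(1, 3))
})

test_that("field gradient covaries with N content inside the printed bounds", {
  set.seed(19)
  r <- replicate(20, {
    fd <- generate_field_dataset(n = 40, seed = sample.int(1e6, 1))
    stopifnot(all(fd$records$n_content >= 0.47),
              all(fd$records$n_content <= 0.96),
              all(fd$records$delta15N >= -12),
              all(fd$records$delta15N <= -2.5))
    cor(fd$records$delta15N, fd$records$n_content)
  })
  expect_gt(median(r), 0.6)
  expect_lt(median(r), 0.9)

  # mixing limit: far from the canopy the signature approaches background
  fd <- generate_field_dataset(n = 60, seed = 5, max_distance = 200)
  far <- fd$records$distance_to_canopy > 100
  expect_lt(mean(fd$records$delta15N[far]), -10.5)
})

test_that("isotope label bookkeeping is exact", {
  # mixing identity: adding material at the pool's own atom fraction
  af0 <- 0.0036765 / (1 + 0.0036765)
  expect_equal(delta_after_label_addition(1e-3, 0, list(c(1e-4, af0))), 0,
               tolerance = 1e-9)

  # the per-10-permil recipe on a 14.8 mmol N pool shifts by ~ +10 permil
  # (frozen from direct atom-count arithmetic; (NH4)2SO4 carries 2 N)
  d <- delta_after_label_addition(
    14.8e-3, 0, list(c(0.274e-6, 0.98), c(2 * 0.145e-6, 0.95)))
  expect_equal(d, 10.03351, tolerance = 1e-5)

  # small-perturbation linearity: doubling the additions ~ doubles the shift
  d2 <- delta_after_label_addition(
    14.8e-3, 0, list(c(2 * 0.274e-6, 0.98), c(4 * 0.145e-6, 0.95)))
  expect_equal(d2 / d, 2, tolerance = 0.01)

  expect_error(delta_after_label_addition(0, 0, list()), "> 0")
  expect_error(delta_after_label_addition(1, 0, list(c(-1, 0.5))), ">= 0")
  expect_error(delta_after_label_addition(1, 0, list(c(1, 1.5))), "atom")
})
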