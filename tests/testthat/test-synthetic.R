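test_that("droplet loading follows the truncated Poisson", {
  lay <- make_layout(1e4, loading_mean = 0.3, max_a = 20, seed = 1)
  frac1 <- mean(lay$cells_per_droplet == 1)
  expect_equal(frac1, truncated_poisson_pmf(1, 0.3, 20), tolerance = 0.02)
  expect_identical(lay$cells_per_droplet,
                   make_layout(1e4, 0.3, 20, seed = 1)$cells_per_droplet)
  expect_true(all(make_layout(500, 2, 1, seed = 2)$cells_per_droplet == 1))
})

test_that("a noise-free experiment is exactly gain * signal + background", {
  lay <- make_layout(5, 0.5, 3, seed = 4)
  nm <- noise_model(0, 0, 0, bleach_rate = 0, excitation_cv = 0)
  tab <- synthesize_experiment(lay, "kuramoto", noise = nm, t_end = 40,
                               seed = 5, gain = 2, background = 10)
  sig <- attr(tab, "signal")
  expect_equal(tab$fluorescence, as.numeric(t(sig * 2 + 10)))
  expect_true(all(tab$rhodamine == 100))
})

test_that("bead sample variance matches the quadratic noise model", {
  nm <- noise_model(c0 = 4, c1 = 0.02, c2 = 2e-5, bleach_rate = 0,
                    excitation_cv = 0)
  tab <- synthesize_beads(40, c(200, 800), noise = nm, t_end = 240, seed = 6)
  v <- tapply(tab$fluorescence, list(tab$droplet_id, tab$cell_id), var)
  v1 <- mean(v["bead_lvl01", ], na.rm = TRUE)
  v2 <- mean(v["bead_lvl02", ], na.rm = TRUE)
  expect_equal(v1, noise_variance(nm, 200), tolerance = 0.10)
  # ratio of variances across intensity levels follows sigma^2(I1)/sigma^2(I2)
  expect_equal(v1 / v2, noise_variance(nm, 200) / noise_variance(nm, 800),
               tolerance = 0.15)
  # zero noise: constant columns
  tab0 <- synthesize_beads(3, 100, noise_model(0, 0, 0, 0, 0), t_end = 20,
                           seed = 7)
  expect_equal(var(tab0$fluorescence), 0)
})

test_that("six bead levels recover the noise coefficients within 20%", {
  nm <- noise_model(c0 = 1, c1 = 0.01, c2 = 1e-5, bleach_rate = 0,
                    excitation_cv = 0)
  tab <- synthesize_beads(50, c(50, 100, 200, 400, 800, 1600), noise = nm,
                          t_end = 240, seed = 8)
  fit <- fit_noise_model(tab)
  expect_equal(fit$c0, 1, tolerance = 0.2)
  expect_equal(fit$c1, 0.01, tolerance = 0.2)
  expect_equal(fit$c2, 1e-5, tolerance = 0.2)
})

test_that("constant-variance beads yield insignificant c1 and c2", {
  nm <- noise_model(c0 = 9, c1 = 0, c2 = 0, bleach_rate = 0,
                    excitation_cv = 0)
  tab <- synthesize_beads(40, c(100, 300, 900), noise = nm, t_end = 200,
                          seed = 9)
  fit <- fit_noise_model(tab)
  co <- attr(fit, "fit")$coefficients
  expect_lt(abs(co[2, "t value"]), 2)
  expect_lt(abs(co[3, "t value"]), 2)
  expect_error(fit_noise_model(synthesize_beads(5, c(100, 200), noise = nm,
                                                t_end = 100, seed = 1)),
               "3 distinct")
})

test_that("bleaching gives a slight negative trend, at most 20% over 240 h", {
  nm <- noise_model()
  expect_lte(1 - exp(-nm$bleach_rate * 240), 0.20)
  lay <- make_layout(4, 0.3, 1, seed = 10)
  tab <- synthesize_experiment(lay, "kuramoto",
                               noise = noise_model(0, 0, 0,
                                                   bleach_rate = 1e-3,
                                                   excitation_cv = 0),
                               t_end = 240, seed = 11)
  tr <- rhodamine_normalize(tab)
  early <- rowMeans(tr$mat[, 1:100])
  late <- rowMeans(tr$mat[, 381:481])
  expect_true(all(late < early))
})

test_that("generation is bit-reproducible under a fixed seed", {
  lay <- make_layout(6, 1, 4, seed = 12)
  t1 <- synthesize_experiment(lay, "kuramoto", t_end = 30, seed = 13)
  t2 <- synthesize_experiment(lay, "kuramoto", t_end = 30, seed = 13)
  expect_identical(t1$fluorescence, t2$fluorescence)
  expect_identical(t1$rhodamine, t2$rhodamine)
})
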