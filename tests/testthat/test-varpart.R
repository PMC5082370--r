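test_that("zero detector variance propagates to zero everywhere", {
  gain <- detrend_noise_gain(ma_weights(48), 240,
                             window_idx = 1:100)
  out <- detector_variance_to_periodogram(gain, 0, runif(50))
  expect_true(all(out$bias == 0))
  expect_true(all(out$var == 0))
  expect_error(detector_variance_to_periodogram(gain[1:10], 1, runif(50)),
               "mismatched")
})

test_that("identity detrending turns white noise into a flat L*sigma^2 spectrum", {
  L <- 170; sig2 <- 2.5
  gain <- detrend_noise_gain(NULL, L)
  expect_equal(gain, rep(L, L %/% 2))
  set.seed(21)
  mats <- matrix(rnorm(8000 * L, 0, sqrt(sig2)), 8000, L)
  pg <- periodogram(mats, normalize = FALSE)
  emp <- colMeans(pg$power)
  expect_lt(max(abs(emp - L * sig2) / (L * sig2)), 0.05)
})

test_that("the filtered-noise spectrum matches the Monte Carlo oracle within 5%", {
  N <- 480; sig2 <- 4
  set.seed(22)
  mats <- matrix(rnorm(6000 * N, 0, sqrt(sig2)), 6000, N)
  dt <- moving_average_detrend(mat_traj(mats))
  win <- window_frames(dt, 60, 230)
  pg <- periodogram(win, normalize = FALSE)
  gain <- detrend_noise_gain(ma_weights(48), N,
                             window_idx = match(win$frames, dt$frames))
  pred <- sig2 * gain
  expect_lt(max(abs(colMeans(pg$power) - pred) / pred), 0.05)
  # per-cell variance of a pure-noise periodogram is the beta term v^2
  empv <- apply(pg$power, 2, var)
  expect_lt(median(abs(empv - pred^2) / pred^2), 0.10)
})

test_that("bootstrap variance of the mean matches the CLT rate", {
  set.seed(23)
  pow <- matrix(rexp(200 * 30), 200, 30)
  pow <- pow / rowSums(pow)
  pg <- structure(list(freq = 1:30, period = 1 / (1:30), power = pow,
                       L = 60, frame_dt = 0.5, normalized = TRUE,
                       degenerate = FALSE), class = "periodogram_set")
  bt <- bootstrap_total_variance(pg, n_boot = 2000, seed = 3)
  clt <- apply(pow, 2, var) / 200
  expect_lt(median(abs(bt$var_mean - clt) / clt), 0.10)
  bt2 <- bootstrap_total_variance(pg, n_boot = 2000, seed = 3)
  expect_identical(bt$var_mean, bt2$var_mean)
  deg <- bootstrap_total_variance(pg, n_boot = 1, seed = 1)
  expect_true(attr(deg, "degenerate"))
})

test_that("partitioning floors negatives and bounds the fraction", {
  tot <- c(4, 2, 1)
  det <- c(4, 1, 2)   # last exceeds the total: subtraction artifact
  p <- partition_variance(tot, det)
  expect_equal(p$stochastic, c(0, 1, 0))
  expect_equal(p$detector_fraction, c(1, 0.5, 1))
  expect_equal(attr(p, "n_floored"), 1)
  p0 <- partition_variance(tot, rep(0, 3))
  expect_equal(max(p0$detector_fraction), 0)
  expect_equal(p0$stochastic, tot)
  pd <- partition_variance(tot, tot)
  expect_equal(pd$stochastic, rep(0, 3))
  expect_equal(attr(pd, "max_fraction"), 1)
})

test_that("harmonic ANOVA partitions and scales sums of squares exactly", {
  L <- 170; dt <- 0.5
  set.seed(24)
  freqs <- c(3, 4, 5) / (L * dt)
  y <- 2 * sin(2 * pi * freqs[2] * (0:(L - 1)) * dt) + rnorm(L, 0, 0.5)
  y <- y - mean(y)
  tab <- harmonic_anova(y, freqs, frame_dt = dt)
  expect_equal(sum(tab$ss), 1, tolerance = 1e-12)
  expect_equal(tab$df, c(2, 2, 2, L - 6))
  expect_true(which.max(tab$ss[1:3]) == 2)
  # lm-based oracle for the same projection
  tt <- (0:(L - 1)) * dt
  X <- do.call(cbind, lapply(freqs, function(f)
    cbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))))
  fit <- lm(y ~ 0 + X)
  ss_err_lm <- sum(residuals(fit)^2)
  expect_equal(tab$ss[4], ss_err_lm / sum(y^2), tolerance = 1e-10)
  expect_error(harmonic_anova(y, c(freqs, freqs[1])), "duplicate")
})

test_that("a pure model-frequency tone saturates its SS with capped F", {
  L <- 120; dt <- 0.5
  f0 <- 6 / (L * dt)
  y <- sin(2 * pi * f0 * (0:(L - 1)) * dt)
  tab <- harmonic_anova(y, f0, frame_dt = dt)
  expect_equal(tab$ss[1], 1, tolerance = 1e-12)
  expect_true(attr(tab, "capped") || tab$f_value[1] > 1e12)
})

test_that("published-table arithmetic is reproduced from SS and df", {
  ss_model <- c(0.045225, 0.150372, 0.160925, 0.104017, 0.067837)
  out <- anova_f_from_ss(ss_model, rep(2, 5), 0.471624, 160)
  expect_equal(round(out$f_value[2], 2), 25.51)
  expect_equal(round(out$f_value[3], 2), 27.30)
  expect_equal(round(100 * attr(out, "model_ss_fraction")), 53)
})

test_that("injected detector noise is recovered by the partition", {
  # build a cell population with a known stochastic tone + white detector
  # noise; the detector share estimated via the propagation route must
  # agree with the truth measured from the noise-free twin
  set.seed(25)
  N <- 480; K <- 150
  tt <- (0:(N - 1)) * 0.5
  phase <- runif(K, 0, 2 * pi)
  amp <- rlnorm(K, 0, 0.3)
  clean <- amp * sin(outer(2 * pi * tt / 21, rep(1, K)) + rep(phase, each = N))
  clean <- t(clean)
  sig2 <- 0.15
  noisy <- clean + rnorm(length(clean), 0, sqrt(sig2))
  prep <- function(m) {
    dt <- moving_average_detrend(mat_traj(m))
    win <- window_frames(dt, 60, 230)
    list(pg = periodogram(win, normalize = FALSE),
         gain = detrend_noise_gain(ma_weights(48), N,
                                   window_idx = match(win$frames, dt$frames)))
  }
  pn <- prep(noisy); pc <- prep(clean)
  true_var_clean <- apply(pc$pg$power, 2, var)
  total_var <- apply(pn$pg$power, 2, var)
  sh <- detector_share(pn$pg, pn$gain, sig2, n_boot = 300, seed = 26)
  # compare at the frequency of maximum detector fraction
  est <- sh$partition$detector_fraction
  truth <- 1 - true_var_clean / total_var
  l_star <- which.max(est)
  expect_equal(est[l_star], max(0, truth[l_star]), tolerance = 0.35)
  expect_true(sh$ci[1] <= sh$max_fraction && sh$max_fraction <= sh$ci[2])
})
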