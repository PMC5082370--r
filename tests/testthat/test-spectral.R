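test_that("a grid-frequency cosine concentrates all normalized power", {
  L <- 170
  for (l0 in c(4, 10, 33)) {
    x <- cos(2 * pi * l0 * (0:(L - 1)) / L)
    pg <- periodogram(x)
    expect_equal(unname(pg$power[1, l0]), 1, tolerance = 1e-12)
    expect_equal(sum(pg$power), 1, tolerance = 1e-12)
    expect_equal(extract_period_amplitude(pg)$period, (L * 0.5) / l0)
  }
})

test_that("normalized rows sum to one and degenerate input is flagged", {
  set.seed(1)
  mat <- matrix(rnorm(4 * 64), 4)
  mat <- mat - rowMeans(mat)
  pg <- periodogram(mat)
  expect_equal(unname(rowSums(pg$power)), rep(1, 4), tolerance = 1e-12)
  pg0 <- periodogram(rep(2, 64))
  expect_true(pg0$degenerate)
  expect_true(all(is.na(pg0$power)))
  bare0 <- periodogram(rep(2, 64), normalize = FALSE)
  expect_equal(max(bare0$power), 0)
  expect_error(periodogram(c(1, NA, rep(1, 10))), "non-finite")
  expect_error(periodogram(rnorm(4)), "too short")
})

test_that("Parseval holds for the bare periodogram", {
  for (L in c(64, 65)) {
    x <- rnorm(L)
    x <- x - mean(x)
    pg <- periodogram(x, normalize = FALSE)
    p <- unname(pg$power[1, ])
    total <- if (L %% 2 == 0)
      2 * sum(p[-length(p)]) + p[length(p)] else 2 * sum(p)
    expect_equal(total, L * sum(x^2), tolerance = 1e-9 * L * sum(x^2))
  }
})

test_that("peak extraction breaks exact ties toward the longer period", {
  # construct an exactly tied normalized periodogram
  p <- c(0.1, 0.35, 0.05, 0.35, 0.15)
  pg <- structure(list(freq = (1:5) / (10 * 0.5), period = (10 * 0.5) / (1:5),
                       power = matrix(p, 1), L = 10, frame_dt = 0.5,
                       normalized = TRUE, degenerate = FALSE),
                  class = "periodogram_set")
  pa <- extract_period_amplitude(pg)
  expect_equal(pa$period, 5 / 2)   # the lower-frequency member of the tie
  expect_true(pa$tie)
  sp <- secondary_peak(pg)
  expect_equal(sp$period2, 5 / 4)  # the member the primary did not take
})

test_that("secondary peaks report the weaker tone and go absent for one tone", {
  L <- 170
  tt <- 0:(L - 1)
  two <- 2 * cos(2 * pi * 8 * tt / L) + 1 * cos(2 * pi * 20 * tt / L)
  pg <- periodogram(two)
  expect_equal(extract_period_amplitude(pg)$period, (L * 0.5) / 8)
  expect_equal(secondary_peak(pg)$period2, (L * 0.5) / 20)
  one <- cos(2 * pi * 8 * tt / L)
  expect_true(is.na(secondary_peak(periodogram(one))$period2))
})

test_that("Hilbert phase counts cycles of a pure tone over the window", {
  tt <- seq(0, 240, by = 0.5)
  x <- sin(2 * pi * tt / 21)
  ph <- hilbert_phase(x, frames = seq_along(tt) - 1L,
                      t0_frame = 60, t1_frame = 230)
  expect_equal(as.numeric(ph), 85 / 21, tolerance = 0.02 * 85 / 21)
  expect_error(hilbert_phase(x, frames = seq_along(tt) - 1L,
                             t0_frame = -5, t1_frame = 230), "window")
})

test_that("cycle counts are invariant under time reversal", {
  # the analytic-signal argument obeys phi_rev(t) = -phi(T - t), so over a
  # window symmetric about the midpoint the accumulated cycles are equal:
  # a reversed oscillation completes the same number of cycles
  set.seed(2)
  tt <- seq(0, 240, by = 0.5)
  x <- sin(2 * pi * tt / 21) + 0.2 * sin(2 * pi * tt / 9 + 1)
  frames <- seq_along(tt) - 1L
  ph_f <- hilbert_phase(x, frames, 125, 355)
  ph_r <- hilbert_phase(rev(x), frames, 125, 355)
  expect_equal(as.numeric(ph_r), as.numeric(ph_f), tolerance = 1e-6)
})

test_that("constant series give zero cycles, flagged degenerate", {
  ph <- hilbert_phase(rep(3, 300), t0_frame = 60, t1_frame = 230)
  expect_equal(as.numeric(ph), 0)
  expect_true(attr(ph, "degenerate"))
})

test_that("periodogram averaging reproduces mean and sample variance", {
  x <- cos(2 * pi * 4 * (0:99) / 100)
  y <- cos(2 * pi * 9 * (0:99) / 100)
  pg <- periodogram(rbind(x, x))
  avg <- average_periodogram(pg)
  expect_equal(unname(avg$mean), unname(pg$power[1, ]))
  expect_equal(max(avg$var), 0)
  pg2 <- periodogram(rbind(x, y))
  avg2 <- average_periodogram(pg2)
  expect_equal(unname(avg2$var),
               unname((pg2$power[1, ] - pg2$power[2, ])^2 / 2),
               tolerance = 1e-12)
  expect_equal(sum(avg2$mean), 1, tolerance = 1e-12)
  expect_error(average_periodogram(periodogram(x)), "two cells")
})

test_that("phase and period are consistent for pure tones", {
  for (period_h in c(17, 21, 26)) {
    tt <- seq(0, 240, by = 0.5)
    x <- sin(2 * pi * tt / period_h)
    cycles <- as.numeric(hilbert_phase(x, seq_along(tt) - 1L, 60, 230))
    expect_equal(cycles * period_h / 85, 1, tolerance = 0.02)
  }
})

test_that("phase correlations on stochastic ensembles have the expected signs", {
  # oscillators completing more cycles in the window have shorter periods,
  # and faster (lower-amplitude) oscillators accumulate more cycles
  net <- build_default_clock()
  mat <- gillespie_ensemble(net, 400, 240, 0.5, seed = 78,
                            obs_species = "prot_ccg2")
  tr <- moving_average_detrend(dropclock:::ssa_matrix_to_ntraj(mat))
  s <- phase_summary(tr)
  expect_lt(cor(s$phase_cycles, s$period), 0)
  expect_lt(cor(s$amplitude, s$phase_cycles), 0)
})
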