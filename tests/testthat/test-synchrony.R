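test_that("the ICC estimator reproduces hand-computed snapshots", {
  # identical within, distinct between droplets: perfect agreement
  expect_equal(icc(rbind(c(1, 1), c(3, 3)))$icc, 1)
  # direct one-way ANOVA arithmetic: SS_B = 4, SS_W = 1
  r <- icc(rbind(c(1, 2), c(3, 4)))
  expect_equal(r$ems_b, 4)
  expect_equal(r$ems_w, 0.5)
  expect_equal(r$icc, 3.5 / 4.5)
  expect_error(icc(matrix(1, 1, 3)), "at least 2")
  expect_error(icc(matrix(1, 3, 1)), "at least 2")
  deg <- icc(matrix(2, 3, 3))
  expect_true(is.na(deg$icc))
  expect_true(attr(deg, "degenerate"))
})

test_that("icc agrees exactly with an aov-based variance-components oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:5, 1); a <- sample(2:4, 1)
    x <- matrix(rnorm(n * a), n, a)
    mine <- icc(x)
    df <- data.frame(y = as.numeric(x),
                     g = factor(rep(seq_len(n), times = a)))
    ms <- summary(stats::aov(y ~ g, df))[[1]]$`Mean Sq`
    oracle <- (ms[1] - ms[2]) / (ms[1] + (a - 1) * ms[2])
    expect_equal(mine$icc, oracle, tolerance = 1e-12)
  }
})

test_that("the ICC null scatters about zero and spans its lower bound", {
  set.seed(12)
  vals <- replicate(100, icc(matrix(rnorm(200 * 4), 200, 4))$icc)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 0.01)
  # perfectly anticorrelated pairs reach the -1/(a-1) = -1 bound
  z <- rnorm(100)
  anti <- icc(cbind(z, -z))
  expect_equal(anti$icc, -1, tolerance = 1e-12)
})

test_that("the surface is 1 for droplet-specific copies and strata are exact sizes", {
  tt <- seq(0, 20, by = 0.5)
  base <- sin(2 * pi * tt / 7)
  mat <- rbind(base + 1, base + 1, base + 5, base + 5,
               base + 2, base + 2, base + 2)
  tr <- mat_traj(mat, droplet_id = c("d1", "d1", "d2", "d2",
                                     "e1", "e1", "e1"))
  surf <- icc_surface(tr, min_droplets = 2)
  expect_equal(surf$a, 2L)  # only the a = 2 stratum has >= 2 droplets
  expect_true(all(surf$icc[1, ] == 1))
})

test_that("strangers resampling destroys within-droplet structure", {
  set.seed(13)
  lay <- make_layout(150, 1.0, 3, seed = 13)
  kp <- kuramoto_params(K_c = 0.4)
  ks <- kuramoto_simulate(kp, lay, t_end = 120, seed = 14)
  tr <- mat_traj(ks$fluorescence, droplet_id = ks$droplet_id)
  true_surf <- icc_surface(tr)
  late <- true_surf$frames >= 80
  expect_gt(mean(true_surf$icc[match(2, true_surf$a), late], na.rm = TRUE),
            0.3)
  reps <- strangers_control(tr, n_reps = 10, seed = 15)
  ms <- attr(reps, "mean_surface")
  expect_lt(mean(abs(ms$icc), na.rm = TRUE), 0.1)
  expect_length(reps, 10)
})

test_that("the Garcia-Ojalvo ratio hits its analytic anchors", {
  tt <- seq(0, 50, 0.5)
  s <- sin(tt)
  ident <- mat_traj(rbind(s, s, s), droplet_id = rep("d1", 3))
  expect_equal(garcia_ojalvo_R(ident)$R, 1)
  anti <- mat_traj(rbind(s, -s), droplet_id = rep("d1", 2))
  expect_equal(garcia_ojalvo_R(anti)$R, 0)
  set.seed(16)
  a <- 8
  Rs <- replicate(60, {
    m <- matrix(rnorm(a * 101), a)
    garcia_ojalvo_R(mat_traj(m, droplet_id = rep("d1", a)))$R
  })
  expect_equal(mean(Rs), 1 / a, tolerance = 0.2)
})

test_that("the Kuramoto order parameter matches closed-form cases", {
  ph_equal <- matrix(1.3, 4, 10)
  expect_equal(kuramoto_order(ph_equal, rep("d1", 4))$K, 1)
  ph_sym <- matrix(c(0, pi / 2, pi, 3 * pi / 2), 4, 5)
  expect_equal(kuramoto_order(ph_sym, rep("d1", 4))$K, 0, tolerance = 1e-12)
  # i.i.d. uniform phases: E|mean phasor| ~ sqrt(pi)/(2 sqrt(a))
  set.seed(17)
  for (a in c(4, 16)) {
    ph <- matrix(runif(a * 2000, 0, 2 * pi), a)
    K <- kuramoto_order(ph, rep("d1", a))$K
    expect_equal(K, sqrt(pi) / (2 * sqrt(a)), tolerance = 0.05)
  }
})

test_that("surface regression recovers slope and size-specific intercepts", {
  frames <- 0:99
  a_sizes <- c(2L, 3L, 4L)
  set.seed(18)
  x_icc <- matrix(runif(3 * 100), 3, dimnames = list(a_sizes, frames))
  x <- structure(list(a = a_sizes, frames = frames, icc = x_icc,
                      n_droplets = setNames(c(5L, 5L, 5L), a_sizes)),
                 class = "icc_surface")
  ident <- surface_regression(x, x)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(unname(ident$intercepts), rep(0, 3), tolerance = 1e-12)
  expect_equal(ident$r_squared, 1, tolerance = 1e-12)
  c_a <- c(`2` = 0.1, `3` = -0.2, `4` = 0.3)
  y <- x
  y$icc <- 0.5 * x$icc + c_a[as.character(a_sizes)]
  fit <- surface_regression(y, x)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercepts[as.character(a_sizes)], c_a, tolerance = 1e-10)
  # unrelated random surfaces: no shared structure
  y2 <- x
  y2$icc <- matrix(runif(300), 3, dimnames = dimnames(x$icc))
  expect_lt(surface_regression(y2, x)$r_squared, 0.2)
})

test_that("period statistics versus droplet size reproduce the rank tests", {
  tab <- period_size_table()
  s1 <- spearman_cor(tab$a, tab$mean_period)
  s2 <- spearman_cor(tab$a, tab$var_period)
  s3 <- spearman_cor(tab$a, tab$mean_period2)
  s4 <- spearman_cor(tab$a, tab$var_period2)
  expect_equal(round(s1$rho, 4), 0.3669)
  expect_equal(round(s2$rho, 4), -0.6316)
  expect_equal(round(s3$rho, 4), 0.7083)
  expect_equal(round(s4$rho, 4), -0.7083)
  # strictly increasing column gives rho exactly 1
  df <- data.frame(droplet_id = rep(c("d1", "d2", "d3"), each = 4),
                   period = rep(c(1, 2, 3), each = 4) + rep(1:4, 3) / 100,
                   period2 = rep(c(5, 6, 7), each = 4))
  lay <- structure(list(droplet_id = c("d1", "d2", "d3"),
                        cells_per_droplet = c(2L, 3L, 4L),
                        genotype = "test"), class = "droplet_layout")
  out <- period_vs_droplet_size(df, lay)
  expect_equal(out$spearman$rho[out$spearman$column == "mean_period"], 1)
})
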