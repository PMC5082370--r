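#' Per-frequency noise gain of the detrend-and-window operator
#'
#' White detector noise reaches the periodogram through the linear operator
#' Q that subtracts the moving average and restricts to the analysis
#' window.  This computes, exactly, the factor `g_l` such that white noise
#' of variance `sigma^2` at the input contributes `sigma^2 * g_l` to the
#' expected bare periodogram at frequency index `l`: `g_l` is the squared
#' modulus of the DFT rows of Q summed over input frames.  For the identity
#' operator `g_l = L` at every `l` (the classic flat white-noise spectrum).
#'
#' @param kw detrending kernel weights (from [ma_weights()]), or `NULL`
#'   for identity detrending.
#' @param n_input number of input frames before detrending.
#' @param window_idx indices (into the detrended frame axis) of the
#'   analysis window; default the whole detrended range.
#' @return Numeric vector `g_l`, `l = 1..floor(L/2)`.
#' @export
detrend_noise_gain <- function(kw, n_input, window_idx = NULL) {
  if (is.null(kw)) {
    half <- 0L
    interior <- seq_len(n_input)
  } else {
    half <- (length(kw) - 1L) %/% 2L
    interior <- (half + 1L):(n_input - half)
  }
  if (is.null(window_idx)) window_idx <- seq_along(interior)
  L <- length(window_idx)
  # Q maps n_input frames to the L window frames
  Q <- matrix(0, L, n_input)
  for (r in seq_len(L)) {
    t_abs <- interior[window_idx[r]]
    Q[r, t_abs] <- 1
    if (!is.null(kw)) {
      cols <- (t_abs - half):(t_abs + half)
      Q[r, cols] <- Q[r, cols] - kw
    }
  }
  lmax <- L %/% 2
  Fm <- exp(-2i * pi * outer(1:lmax, 0:(L - 1)) / L)
  C <- Fm %*% Q
  rowSums(Mod(C)^2)
}

#' Detector-noise contribution to the bare periodogram variance
#'
#' Propagates additive white detector noise of per-frame variance
#' `sigma_det2` through detrending and the DFT.  Writing the observed
#' transform as signal plus filtered noise, the noise adds
#' `v_l = sigma_det2 * g_l` to the expected bare periodogram (the bias
#' term) and contributes per-cell periodogram variance
#' `(sigma_l^e)^2 = gamma_l * |S_l|^2 + beta_l`, with
#' `gamma_l = 2 v_l` (signal-noise cross term) and `beta_l = v_l^2`
#' (noise-noise term); `|S_l|^2` is estimated by the bias-corrected sample
#' mean of the bare periodogram.
#'
#' @param gain per-frequency noise gain from [detrend_noise_gain()].
#' @param sigma_det2 detector variance per frame of the (normalized)
#'   series, averaged over frames and cells.
#' @param mean_bare mean bare periodogram across cells (same grid), or
#'   `NULL` for a pure-noise series.
#' @return List with `bias` (`v_l`), `var` (`(sigma_l^e)^2`), `gamma`,
#'   `beta`.
#' @export
detector_variance_to_periodogram <- function(gain, sigma_det2,
                                             mean_bare = NULL) {
  stopifnot(sigma_det2 >= 0)
  v <- sigma_det2 * gain
  s2 <- if (is.null(mean_bare)) 0 else {
    if (length(mean_bare) != length(gain)) stop("mismatched frequency grids")
    pmax(mean_bare - v, 0)
  }
  list(bias = v, var = 2 * v * s2 + v^2, gamma = 2 * v, beta = v^2)
}

#' Bootstrap variance of the cell-averaged periodogram
#'
#' Resamples cells with replacement and returns the per-frequency variance
#' of the cell-averaged periodogram with percentile confidence intervals.
#'
#' @param pgrams a `periodogram_set` with at least 10 cells.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @param level CI level (default 0.95).
#' @return List with `var_mean` (per-frequency bootstrap variance of the
#'   mean), `ci_lo`, `ci_hi` (percentile CIs of the mean periodogram),
#'   `var_cell` (plain across-cell sample variance), `n_cells`, `n_boot`.
#' @export
bootstrap_total_variance <- function(pgrams, n_boot = 5000, seed = 1L,
                                     level = 0.95) {
  stopifnot(inherits(pgrams, "periodogram_set"))
  pow <- pgrams$power
  K <- nrow(pow)
  if (K < 10) stop("need at least 10 cells to bootstrap")
  set.seed(seed)
  means <- matrix(NA_real_, n_boot, ncol(pow))
  for (b in seq_len(n_boot))
    means[b, ] <- colMeans(pow[sample.int(K, K, replace = TRUE), ,
                               drop = FALSE])
  al <- (1 - level) / 2
  out <- list(var_mean = apply(means, 2, stats::var),
              ci_lo = apply(means, 2, stats::quantile, probs = al),
              ci_hi = apply(means, 2, stats::quantile, probs = 1 - al),
              var_cell = apply(pow, 2, stats::var),
              n_cells = K, n_boot = n_boot)
  if (n_boot < 2) {
    out$var_mean <- rep(NA_real_, ncol(pow))
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Partition periodogram variance into stochastic and detector components
#'
#' Per frequency, the stochastic (intra-cellular) variance is the total
#' minus the detector component; negative differences (subtraction
#' artifacts) are floored at zero and flagged.  The summary is the maximum
#' detector fraction over frequencies.
#'
#' @param total per-frequency total variance (across-cell variance of the
#'   bare periodogram).
#' @param detector per-frequency detector variance on the same scale
#'   (e.g. `detector_variance_to_periodogram()$var`).
#' @return A `variance_partition`: data frame with `total`, `detector`,
#'   `stochastic`, `detector_fraction`, plus attributes `max_fraction` and
#'   `n_floored`.
#' @export
partition_variance <- function(total, detector) {
  if (length(total) != length(detector)) stop("mismatched frequency grids")
  stoch <- total - detector
  n_floored <- sum(stoch < 0)
  stoch <- pmax(stoch, 0)
  frac <- ifelse(total > 0, pmin(detector / total, 1), 0)
  out <- data.frame(total = total, detector = detector, stochastic = stoch,
                    detector_fraction = frac)
  class(out) <- c("variance_partition", class(out))
  attr(out, "max_fraction") <- max(frac)
  attr(out, "n_floored") <- n_floored
  out
}

#' Detector share of periodogram variance, with bootstrap CI
#'
#' High-level wrapper: from bare per-cell periodograms and the detector
#' variance per frame, computes the per-frequency partition and a
#' percentile bootstrap CI (over cells) of the maximum detector fraction.
#'
#' @param pgrams bare (unnormalized) `periodogram_set`.
#' @param gain noise gain from [detrend_noise_gain()].
#' @param sigma_det2 detector variance per frame.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return List with `partition` (a [partition_variance()] result),
#'   `max_fraction`, `ci` (bootstrap CI of `max_fraction`).
#' @export
detector_share <- function(pgrams, gain, sigma_det2, n_boot = 500,
                           seed = 1L) {
  stopifnot(inherits(pgrams, "periodogram_set"), !pgrams$normalized)
  pow <- pgrams$power
  K <- nrow(pow)
  stat <- function(idx) {
    m <- colMeans(pow[idx, , drop = FALSE])
    v <- apply(pow[idx, , drop = FALSE], 2, stats::var)
    det <- detector_variance_to_periodogram(gain, sigma_det2, m)$var
    max(ifelse(v > 0, pmin(det / v, 1), 0))
  }
  est <- stat(seq_len(K))
  set.seed(seed)
  draws <- vapply(seq_len(n_boot),
                  function(b) stat(sample.int(K, K, replace = TRUE)),
                  numeric(1))
  m <- colMeans(pow)
  v <- apply(pow, 2, stats::var)
  det <- detector_variance_to_periodogram(gain, sigma_det2, m)$var
  list(partition = partition_variance(v, det),
       max_fraction = est,
       ci = stats::quantile(draws, c(0.025, 0.975)))
}

#' Harmonic analysis of variance of an oscillatory series
#'
#' Partitions the total sum of squares of a (detrended) series into
#' per-frequency components -- each model frequency contributes a sine and
#' a cosine term, hence 2 degrees of freedom -- and a residual.  All SS
#' are scaled so that their sum is 1; EMS = SS/df and each frequency's F
#' is its EMS over the error EMS.  The error df is `n - 2 m` for `m`
#' model frequencies (no mean correction: the input is already centered
#' by detrending).
#'
#' @param y numeric series (detrended).
#' @param model_freqs frequencies in 1/h, on the observable grid
#'   `l/(L*frame_dt)`.
#' @param frame_dt frame spacing in hours.
#' @return A `harmonic_anova` data frame: one row per model frequency plus
#'   an error row, with `df`, `ss` (scaled), `ems`, `f_value`, `p_value`.
#' @export
harmonic_anova <- function(y, model_freqs, frame_dt = 0.5) {
  n <- length(y)
  if (anyDuplicated(model_freqs)) stop("duplicate model frequencies")
  tt <- (seq_len(n) - 1) * frame_dt
  ss_total <- sum(y^2)
  ss_f <- vapply(model_freqs, function(f) {
    cc <- cos(2 * pi * f * tt); ss <- sin(2 * pi * f * tt)
    out <- (sum(y * cc))^2 / sum(cc^2)
    if (sum(ss^2) > 1e-12) out <- out + (sum(y * ss))^2 / sum(ss^2)
    out
  }, numeric(1))
  ss_err <- ss_total - sum(ss_f)
  df_err <- n - 2 * length(model_freqs)
  # scale so the SS sum to 1
  sc <- 1 / ss_total
  ems_err <- ss_err * sc / df_err
  f_val <- (ss_f * sc / 2) / ems_err
  capped <- !is.finite(f_val)
  tab <- data.frame(
    source = c(sprintf("frequency %.4f /h (period %.3g h)", model_freqs,
                       1 / model_freqs), "error"),
    df = c(rep(2L, length(model_freqs)), df_err),
    ss = c(ss_f * sc, ss_err * sc),
    ems = c(ss_f * sc / 2, ems_err),
    f_value = c(f_val, NA_real_),
    p_value = c(stats::pf(f_val, 2, df_err, lower.tail = FALSE), NA_real_))
  class(tab) <- c("harmonic_anova", class(tab))
  attr(tab, "model_ss_fraction") <- sum(ss_f) * sc
  attr(tab, "capped") <- any(capped)
  tab
}

#' F statistics from a printed sums-of-squares table
#'
#' Recomputes EMS = SS/df and F = EMS_model/EMS_error from tabulated
#' values, as used to check published analysis-of-variance tables.
#'
#' @param ss_model,df_model vectors of model sums of squares and df.
#' @param ss_error,df_error error sum of squares and df.
#' @return Data frame with `ems` and `f_value` per model row, plus
#'   attribute `model_ss_fraction` = sum(ss_model)/(sum(ss_model)+ss_error).
#' @export
anova_f_from_ss <- function(ss_model, df_model, ss_error, df_error) {
  ems <- ss_model / df_model
  ems_err <- ss_error / df_error
  out <- data.frame(ss = ss_model, df = df_model, ems = ems,
                    f_value = ems / ems_err)
  attr(out, "model_ss_fraction") <- sum(ss_model) / (sum(ss_model) + ss_error)
  out
}
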