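#' Droplet layout with truncated-Poisson loading
#'
#' Cells per droplet are drawn from a Poisson(`loading_mean`) distribution
#' truncated to `[1, max_a]`, the standard occupancy model for
#' flow-focusing encapsulation (empty droplets are not observed).
#'
#' @param n_droplets number of droplets.
#' @param loading_mean mean of the untruncated Poisson (> 0).
#' @param max_a maximum cells per droplet.
#' @param seed integer seed.
#' @param genotype label attached to the layout.
#' @return A `droplet_layout`: data frame-like list with `droplet_id`,
#'   `cells_per_droplet`, `genotype`.
#' @export
make_layout <- function(n_droplets, loading_mean = 0.3, max_a = 20,
                        seed = 1L, genotype = "reference") {
  stopifnot(n_droplets >= 1, loading_mean > 0, max_a >= 1)
  set.seed(seed)
  pmf <- stats::dpois(1:max_a, loading_mean)
  pmf <- pmf / sum(pmf)
  a <- sample.int(max_a, n_droplets, replace = TRUE, prob = pmf)
  structure(list(droplet_id = sprintf("d%05d", seq_len(n_droplets)),
                 cells_per_droplet = as.integer(a),
                 genotype = genotype),
            class = "droplet_layout")
}

#' @export
print.droplet_layout <- function(x, ...) {
  cat("droplet_layout: ", length(x$droplet_id), " droplets, ",
      sum(x$cells_per_droplet), " cells (genotype ", x$genotype, ")\n",
      sep = "")
  print(table(x$cells_per_droplet))
  invisible(x)
}

#' Truncated-Poisson probability of each droplet size
#'
#' @param a integer droplet sizes.
#' @param loading_mean Poisson mean.
#' @param max_a truncation bound.
#' @return P(size = a | 1 <= size <= max_a).
#' @export
truncated_poisson_pmf <- function(a, loading_mean, max_a = 20) {
  pmf <- stats::dpois(1:max_a, loading_mean)
  out <- numeric(length(a))
  ok <- a >= 1 & a <= max_a
  out[ok] <- stats::dpois(a[ok], loading_mean) / sum(pmf)
  out
}

#' Detection-noise model
#'
#' Additive Gaussian detector noise whose variance is quadratic in the
#' noise-free intensity, `sigma^2(I) = c0 + c1 I + c2 I^2` (offset, shot,
#' and multiplicative gain terms), plus a multiplicative exponential
#' photobleaching trend and multiplicative excitation fluctuations shared
#' with the reference channel.
#'
#' @param c0,c1,c2 variance polynomial coefficients.
#' @param bleach_rate exponential bleaching rate, 1/h (default gives <=
#'   20 percent total decay over 240 h).
#' @param excitation_cv coefficient of variation of the shared excitation
#'   factor.
#' @return A `noise_model` object.
#' @export
noise_model <- function(c0 = 1, c1 = 0.01, c2 = 1e-5,
                        bleach_rate = 8e-4, excitation_cv = 0.05) {
  stopifnot(bleach_rate >= 0, excitation_cv >= 0)
  nm <- structure(list(c0 = c0, c1 = c1, c2 = c2, bleach_rate = bleach_rate,
                       excitation_cv = excitation_cv),
                  class = "noise_model")
  nm
}

#' Detection variance at intensity I
#' @param nm a [noise_model()].
#' @param I noise-free intensity (detector units).
#' @return `c0 + c1 I + c2 I^2`.
#' @export
noise_variance <- function(nm, I) nm$c0 + nm$c1 * I + nm$c2 * I^2

# shared excitation/reference series for one acquisition
excitation_series <- function(n_frames, cv) {
  if (cv <= 0) rep(1, n_frames) else {
    # lognormal with unit mean and the requested CV, i.i.d. per frame
    sdl <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n_frames, -sdl^2 / 2, sdl))
  }
}

#' Synthesize a droplet fluorescence experiment
#'
#' Generates per-cell raw fluorescence with the full measurement chain:
#' `raw(t) = E(t) * B(t) * (gain * signal(t) + background) + eps(t)`, where
#' `E(t)` is a shared excitation factor (also multiplying the recorded
#' reference series), `B(t) = exp(-bleach_rate * t)` models photobleaching,
#' and `eps(t) ~ N(0, sigma^2(I))` with `I` the noise-free intensity.
#' Signals come from the stochastic clock (`gillespie`), the mean-field
#' quorum-sensing model (`quorum`), or the Kuramoto phase model
#' (`kuramoto`); for `gillespie` the droplet's cells are independent.
#'
#' @param layout a [make_layout()] result.
#' @param source one of `"gillespie"`, `"quorum"`, `"kuramoto"`.
#' @param noise a [noise_model()].
#' @param t_end,frame_dt grid in hours.
#' @param seed integer seed.
#' @param gain,background detector transfer (defaults 1 and 50).
#' @param net clock network for `source = "gillespie"`
#'   (default [build_default_clock()]).
#' @param quorum_params parameters for `source = "quorum"`, see
#'   [quorum_params()].
#' @param kuramoto_params parameters for `source = "kuramoto"`, see
#'   [kuramoto_params()].
#' @param obs_species observed species name (default `"prot_ccg2"`).
#' @return A trajectory table (data frame): `droplet_id`, `cell_id`,
#'   `frame`, `fluorescence`, `rhodamine`, `is_bead`.  The number of
#'   frames clipped at the intensity floor is in attribute
#'   `"n_clipped"`; the noise-free signal matrix in `"signal"`.
#' @export
synthesize_experiment <- function(layout, source = c("gillespie", "quorum",
                                                     "kuramoto"),
                                  noise = noise_model(), t_end = 240,
                                  frame_dt = 0.5, seed = 1L, gain = 1,
                                  background = 50,
                                  net = NULL, quorum_params = NULL,
                                  kuramoto_params = NULL,
                                  obs_species = "prot_ccg2") {
  source <- match.arg(source)
  stopifnot(inherits(layout, "droplet_layout"), inherits(noise, "noise_model"))
  n_frames <- floor(t_end / frame_dt + 1e-9) + 1L
  a <- layout$cells_per_droplet
  n_cells <- sum(a)
  droplet_of <- rep(layout$droplet_id, a)
  cell_id <- sprintf("%s_c%02d", droplet_of,
                     unlist(lapply(a, seq_len), use.names = FALSE))

  sig <- switch(source,
    gillespie = {
      if (is.null(net)) net <- build_default_clock()
      gillespie_ensemble(net, n_cells, t_end, frame_dt, seed = seed,
                         obs_species = obs_species)
    },
    quorum = {
      qp <- quorum_params %||% quorum_params()
      quorum_ensemble(layout, qp, t_end, frame_dt, seed = seed)
    },
    kuramoto = {
      kp <- kuramoto_params %||% kuramoto_params()
      ks <- kuramoto_simulate(kp, layout, t_end, frame_dt, seed = seed)
      ks$fluorescence
    })
  intensity <- sig * gain + background

  set.seed(seed + 1L)
  E <- excitation_series(n_frames, noise$excitation_cv)
  B <- exp(-noise$bleach_rate * seq(0, t_end, by = frame_dt))
  clean <- t(t(intensity) * (E * B))
  sigma <- sqrt(pmax(noise_variance(noise, clean), 0))
  eps <- matrix(stats::rnorm(length(clean)), nrow(clean)) * sigma
  raw <- clean + eps
  floor_val <- 1e-6
  n_clip <- sum(raw < floor_val)
  if (n_clip > 0) {
    warning(n_clip, " frames clipped at the intensity floor")
    raw[raw < floor_val] <- floor_val
  }
  rho_level <- 100
  tab <- data.frame(
    droplet_id = rep(droplet_of, each = n_frames),
    cell_id = rep(cell_id, each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, n_cells),
    fluorescence = as.numeric(t(raw)),
    rhodamine = rep(rho_level * E, n_cells),
    is_bead = FALSE)
  attr(tab, "n_clipped") <- n_clip
  attr(tab, "signal") <- sig
  attr(tab, "excitation") <- E
  tab
}

#' Synthesize constant-intensity bead controls
#'
#' Beads are constant-signal particles passed through the same detection,
#' excitation and reference machinery as cells; they calibrate the
#' quadratic detector-noise model.
#'
#' @param n_beads beads per intensity level.
#' @param intensity_levels vector of noise-free bead intensities.
#' @param noise a [noise_model()].
#' @param t_end,frame_dt grid in hours.
#' @param seed integer seed.
#' @return A trajectory table with `is_bead = TRUE`; droplet ids encode the
#'   intensity level.
#' @export
synthesize_beads <- function(n_beads, intensity_levels, noise = noise_model(),
                             t_end = 240, frame_dt = 0.5, seed = 1L) {
  stopifnot(n_beads >= 1, length(intensity_levels) >= 1)
  n_frames <- floor(t_end / frame_dt + 1e-9) + 1L
  set.seed(seed)
  E <- excitation_series(n_frames, noise$excitation_cv)
  B <- exp(-noise$bleach_rate * seq(0, t_end, by = frame_dt))
  rows <- list()
  for (k in seq_along(intensity_levels)) {
    I0 <- intensity_levels[k]
    clean <- outer(rep(I0, n_beads), E * B)
    sigma <- sqrt(pmax(noise_variance(noise, clean), 0))
    raw <- clean + matrix(stats::rnorm(length(clean)), n_beads) * sigma
    rows[[k]] <- data.frame(
      droplet_id = rep(sprintf("bead_lvl%02d", k), n_beads * n_frames),
      cell_id = rep(sprintf("bead_lvl%02d_b%03d", k, seq_len(n_beads)),
                    each = n_frames),
      frame = rep(seq_len(n_frames) - 1L, n_beads),
      fluorescence = as.numeric(t(raw)),
      rhodamine = rep(100 * E, n_beads),
      is_bead = TRUE)
  }
  do.call(rbind, rows)
}

#' Fit the quadratic detector-noise model from bead controls
#'
#' Least-squares fit of per-bead sample variance against per-bead mean
#' intensity with a quadratic polynomial, recovering the coefficients of
#' `sigma^2(I) = c0 + c1 I + c2 I^2`.
#'
#' @param bead_table a trajectory table of beads
#'   (from [synthesize_beads()]); bleaching/excitation trends are removed
#'   per bead with a centered moving average before computing variances.
#' @param window_frames detrending window in frames (default 48).
#' @return A [noise_model()] with the fitted `c0`, `c1`, `c2`; the lm fit
#'   is attached as attribute `"fit"`.
#' @export
fit_noise_model <- function(bead_table, window_frames = 48) {
  stopifnot(all(c("cell_id", "frame", "fluorescence") %in% names(bead_table)))
  if (length(unique(bead_table$droplet_id)) < 3)
    stop("need at least 3 distinct intensity levels to identify a quadratic")
  # cancel shared excitation fluctuations with the reference channel
  # (unit-mean correction keeps detector units intact)
  fl <- bead_table$fluorescence
  if ("rhodamine" %in% names(bead_table)) {
    e_hat <- bead_table$rhodamine / mean(bead_table$rhodamine)
    fl <- fl / e_hat
  }
  kw <- ma_weights(window_frames)
  half <- (length(kw) - 1L) %/% 2L
  # x - MA(x) deflates i.i.d. noise variance by this exact kernel factor
  deflate <- 1 - 2 * kw[half + 1L] + sum(kw^2)
  per_bead <- lapply(split(fl, bead_table$cell_id), function(x) {
    tr <- as.numeric(stats::filter(x, kw, sides = 2))
    keep <- (half + 1L):(length(x) - half)
    resid <- x[keep] - tr[keep]
    c(mean_I = mean(tr[keep]), var_I = stats::var(resid) / deflate)
  })
  st <- do.call(rbind, per_bead)
  df <- data.frame(I = st[, "mean_I"], v = st[, "var_I"])
  fit <- stats::lm(v ~ I + I(I^2), data = df)
  co <- stats::coef(fit)
  nm <- noise_model(c0 = unname(co[1]), c1 = unname(co[2]),
                    c2 = unname(co[3]), bleach_rate = 0, excitation_cv = 0)
  attr(nm, "fit") <- summary(fit)
  nm
}
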