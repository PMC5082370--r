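#' Parameters of the Kuramoto phase-locking control model
#'
#' Each cell is a phase oscillator with its own natural frequency; cells
#' in the same droplet attract each other's phases with coupling `K_c`:
#' \deqn{d\phi_j/dt = \omega_j + (K_c/a) \sum_{k \in droplet} \sin(\phi_k - \phi_j)}
#' plus optional white phase noise.  Pseudo-fluorescence is
#' `amplitude * sin(phi_j)`.
#'
#' @param omega_mean mean natural frequency, rad/h (default `2*pi/21`,
#'   a 21 h period).
#' @param omega_sd between-cell SD of the natural frequency, rad/h.
#' @param K_c coupling strength, rad/h (>= 0).
#' @param noise_sd white phase-noise intensity, rad/sqrt(h).
#' @param amplitude pseudo-fluorescence amplitude.
#' @return A `kuramoto_params` list.
#' @export
kuramoto_params <- function(omega_mean = 2 * pi / 21, omega_sd = 0.03,
                            K_c = 0.2, noise_sd = 0.05, amplitude = 1) {
  if (K_c < 0) stop("K_c must be >= 0")
  structure(list(omega_mean = omega_mean, omega_sd = omega_sd, K_c = K_c,
                 noise_sd = noise_sd, amplitude = amplitude),
            class = "kuramoto_params")
}

#' Simulate droplet-grouped Kuramoto oscillators
#'
#' Euler-Maruyama integration at a fixed internal step, recorded on the
#' frame grid.  Natural frequencies are drawn per cell; initial phases are
#' uniform on the circle.
#'
#' @param params a [kuramoto_params()].
#' @param layout a [make_layout()] giving the droplet grouping.
#' @param t_end,frame_dt grid in hours.
#' @param seed integer seed.
#' @param dt_int internal integration step in hours (default 0.05).
#' @param omegas optional explicit natural frequencies (length = total
#'   cells), overriding the random draw.
#' @param init_phases optional explicit initial phases.
#' @return List with `phases` (cells x frames, unwrapped radians),
#'   `fluorescence` (`amplitude * sin(phases)`), `droplet_id` per cell,
#'   `omegas`.
#' @export
kuramoto_simulate <- function(params, layout, t_end = 240, frame_dt = 0.5,
                              seed = 1L, dt_int = 0.05, omegas = NULL,
                              init_phases = NULL) {
  stopifnot(inherits(params, "kuramoto_params"),
            inherits(layout, "droplet_layout"))
  a <- layout$cells_per_droplet
  n <- sum(a)
  grp <- rep(seq_along(a), a)
  set.seed(seed)
  if (is.null(omegas))
    omegas <- stats::rnorm(n, params$omega_mean, params$omega_sd)
  phi <- if (is.null(init_phases)) stats::runif(n, 0, 2 * pi) else init_phases
  n_frames <- floor(t_end / frame_dt + 1e-9) + 1L
  steps_per_frame <- max(1L, round(frame_dt / dt_int))
  dt <- frame_dt / steps_per_frame
  out <- matrix(NA_real_, n, n_frames)
  out[, 1] <- phi
  a_of_cell <- a[grp]
  for (f in 2:n_frames) {
    for (s in seq_len(steps_per_frame)) {
      z <- exp(1i * phi)
      zbar <- (rowsum(Re(z), grp) + 1i * rowsum(Im(z), grp))[grp] / a_of_cell
      # (K_c/a)*sum_k sin(phi_k - phi_j) = K_c * Im(conj(z_j) * mean phasor)
      drift <- omegas + params$K_c * Im(Conj(z) * zbar)
      phi <- phi + drift * dt +
        if (params$noise_sd > 0)
          stats::rnorm(n, 0, params$noise_sd * sqrt(dt)) else 0
    }
    out[, f] <- phi
  }
  rownames(out) <- sprintf("%s_c%02d", rep(layout$droplet_id, a),
                           unlist(lapply(a, seq_len), use.names = FALSE))
  list(phases = out, fluorescence = params$amplitude * sin(out),
       droplet_id = rep(layout$droplet_id, a), omegas = omegas)
}
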