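#' Per-cell periodogram over the observable frequency grid
#'
#' Squared modulus of the discrete Fourier transform of each detrended
#' series at the observable frequencies `f_l = l / (L * dt)`,
#' `l = 1..floor(L/2)`.  The normalized variant divides each cell's row by
#' its sum over `l`, so power is the fraction of oscillators at each
#' frequency; DC is excluded (the input is detrended).
#'
#' @param x numeric vector, or a cells x frames matrix, or a `norm_traj`.
#' @param frame_dt frame spacing in hours.
#' @param normalize logical; return normalized power (default) or bare
#'   `|DFT|^2`.
#' @return A `periodogram_set`: list with `freq` (1/h), `period` (h),
#'   `power` (cells x frequency matrix) and the `normalized` flag.
#' @export
periodogram <- function(x, frame_dt = 0.5, normalize = TRUE) {
  mat <- if (inherits(x, "norm_traj")) x$mat
         else if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (!all(is.finite(mat))) stop("non-finite values in input series")
  L <- ncol(mat)
  if (L < 8) stop("series too short for a periodogram (L >= 8)")
  lmax <- L %/% 2
  ft <- stats::mvfft(t(mat))
  pow <- t(Mod(ft[2:(lmax + 1), , drop = FALSE])^2)
  dimnames(pow) <- list(rownames(mat), NULL)
  flag_degenerate <- FALSE
  if (normalize) {
    tot <- rowSums(pow)
    if (any(tot == 0)) {
      flag_degenerate <- TRUE
      tot[tot == 0] <- NA_real_
    }
    pow <- pow / tot
  }
  structure(list(freq = (1:lmax) / (L * frame_dt),
                 period = (L * frame_dt) / (1:lmax),
                 power = pow, L = L, frame_dt = frame_dt,
                 normalized = normalize,
                 degenerate = flag_degenerate),
            class = "periodogram_set")
}

#' @export
print.periodogram_set <- function(x, ...) {
  cat("periodogram_set:", nrow(x$power), "cells,", length(x$freq),
      "frequencies (", if (x$normalized) "normalized" else "bare", ")\n")
  invisible(x)
}

#' Period and amplitude of the dominant periodogram peak
#'
#' The period is `1/f_l*` at the frequency of maximum normalized power and
#' the amplitude is the square root of that maximum power.  Ties are broken
#' toward the lower frequency (longer period) and flagged.
#'
#' @param pgram a normalized `periodogram_set` (or a single numeric row of
#'   normalized power).
#' @return Data frame with one row per cell: `period` (h), `amplitude`,
#'   `tie` flag.
#' @export
extract_period_amplitude <- function(pgram) {
  stopifnot(inherits(pgram, "periodogram_set"))
  if (!pgram$normalized) stop("extract_period_amplitude expects normalized power")
  pow <- unname(pgram$power)
  res <- t(apply(pow, 1, function(p) {
    m <- max(p)
    # which.max takes the first (lowest-frequency) index, the tie rule
    c(which.max(p), sqrt(m), as.numeric(sum(p == m) > 1))
  }))
  data.frame(cell_id = rownames(pgram$power) %||% seq_len(nrow(pow)),
             period = pgram$period[res[, 1]],
             amplitude = res[, 2],
             tie = res[, 3] > 0,
             row.names = NULL)
}

#' Secondary periodogram peak (second harmonic of interest)
#'
#' Finds the second-largest local maximum of each cell's periodogram; if no
#' second local maximum exists the value is absent (`NA`).
#'
#' @inheritParams extract_period_amplitude
#' @param min_rel local maxima below `min_rel` times the global maximum are
#'   treated as numerical leakage, not peaks.
#' @return Data frame with `period2` (h) and `power2` per cell, `NA` when
#'   absent.
#' @export
secondary_peak <- function(pgram, min_rel = 1e-9) {
  stopifnot(inherits(pgram, "periodogram_set"))
  res <- t(apply(unname(pgram$power), 1, function(p) {
    n <- length(p)
    left <- c(-Inf, p[-n]); right <- c(p[-1], -Inf)
    loc <- which(p >= left & p >= right & p > min_rel * max(p))
    if (length(loc) < 2) return(c(NA_real_, NA_real_))
    ord <- loc[order(-p[loc], loc)]  # power desc, ties toward lower frequency
    c(ord[2], p[ord[2]])
  }))
  data.frame(cell_id = rownames(pgram$power) %||% seq_len(nrow(pgram$power)),
             period2 = pgram$period[res[, 1]],
             power2 = res[, 2], row.names = NULL)
}

#' Analytic signal via the discrete Hilbert transform
#'
#' @param x numeric vector (mean is subtracted internally).
#' @return Complex vector of the analytic signal.
#' @export
analytic_signal <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert phase in cycles over an analysis window
#'
#' Computes the argument of the analytic signal on the full series (to
#' push edge effects outside the window), unwraps it by recursively
#' choosing the integer multiple of \eqn{2\pi} that minimizes each phase
#' increment, and reports the accumulated phase over the window
#' `(phi(t1) - phi(t0)) / (2*pi)` in cycles.
#'
#' @param x numeric vector: the full detrended series.
#' @param frames integer frame indices matching `x` (defaults to
#'   `0:(length(x)-1)`).
#' @param t0_frame,t1_frame window ends in frame units.
#' @return Number of cycles completed over the window (0 and flagged
#'   degenerate for a constant series).
#' @export
hilbert_phase <- function(x, frames = seq_along(x) - 1L,
                          t0_frame = 60, t1_frame = 230) {
  if (t0_frame < min(frames) || t1_frame > max(frames))
    stop("phase window lies outside the series")
  if (stats::var(x) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  phi <- Arg(analytic_signal(x))
  dphi <- diff(phi)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))  # minimal-increment unwrap
  phi_c <- cumsum(c(phi[1], dphi))
  i0 <- which(frames == t0_frame)[1]
  i1 <- which(frames == t1_frame)[1]
  (phi_c[i1] - phi_c[i0]) / (2 * pi)
}

#' Cell-averaged periodogram with per-frequency variance
#'
#' @param pgrams a `periodogram_set` with at least two cells.
#' @return An `avg_periodogram`: list with `freq`, `period`, `mean`
#'   (per-frequency mean power), `var` (per-frequency sample variance) and
#'   `n_cells`.
#' @export
average_periodogram <- function(pgrams) {
  stopifnot(inherits(pgrams, "periodogram_set"))
  if (nrow(pgrams$power) < 2) stop("need at least two cells to average")
  structure(list(freq = pgrams$freq, period = pgrams$period,
                 mean = colMeans(pgrams$power),
                 var = apply(pgrams$power, 2, stats::var),
                 n_cells = nrow(pgrams$power),
                 L = pgrams$L, frame_dt = pgrams$frame_dt,
                 normalized = pgrams$normalized),
            class = "avg_periodogram")
}

#' @export
print.avg_periodogram <- function(x, ...) {
  pk <- which.max(x$mean)
  cat("avg_periodogram over", x$n_cells, "cells; peak period",
      round(x$period[pk], 2), "h\n")
  invisible(x)
}

#' Phase, period and amplitude summary for a trajectory set
#'
#' Convenience wrapper running [periodogram()], [extract_period_amplitude()],
#' [secondary_peak()] and [hilbert_phase()] per cell.
#'
#' @param traj a detrended `norm_traj`.
#' @param t0_frame,t1_frame Hilbert phase window in frame units (clipped to
#'   the available frames).
#' @param frame_dt frame spacing in hours.
#' @return Data frame with one row per cell: `cell_id`, `droplet_id`,
#'   `period`, `amplitude`, `period2`, `phase_cycles`.
#' @export
phase_summary <- function(traj, t0_frame = 60, t1_frame = 230,
                          frame_dt = 0.5) {
  stopifnot(inherits(traj, "norm_traj"))
  t0 <- max(t0_frame, min(traj$frames))
  t1 <- min(t1_frame, max(traj$frames))
  pg <- periodogram(window_frames(traj, t0, t1), frame_dt = frame_dt)
  pa <- extract_period_amplitude(pg)
  sp <- secondary_peak(pg)
  ph <- apply(traj$mat, 1, hilbert_phase, frames = traj$frames,
              t0_frame = t0, t1_frame = t1)
  data.frame(cell_id = traj$cells$cell_id,
             droplet_id = traj$cells$droplet_id,
             period = pa$period, amplitude = pa$amplitude,
             period2 = sp$period2, phase_cycles = as.numeric(ph),
             row.names = NULL)
}
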