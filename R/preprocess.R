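#' Reference-channel normalization
#'
#' Divides every cell's fluorescence series frame-wise by the shared
#' reference-dye (Rhodamine B) series recorded concurrently, cancelling
#' multiplicative excitation fluctuations common to the whole field.
#'
#' @param table a trajectory table as produced by the generators: a
#'   data frame with columns `droplet_id`, `cell_id`, `frame`,
#'   `fluorescence`, `rhodamine` (and optionally `is_bead`).
#' @return A `norm_traj` object: list with `mat` (cells x frames matrix of
#'   normalized fluorescence), `frames` (integer frame indices), `cells`
#'   (data frame with `cell_id`, `droplet_id`), and provenance flags.
#' @export
rhodamine_normalize <- function(table) {
  stopifnot(all(c("droplet_id", "cell_id", "frame", "fluorescence",
                  "rhodamine") %in% names(table)))
  ref <- tapply(table$rhodamine, table$frame, function(v) v[1])
  frames <- as.integer(names(ref))
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("reference series must be positive at all frames; offending frames: ",
         paste(utils::head(frames[!(is.finite(ref) & ref > 0)], 5), collapse = ", "))
  cells <- unique(table[c("cell_id", "droplet_id")])
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  mat <- matrix(NA_real_, nrow(cells), length(frames),
                dimnames = list(cells$cell_id, frames))
  idx <- cbind(match(table$cell_id, cells$cell_id),
               match(table$frame, frames))
  mat[idx] <- table$fluorescence
  if (anyNA(mat)) stop("incomplete frame grid: every cell needs every frame")
  mat <- sweep(mat, 2, as.numeric(ref), "/")
  structure(list(mat = mat, frames = frames, cells = cells,
                 normalized = TRUE, detrended = FALSE, ma_weights = NULL),
            class = "norm_traj")
}

#' @export
print.norm_traj <- function(x, ...) {
  cat("norm_traj:", nrow(x$mat), "cells x", ncol(x$mat), "frames",
      if (isTRUE(x$normalized)) "[normalized]" else "",
      if (isTRUE(x$detrended)) "[detrended]" else "", "\n")
  invisible(x)
}

#' Centered moving-average detrending weights
#'
#' For an even window of `w` frames the kernel is the symmetric
#' `w + 1`-tap average with half weights at the two ends
#' (`(1/2, 1, ..., 1, 1/2)/w`); for odd `w` it is the plain `w`-tap
#' average.  Both have unit sum and zero first moment, so a linear trend is
#' reproduced exactly and removed exactly by subtraction.
#'
#' @param window_frames window length in frames.
#' @return Numeric vector of kernel weights (odd length).
#' @export
ma_weights <- function(window_frames) {
  w <- as.integer(window_frames)
  stopifnot(w >= 2)
  if (w %% 2 == 0) c(0.5, rep(1, w - 1), 0.5) / w else rep(1 / w, w)
}

#' Amplitude transfer of the moving-average kernel
#'
#' Frequency response of the [ma_weights()] kernel at frequency `f` in
#' cycles per frame; the detrending operator (subtraction) has response
#' `1 - ma_transfer(f, w)`.  Closed form:
#' `sin(pi*w*f) * cos(pi*f) / (w * sin(pi*f))` for even `w`,
#' `sin(pi*w*f) / (w * sin(pi*f))` for odd `w`.
#'
#' @param f frequency in cycles per frame.
#' @param window_frames window length in frames.
#' @return Numeric vector of the (real) kernel response.
#' @export
ma_transfer <- function(f, window_frames) {
  w <- as.integer(window_frames)
  out <- ifelse(f == 0, 1,
                if (w %% 2 == 0) sin(pi * w * f) * cos(pi * f) / (w * sin(pi * f))
                else sin(pi * w * f) / (w * sin(pi * f)))
  out
}

#' 24-hour moving-average detrending
#'
#' Subtracts the centered moving average (default window 24 h = 48 frames
#' at 0.5 h spacing) from every cell's normalized series, removing slow
#' nonstationarities such as photobleaching.  Edge frames where the full
#' window does not fit are dropped, so the operator has uniform weights on
#' the interior; the kernel is exported for detector-noise propagation.
#'
#' @param traj a `norm_traj` from [rhodamine_normalize()].
#' @param window_h window span in hours.
#' @param frame_dt frame spacing in hours.
#' @return A detrended `norm_traj` covering the interior frames only, with
#'   the kernel stored in `$ma_weights`.
#' @export
moving_average_detrend <- function(traj, window_h = 24, frame_dt = 0.5) {
  stopifnot(inherits(traj, "norm_traj"))
  w <- as.integer(round(window_h / frame_dt))
  kw <- ma_weights(w)
  half <- (length(kw) - 1L) %/% 2L
  L <- ncol(traj$mat)
  if (L <= length(kw)) stop("series shorter than the detrending window")
  keep <- (half + 1L):(L - half)
  trend <- t(apply(traj$mat, 1, function(x)
    as.numeric(stats::filter(x, kw, sides = 2))))[, keep, drop = FALSE]
  out <- traj
  out$mat <- traj$mat[, keep, drop = FALSE] - trend
  out$frames <- traj$frames[keep]
  out$detrended <- TRUE
  out$ma_weights <- kw
  out
}

#' Quality-control filter for cell trajectories
#'
#' Removes cells whose traces look mistracked: missing frames, isolated
#' spikes beyond a robust threshold, or dead/flat traces.
#'
#' @param traj a `norm_traj`.
#' @param rules list with elements `min_frames_frac` (default 0.95),
#'   `spike_mad` (spike threshold in MADs from the cell median, default 10),
#'   `drop_flat` (drop zero-variance traces, default TRUE).
#' @return The filtered `norm_traj`; the rejection report (counts per rule
#'   and rejected cell ids) is attached as attribute `"qc_report"`.
#' @export
qc_filter <- function(traj, rules = list()) {
  stopifnot(inherits(traj, "norm_traj"))
  r <- utils::modifyList(list(min_frames_frac = 0.95, spike_mad = 10,
                              drop_flat = TRUE), rules)
  mat <- traj$mat
  frac_present <- rowMeans(is.finite(mat))
  bad_missing <- frac_present < r$min_frames_frac
  med <- apply(mat, 1, stats::median, na.rm = TRUE)
  mad_ <- apply(mat, 1, stats::mad, na.rm = TRUE)
  dev <- abs(mat - med)
  bad_spike <- apply(dev > r$spike_mad * pmax(mad_, .Machine$double.eps), 1,
                     any, na.rm = TRUE) & mad_ > 0
  bad_flat <- if (isTRUE(r$drop_flat))
    apply(mat, 1, function(x) stats::var(x, na.rm = TRUE) == 0) else
      rep(FALSE, nrow(mat))
  bad <- bad_missing | bad_spike | bad_flat
  report <- list(n_in = nrow(mat), n_removed = sum(bad),
                 by_rule = c(missing_frames = sum(bad_missing),
                             spikes = sum(bad_spike), flat = sum(bad_flat)),
                 removed = rownames(mat)[bad])
  out <- traj
  out$mat <- mat[!bad, , drop = FALSE]
  out$cells <- traj$cells[!bad, , drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Restrict a trajectory set to an analysis window
#'
#' @param traj a `norm_traj`.
#' @param t0_frame,t1_frame first frame (inclusive) and last frame
#'   (exclusive) of the window, in absolute frame units.
#' @return The windowed `norm_traj`.
#' @export
window_frames <- function(traj, t0_frame = 60L, t1_frame = 230L) {
  keep <- traj$frames >= t0_frame & traj$frames < t1_frame
  if (!any(keep)) stop("analysis window is outside the available frames")
  out <- traj
  out$mat <- traj$mat[, keep, drop = FALSE]
  out$frames <- traj$frames[keep]
  out
}
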