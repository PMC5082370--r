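#' Write or read a trajectory table as delimited text
#'
#' The canonical long-format exchange table: one row per (cell, frame)
#' with columns `droplet_id`, `cell_id`, `frame`, `fluorescence`,
#' `rhodamine`, `is_bead`.  Floating point is written with 17 significant
#' digits so tables round-trip losslessly.
#'
#' @param table the trajectory table (data frame).
#' @param path file path (tab-separated, with header).
#' @return `read_trajectory_table()` returns the data frame;
#'   `write_trajectory_table()` returns `path` invisibly.
#' @export
write_trajectory_table <- function(table, path) {
  tab <- table
  for (cl in names(tab))
    if (is.double(tab[[cl]])) tab[[cl]] <- sprintf("%.17g", tab[[cl]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Default analysis configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_droplets,loading_mean,max_a droplet layout settings.
#' @param t_end,frame_dt acquisition grid (hours).
#' @param window_h detrending window (hours).
#' @param t0_frame,t1_frame spectral/phase analysis window (frames).
#' @param source trajectory generator for the simulation stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_droplets = 400, loading_mean = 1.2,
                            max_a = 20, t_end = 240, frame_dt = 0.5,
                            window_h = 24, t0_frame = 60, t1_frame = 230,
                            source = "gillespie") {
  if (is.null(seed) || !is.finite(seed))
    stop("the configuration must fix an explicit seed")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes simulate -> normalize -> detrend -> QC -> periodogram/phase ->
#' variance partition -> synchronization surface, writing every table plus
#' a run manifest to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return Invisible list with all stage outputs (`table`, `traj`,
#'   `summary`, `avg_pgram`, `partition`, `surface`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  layout <- stage("layout", make_layout(cfg$n_droplets, cfg$loading_mean,
                                        cfg$max_a, seed = cfg$seed))
  nm <- noise_model()
  tab <- stage("simulate",
               synthesize_experiment(layout, source = cfg$source, noise = nm,
                                     t_end = cfg$t_end,
                                     frame_dt = cfg$frame_dt,
                                     seed = cfg$seed + 1L))
  traj <- stage("normalize", rhodamine_normalize(tab))
  det <- stage("detrend", moving_average_detrend(traj, cfg$window_h,
                                                 cfg$frame_dt))
  det <- stage("qc", qc_filter(det))
  summ <- stage("spectra", phase_summary(det, cfg$t0_frame, cfg$t1_frame,
                                         cfg$frame_dt))
  win <- window_frames(det, cfg$t0_frame, cfg$t1_frame)
  avg <- average_periodogram(periodogram(win, cfg$frame_dt))
  bare <- periodogram(win, cfg$frame_dt, normalize = FALSE)
  gain <- detrend_noise_gain(det$ma_weights,
                             n_input = length(traj$frames),
                             window_idx = match(win$frames, det$frames))
  sigma_det2 <- mean(noise_variance(nm, tab$fluorescence) /
                       tab$rhodamine^2)
  part <- stage("partition", {
    tot <- apply(bare$power, 2, stats::var)
    detv <- detector_variance_to_periodogram(gain, sigma_det2,
                                             colMeans(bare$power))$var
    partition_variance(tot, detv)
  })
  surf <- stage("synchrony", icc_surface(det))
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("dropclock")),
                   n_cells = nrow(det$mat),
                   timestamp = format(Sys.time()))
  out <- list(table = tab, traj = det, summary = summ, avg_pgram = avg,
              partition = part, surface = surf, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_table(tab, file.path(out_dir, "trajectories.tsv"))
    utils::write.table(summ, file.path(out_dir, "phase_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(freq = avg$freq, period = avg$period, mean = avg$mean,
                 var = avg$var),
      file.path(out_dir, "average_periodogram.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(part),
                       file.path(out_dir, "variance_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    surf_long <- data.frame(
      a = rep(surf$a, times = length(surf$frames)),
      frame = rep(surf$frames, each = length(surf$a)),
      icc = as.numeric(surf$icc),
      n_droplets = rep(surf$n_droplets, times = length(surf$frames)))
    utils::write.table(surf_long, file.path(out_dir, "icc_surface.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(out)
}

#' Small deterministic fixtures for examples and tests
#'
#' @param seed integer seed.
#' @return List with `icc_example` (two 2-cell droplets whose ICC is
#'   35/45), `two_tone` (a two-sinusoid series with 2:1 amplitudes),
#'   `bead_table` (six-level bead experiment with known noise
#'   coefficients) and `bead_noise` (the embedded [noise_model()]).
#' @export
make_fixtures <- function(seed = 1L) {
  nm <- noise_model(c0 = 1, c1 = 0.01, c2 = 1e-5, bleach_rate = 0,
                    excitation_cv = 0)
  tt <- seq(0, 84.5, by = 0.5)  # L = 170 frames: grid periods 85/l hours
  list(icc_example = rbind(c(1, 2), c(3, 4)),
       two_tone = 2 * sin(2 * pi * tt / 21.25) + 1 * sin(2 * pi * tt / 8.5),
       bead_table = synthesize_beads(20, c(50, 100, 200, 400, 800, 1600),
                                     noise = nm, t_end = 120, seed = seed),
       bead_noise = nm)
}
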