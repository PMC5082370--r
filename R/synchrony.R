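#' Intraclass correlation from one balanced droplet snapshot
#'
#' One-way variance-components estimator for cells grouped by droplets at a
#' single time point.  With `n` droplets of exactly `a` cells,
#' `SS_B = a * sum_i (Xbar_i - Xbar)^2`, `SS_W = sum_ij (X_ij - Xbar_i)^2`,
#' `EMS_B = SS_B/(n-1)`, `EMS_W = SS_W/(n(a-1))` and
#' `ICC = (EMS_B - EMS_W) / (EMS_B + (a-1) EMS_W)`, the sample estimator of
#' the within-droplet correlation rho obtained by equating the mean squares
#' to their expectations `sigma^2 (1 + (a-1) rho)` and `sigma^2 (1 - rho)`.
#'
#' @param x an `n x a` matrix: droplet i in row i, its `a` cells in columns.
#' @return List with `icc`, `ems_b`, `ems_w`, `n`, `a`.
#' @examples
#' icc(rbind(c(1, 2), c(3, 4)))$icc  # 3.5/4.5
#' @export
icc <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); a <- ncol(x)
  if (n < 2 || a < 2) stop("icc needs at least 2 droplets of at least 2 cells")
  if (anyNA(x)) stop("icc needs a balanced, complete snapshot")
  xbar_i <- rowMeans(x)
  xbar <- mean(x)
  ss_b <- a * sum((xbar_i - xbar)^2)
  ss_w <- sum((x - xbar_i)^2)
  if (ss_b + ss_w == 0) {
    out <- list(icc = NA_real_, ems_b = 0, ems_w = 0, n = n, a = a)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ems_b <- ss_b / (n - 1)
  ems_w <- ss_w / (n * (a - 1))
  list(icc = (ems_b - ems_w) / (ems_b + (a - 1) * ems_w),
       ems_b = ems_b, ems_w = ems_w, n = n, a = a)
}

# Split a trajectory set into exact-size droplet strata:
# list over a of list(mat = cells x frames, droplet = droplet id per cell)
droplet_strata <- function(traj) {
  stopifnot(inherits(traj, "norm_traj"))
  sizes <- table(traj$cells$droplet_id)
  out <- list()
  for (a in sort(unique(as.integer(sizes)))) {
    drops <- names(sizes)[sizes == a]
    sel <- traj$cells$droplet_id %in% drops
    out[[as.character(a)]] <- list(
      a = a,
      droplet = traj$cells$droplet_id[sel],
      mat = traj$mat[sel, , drop = FALSE])
  }
  out
}

#' ICC synchronization surface over droplet size and time
#'
#' For every droplet size `a >= 2` with at least `min_droplets` droplets of
#' exactly `a` cells, computes [icc()] on the single-time-point snapshot at
#' every frame.
#'
#' @param traj a `norm_traj` with droplet assignments.
#' @param min_droplets minimum droplets per stratum (default 2).
#' @return An `icc_surface`: list with `a` (droplet sizes), `frames`,
#'   `icc` (size x frame matrix, `NA` where undefined) and `n_droplets`
#'   per size.
#' @export
icc_surface <- function(traj, min_droplets = 2) {
  strata <- droplet_strata(traj)
  strata <- Filter(function(s) s$a >= 2 &&
                     length(unique(s$droplet)) >= min_droplets, strata)
  a_sizes <- vapply(strata, `[[`, 0L, "a")
  surf <- matrix(NA_real_, length(strata), ncol(traj$mat),
                 dimnames = list(a_sizes, traj$frames))
  nd <- integer(length(strata))
  for (k in seq_along(strata)) {
    s <- strata[[k]]
    ord <- order(s$droplet)
    m <- s$mat[ord, , drop = FALSE]
    nd[k] <- length(unique(s$droplet))
    for (j in seq_len(ncol(m))) {
      snap <- matrix(m[, j], nrow = nd[k], ncol = s$a, byrow = TRUE)
      val <- icc(snap)
      surf[k, j] <- val$icc
    }
  }
  structure(list(a = as.integer(a_sizes), frames = traj$frames, icc = surf,
                 n_droplets = stats::setNames(nd, a_sizes)),
            class = "icc_surface")
}

#' @export
print.icc_surface <- function(x, ...) {
  cat("icc_surface: droplet sizes", paste(x$a, collapse = ", "),
      "over", length(x$frames), "frames\n")
  invisible(x)
}

#' Strangers-resampling null for the ICC surface
#'
#' For every cell in every multi-cell droplet and at every time point, the
#' fluorescence value is replaced (sampling with replacement) by the value
#' of a randomly chosen singleton cell at the same time point, destroying
#' any within-droplet communication signal while preserving the marginal
#' distribution.  The surface is recomputed `n_reps` times.
#'
#' @param traj a `norm_traj`.
#' @param n_reps number of resampling replicates (default 20).
#' @param seed integer seed.
#' @param min_droplets passed to [icc_surface()].
#' @return List of `n_reps` `icc_surface` objects, with the replicate-mean
#'   surface in attribute `"mean_surface"`.
#' @export
strangers_control <- function(traj, n_reps = 20, seed = 1L, min_droplets = 2) {
  stopifnot(inherits(traj, "norm_traj"))
  sizes <- table(traj$cells$droplet_id)
  singles <- names(sizes)[sizes == 1]
  if (!length(singles)) stop("strangers control needs singleton cells in the pool")
  pool <- traj$cells$droplet_id %in% singles
  multi <- !pool
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tr <- traj
    for (j in seq_len(ncol(tr$mat))) {
      draw <- sample(which(pool), sum(multi), replace = TRUE)
      tr$mat[multi, j] <- traj$mat[draw, j]
    }
    reps[[r]] <- icc_surface(tr, min_droplets = min_droplets)
  }
  msurf <- reps[[1]]
  if (n_reps > 1) {
    acc <- Reduce(`+`, lapply(reps, function(s) s$icc))
    msurf$icc <- acc / n_reps
  }
  attr(reps, "mean_surface") <- msurf
  reps
}

#' Garcia-Ojalvo synchrony ratio per droplet
#'
#' Variance over time of the within-droplet mean trajectory divided by the
#' mean over cells of each cell's variance over time.  1 for identical
#' trajectories, about `1/a` for independent cells, 0 for exactly
#' cancelling (antiphase) trajectories.
#'
#' @param traj a `norm_traj`.
#' @param min_frames minimum frames required (default 10).
#' @return Data frame with `droplet_id`, `a`, `R`.
#' @export
garcia_ojalvo_R <- function(traj, min_frames = 10) {
  stopifnot(inherits(traj, "norm_traj"), ncol(traj$mat) >= min_frames)
  drops <- unique(traj$cells$droplet_id[duplicated(traj$cells$droplet_id)])
  out <- lapply(drops, function(d) {
    m <- traj$mat[traj$cells$droplet_id == d, , drop = FALSE]
    denom <- mean(apply(m, 1, stats::var))
    R <- if (denom == 0) NA_real_ else stats::var(colMeans(m)) / denom
    data.frame(droplet_id = d, a = nrow(m), R = R)
  })
  do.call(rbind, out)
}

#' Kuramoto order parameter per droplet-size stratum
#'
#' Time average of the modulus of the mean unit phasor
#' `|mean_j exp(i phi_j(t))|` within each droplet, averaged within each
#' exact-size stratum.
#'
#' @param phases cells x frames matrix of instantaneous phases in radians.
#' @param droplet_id droplet assignment per cell (length `nrow(phases)`).
#' @return Data frame with `a`, `K` (stratum mean), `n_droplets`.
#' @export
kuramoto_order <- function(phases, droplet_id) {
  stopifnot(nrow(phases) == length(droplet_id))
  drops <- unique(droplet_id)
  per_drop <- lapply(drops, function(d) {
    m <- phases[droplet_id == d, , drop = FALSE]
    z <- colMeans(exp(1i * m))
    data.frame(droplet_id = d, a = nrow(m), K = mean(Mod(z)))
  })
  per_drop <- do.call(rbind, per_drop)
  agg <- stats::aggregate(K ~ a, per_drop, mean)
  agg$n_droplets <- as.integer(table(per_drop$a)[as.character(agg$a)])
  agg
}

#' Regress one ICC surface on another
#'
#' Least-squares fit of `y = m x + b_a`: a common slope and a separate
#' intercept for every droplet size `a`, over all (a, frame) cells defined
#' in both surfaces.  Also reports each size's mean ICC of `y` with twice
#' its standard error.
#'
#' @param y,x `icc_surface` objects on matching strata/frames.
#' @param min_points minimum defined points for a stratum to enter the fit.
#' @return List with `slope`, `intercepts` (named by `a`), `r_squared`,
#'   `slope_se`, and `by_a` (data frame: `a`, `mean_icc`, `two_se`, `n`).
#' @export
surface_regression <- function(y, x, min_points = 3) {
  stopifnot(inherits(y, "icc_surface"), inherits(x, "icc_surface"))
  common_a <- intersect(y$a, x$a)
  rows <- list()
  for (a in common_a) {
    yi <- y$icc[match(a, y$a), match(x$frames, y$frames)]
    xi <- x$icc[match(a, x$a), ]
    ok <- is.finite(yi) & is.finite(xi)
    if (sum(ok) < min_points) {
      warning("stratum a = ", a, " dropped (fewer than ", min_points,
              " defined points)")
      next
    }
    rows[[as.character(a)]] <- data.frame(a = a, y = yi[ok], x = xi[ok])
  }
  if (!length(rows)) stop("no strata with enough overlapping points")
  dat <- do.call(rbind, rows)
  dat$a <- factor(dat$a)
  fit <- stats::lm(y ~ 0 + a + x, data = dat)
  co <- stats::coef(fit)
  icpt <- co[grep("^a", names(co))]
  names(icpt) <- sub("^a", "", names(icpt))
  by_a <- do.call(rbind, lapply(split(dat, dat$a), function(g)
    data.frame(a = as.integer(as.character(g$a[1])),
               mean_icc = mean(g$y),
               two_se = 2 * stats::sd(g$y) / sqrt(nrow(g)),
               n = nrow(g))))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((dat$y - mean(dat$y))^2)
  sm <- suppressWarnings(summary(fit))  # exact fits trip summary.lm
  list(slope = unname(co["x"]),
       slope_se = sm$coefficients["x", "Std. Error"],
       intercepts = icpt,
       r_squared = 1 - rss / tss,
       by_a = by_a)
}

#' Period statistics versus droplet size
#'
#' Mean and variance of per-cell periods (primary and secondary
#' periodogram peaks) within each exact droplet size, with Spearman rank
#' tests of each column against droplet size.
#'
#' @param summary_df data frame with columns `droplet_id`, `period`,
#'   `period2` as returned by [phase_summary()], or a precomputed per-size
#'   table via `by_size`.
#' @param layout optional [make_layout()] result giving `cells_per_droplet`;
#'   if omitted, sizes are taken from `droplet_id` multiplicities.
#' @return List with `table` (per `a`: mean/variance of primary and
#'   secondary period, `n_cells`) and `spearman` (data frame of `rho`,
#'   `p_value` per column).
#' @export
period_vs_droplet_size <- function(summary_df, layout = NULL) {
  df <- summary_df
  size_of <- if (!is.null(layout))
    stats::setNames(layout$cells_per_droplet, layout$droplet_id)
  else table(df$droplet_id)
  df$a <- as.integer(size_of[as.character(df$droplet_id)])
  groups <- split(df, df$a)
  tab <- do.call(rbind, lapply(groups, function(g) {
    if (nrow(g) < 2) return(NULL)
    data.frame(a = g$a[1],
               mean_period = mean(g$period, na.rm = TRUE),
               var_period = stats::var(g$period, na.rm = TRUE),
               mean_period2 = mean(g$period2, na.rm = TRUE),
               var_period2 = stats::var(g$period2, na.rm = TRUE),
               n_cells = nrow(g))
  }))
  rownames(tab) <- NULL
  sp <- do.call(rbind, lapply(
    c("mean_period", "var_period", "mean_period2", "var_period2"),
    function(cl) {
      ok <- is.finite(tab[[cl]])
      s <- spearman_cor(tab$a[ok], tab[[cl]][ok])
      data.frame(column = cl, rho = s$rho, p_value = s$p_value)
    }))
  list(table = tab, spearman = sp)
}
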