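# Wrap an SSA ensemble matrix (cells x frames of the observed species)
# into a norm_traj so the standard preprocessing/spectral chain applies.
ssa_matrix_to_ntraj <- function(mat, droplet_id = NULL) {
  n <- nrow(mat)
  cells <- data.frame(cell_id = rownames(mat) %||% paste0("cell", seq_len(n)),
                      droplet_id = droplet_id %||% paste0("d", seq_len(n)))
  structure(list(mat = `dimnames<-`(mat, list(cells$cell_id,
                                              seq_len(ncol(mat)) - 1L)),
                 frames = seq_len(ncol(mat)) - 1L, cells = cells,
                 normalized = TRUE, detrended = FALSE, ma_weights = NULL),
            class = "norm_traj")
}

#' Expected average periodogram under a clock parameter vector
#'
#' Simulates `n_sim` detection-free single-cell trajectories under the
#' stochastic clock with parameters `theta`, detrends them with the
#' standard 24-h moving average, restricts to the analysis window, and
#' returns the cell-averaged normalized periodogram.  With a fixed `seed`
#' the Monte Carlo noise is common across calls (common random numbers),
#' which keeps chi-squared differences between nearby parameter vectors
#' smooth during Metropolis fitting.
#'
#' @param theta clock parameter vector (see [clock_default_theta()]).
#' @param n_sim number of simulated cells.
#' @param t_end,frame_dt simulation grid in hours.
#' @param seed integer seed.
#' @param t0_frame,t1_frame analysis window in frames.
#' @param obs_species observed species.
#' @return An `avg_periodogram`.
#' @export
model_expected_periodogram <- function(theta, n_sim = 128, t_end = 240,
                                       frame_dt = 0.5, seed = 1L,
                                       t0_frame = 60, t1_frame = 230,
                                       obs_species = "prot_ccg2") {
  net <- clock_network(theta)
  mat <- gillespie_ensemble(net, n_sim, t_end, frame_dt, seed = seed,
                            obs_species = obs_species)
  tr <- ssa_matrix_to_ntraj(mat)
  tr <- moving_average_detrend(tr, frame_dt = frame_dt)
  tr <- window_frames(tr, t0_frame, t1_frame)
  average_periodogram(periodogram(tr, frame_dt = frame_dt))
}

#' Chi-squared criterion between observed and model average periodograms
#'
#' `chi2 = sum_l (Pbar_obs(f_l) - Pbar_model(f_l))^2 / sigma_l^2` over the
#' observable frequencies, with `sigma_l^2` the per-frequency total
#' variance of the observed cell-averaged periodogram.
#'
#' @param observed,model `avg_periodogram` objects on the same grid.
#' @param variances per-frequency variances of the observed mean (defaults
#'   to `observed$var / observed$n_cells`).
#' @param n_constraints constraints to subtract from the frequency count
#'   when reporting df (default 0).
#' @return List with `chi2`, `df`, `p_value`.
#' @export
chi2_criterion <- function(observed, model, variances = NULL,
                           n_constraints = 0) {
  stopifnot(inherits(observed, "avg_periodogram"),
            inherits(model, "avg_periodogram"))
  if (length(observed$freq) != length(model$freq) ||
      max(abs(observed$freq - model$freq)) > 1e-10)
    stop("observed and model periodograms are on different frequency grids")
  v <- variances %||% (observed$var / observed$n_cells)
  if (any(v <= 0)) stop("zero variance at an included frequency")
  chi2 <- sum((observed$mean - model$mean)^2 / v)
  df <- length(observed$freq) - n_constraints
  list(chi2 = chi2, df = df, p_value = chi2_sf(chi2, df))
}

#' Metropolis ensemble fit of the clock model
#'
#' Random-walk Metropolis over selected clock parameters using the
#' chi-squared periodogram criterion: at each step one free parameter is
#' perturbed (log-normal proposal for log-scale parameters), the expected
#' periodogram is re-simulated, and the proposal is accepted with
#' probability `min(1, exp(-delta_chi2 / (2 * temperature)))`.  The
#' chi-squared surface is itself a Monte Carlo estimate; common random
#' numbers (a fixed simulation seed, refreshed every `refresh_every`
#' steps) keep it coherent between proposals, a pragmatic deviation from
#' exact pseudo-marginal MCMC.
#'
#' @param init_theta initial parameter vector.
#' @param criterion either a function `theta -> chi2`, or a list with the
#'   observed `avg_periodogram` (`$observed`) and optional `$variances`,
#'   in which case chi-squared comes from [model_expected_periodogram()]
#'   and [chi2_criterion()].
#' @param n_steps number of proposals.
#' @param proposal_scales named vector of proposal standard deviations
#'   (log scale); names pick the free parameters.
#' @param temperature Metropolis temperature (default 1).
#' @param seed integer seed.
#' @param n_sim,t_end simulation settings when `criterion` is a target
#'   periodogram.
#' @param refresh_every refresh the common-random-number seed every this
#'   many steps (default `Inf`: never).
#' @return An `ensemble_chain`: data frame with `step`, `chi2`,
#'   `accepted`, and one column per free parameter; acceptance rate in
#'   attribute `"acceptance_rate"`.
#' @export
metropolis_fit <- function(init_theta, criterion, n_steps = 2000,
                           proposal_scales, temperature = 1, seed = 1L,
                           n_sim = 128, t_end = 240,
                           refresh_every = Inf) {
  stopifnot(n_steps >= 1, length(proposal_scales) >= 1,
            !is.null(names(proposal_scales)))
  free <- names(proposal_scales)
  theta <- init_theta
  set.seed(seed)
  sim_seed <- sample.int(.Machine$integer.max, 1)
  chi2_of <- if (is.function(criterion)) {
    function(th) criterion(th)
  } else {
    obs <- criterion$observed
    # default denominator: variance of the observed mean plus the Monte
    # Carlo variance of the simulated model mean (n_sim cells per proposal)
    vr <- criterion$variances %||%
      (obs$var / obs$n_cells + obs$var / n_sim)
    function(th) {
      mod <- try(model_expected_periodogram(th, n_sim = n_sim, t_end = t_end,
                                            seed = sim_seed), silent = TRUE)
      if (inherits(mod, "try-error")) return(Inf)
      chi2_criterion(obs, mod, variances = vr)$chi2
    }
  }
  cur <- chi2_of(theta)
  out <- matrix(NA_real_, n_steps, 2 + length(free),
                dimnames = list(NULL, c("chi2", "accepted", free)))
  n_acc <- 0
  for (s in seq_len(n_steps)) {
    if (is.finite(refresh_every) && s %% refresh_every == 0) {
      sim_seed <- sample.int(.Machine$integer.max, 1)
      cur <- chi2_of(theta)
    }
    p <- free[sample.int(length(free), 1)]
    prop <- theta
    prop[p] <- prop[p] * exp(stats::rnorm(1, 0, proposal_scales[p]))
    cand <- chi2_of(prop)
    if (stats::runif(1) < exp(-(cand - cur) / (2 * temperature))) {
      theta <- prop
      cur <- cand
      n_acc <- n_acc + 1
      out[s, "accepted"] <- 1
    } else out[s, "accepted"] <- 0
    out[s, "chi2"] <- cur
    out[s, free] <- theta[free]
  }
  chain <- data.frame(step = seq_len(n_steps), out)
  class(chain) <- c("ensemble_chain", class(chain))
  attr(chain, "acceptance_rate") <- n_acc / n_steps
  attr(chain, "temperature") <- temperature
  attr(chain, "seed") <- seed
  chain
}

#' Independent phase-based validation of a fitted clock model
#'
#' Compares the distribution of observed per-cell phases with phases of
#' trajectories simulated under the model, after subtracting each sample's
#' mean (phase is not used in the periodogram fit, so this is an
#' independent check).
#'
#' @param data_phases,model_phases numeric vectors of per-cell phases in
#'   cycles (each of length >= 20).
#' @return List with `D` and `p_value` from the two-sample
#'   Kolmogorov-Smirnov test on the centered samples.
#' @export
validate_phase_distribution <- function(data_phases, model_phases) {
  if (length(data_phases) < 20 || length(model_phases) < 20)
    stop("need at least 20 phases per sample")
  ks_2sample(data_phases, model_phases, center = TRUE)
}
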