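#' Parameters of the mean-field quorum-sensing droplet model
#'
#' Deterministic model of `a` coupled cellular clocks sharing one
#' instantaneously mixed external signal pool.  Each cell runs the
#' deterministic mirror of the stochastic clock network (mean-field rate
#' equations with gene-occupancy fractions).  A clock-controlled gene
#' product drives synthesis of an intracellular signaling molecule `S_j`
#' which exchanges with the shared external pool `S_e`; the signal
#' sequesters the white-collar proteins, slowing WCC formation and closing
#' a coupling negative-feedback loop:
#' \deqn{dS_j/dt = k_{S1} s_{scale} [CCG]_j - \eta (S_j - S^e) - D_9 S_j}
#' \deqn{dS^e/dt = \eta_{ext} \sum_j (S_j - S^e) - D_{10} S^e}
#' and WCC formation proceeds at rate
#' `k_bind * max(WC1 - C2*S_j, 0) * max(WC2 - C4*S_j, 0)` (the
#' sequestration terms are clipped at zero).  The per-droplet volume ratio
#' of the exchange is folded into `eta_ext`.
#'
#' @param a cells per droplet (>= 1).
#' @param D2 basal decay of the signal-producing clock-controlled protein
#'   (1/h).
#' @param eta cell/pool signal exchange rate (1/h).
#' @param eta_ext pool-side exchange rate, volume ratio absorbed (1/h).
#' @param D9 intracellular signal decay (1/h).
#' @param D10 external signal decay (1/h).
#' @param C2,C4 sequestration coefficients for WC-1 and WC-2.
#' @param k_S1 signal production coefficient.
#' @param s_scale production normalization mapping molecule counts of the
#'   clock output onto the signal concentration scale.
#' @param clock_theta parameter vector of the within-cell clock.
#' @return A `quorum_params` list.
#' @export
quorum_params <- function(a = 4, D2 = 1e-4, eta = 100, eta_ext = 1.44,
                          D9 = 26, D10 = 4, C2 = 0.8, C4 = 0.8,
                          k_S1 = 5e9, s_scale = 1e-8,
                          clock_theta = clock_default_theta()) {
  p <- list(a = as.integer(a), D2 = D2, eta = eta, eta_ext = eta_ext,
            D9 = D9, D10 = D10, C2 = C2, C4 = C4, k_S1 = k_S1,
            s_scale = s_scale, clock_theta = clock_theta)
  rates <- unlist(p[c("D2", "eta", "eta_ext", "D9", "D10", "k_S1")])
  if (any(rates < 0) || p$a < 1) stop("rates must be >= 0 and a >= 1")
  structure(p, class = "quorum_params")
}

# species order of the per-cell clock block (mirrors clock_network)
quorum_species <- c("gene_frq", "mrna_frq", "prot_frq",
                    "gene_wc1", "mrna_wc1", "prot_wc1", "prot_wc2", "wcc",
                    "gene_ccg2", "mrna_ccg2", "prot_ccg2", "signal")

quorum_rhs <- function(t, y, p) {
  a <- p$a
  th <- p$th
  ns <- length(quorum_species)
  ym <- matrix(pmax(y[seq_len(a * ns)], 0), nrow = ns)
  Se <- max(y[a * ns + 1], 0)
  d <- matrix(0, ns, a)
  gf <- ym[1, ]; Mf <- ym[2, ]; Pf <- ym[3, ]
  gw <- ym[4, ]; Mw <- ym[5, ]; Pw <- ym[6, ]
  W2 <- ym[7, ]; C <- ym[8, ]
  gc_ <- ym[9, ]; Mc <- ym[10, ]; Pc <- ym[11, ]
  S <- ym[12, ]
  hill <- function(x, K, h) x^h / (K^h + x^h)
  # gene occupancy fractions
  d[1, ] <- th$gon_frq * hill(C, th$K_frq, th$h_frq) * (1 - gf) -
    th$goff_frq * gf
  d[2, ] <- th$km_frq * gf - th$dm_frq * Mf
  d[3, ] <- th$kp_frq * Mf - th$dp_frq * Pf
  d[4, ] <- th$gon_wc1 * (1 - gw) - th$goff_wc1 * gw
  d[5, ] <- th$km_wc1 * gw - th$dm_wc1 * Mw
  # WCC formation with signal sequestration of WC-1 and WC-2
  form <- th$k_bind * pmax(Pw - p$C2 * S, 0) * pmax(W2 - p$C4 * S, 0)
  d[6, ] <- th$kp_wc1 * Mw - th$dp_wc1 * Pw - form
  d[7, ] <- th$k_wc2 - th$d_wc2 * W2 - form
  d[8, ] <- form - th$d_wcc * C - th$k_inact * Pf * C
  d[9, ] <- th$gon_ccg * hill(C, th$K_ccg, th$h_ccg) * (1 - gc_) -
    th$goff_ccg * gc_
  d[10, ] <- th$km_ccg * gc_ - th$dm_ccg * Mc
  d[11, ] <- th$kp_ccg * Mc - th$dp_ccg * Pc - p$D2 * Pc
  d[12, ] <- p$k_S1 * p$s_scale * Pc - p$eta * (S - Se) - p$D9 * S
  dSe <- p$eta_ext * sum(S - Se) - p$D10 * Se
  list(c(as.numeric(d), dSe))
}

#' Default initial state of a quorum droplet
#'
#' @param params a [quorum_params()].
#' @param jitter_cv lognormal coefficient of variation applied per cell to
#'   the mRNA/protein species (0 = identical cells).
#' @param phase_jitter_h cell-to-cell phase dispersion: each cell starts
#'   from the uncoupled limit cycle at a uniformly drawn offset in
#'   `[0, phase_jitter_h)` hours (0 = identical phases).  Amplitude jitter
#'   alone barely perturbs the oscillator's phase, so this is the natural
#'   way to emulate desynchronized cells.
#' @param seed integer seed for the jitter.
#' @return Numeric state vector (per-cell species blocks, then the shared
#'   external signal).
#' @export
quorum_init <- function(params, jitter_cv = 0, phase_jitter_h = 0,
                        seed = 1L) {
  th <- as.list(params$clock_theta)
  base <- c(gene_frq = th$x0_gene, mrna_frq = th$x0_mrna_frq,
            prot_frq = th$x0_prot_frq, gene_wc1 = th$x0_gene,
            mrna_wc1 = th$x0_mrna_wc1, prot_wc1 = th$x0_prot_wc1,
            prot_wc2 = th$x0_prot_wc2, wcc = th$x0_wcc,
            gene_ccg2 = th$x0_gene, mrna_ccg2 = th$x0_mrna_ccg2,
            prot_ccg2 = th$x0_prot_ccg2, signal = 0)
  set.seed(seed)
  if (phase_jitter_h > 0) {
    # relax one uncoupled cell onto its limit cycle, then read states at
    # per-cell phase offsets
    p1 <- params
    p1$a <- 1L
    p1$eta <- 0; p1$eta_ext <- 0; p1$k_S1 <- 0
    p1$th <- as.list(params$clock_theta)
    burn <- 240
    times <- seq(0, burn + phase_jitter_h, by = 0.25)
    sol <- deSolve::ode(y = c(unlist(base), 0), times = times,
                        func = quorum_rhs, parms = p1,
                        method = "lsoda", rtol = 1e-6, atol = 1e-8)
    off <- stats::runif(params$a, 0, phase_jitter_h)
    y <- as.numeric(t(vapply(off, function(o) {
      sol[which.min(abs(times - (burn + o))), 1 + seq_along(base)]
    }, numeric(length(base)))))
  } else {
    y <- rep(unlist(base), params$a)
  }
  if (jitter_cv > 0) {
    sdl <- sqrt(log(1 + jitter_cv^2))
    jit <- exp(stats::rnorm(length(y), -sdl^2 / 2, sdl))
    # leave gene occupancies and the signal alone
    keep <- rep(quorum_species %in% c("gene_frq", "gene_wc1", "gene_ccg2",
                                      "signal"), params$a)
    jit[keep] <- 1
    y <- y * jit
  }
  pmax(c(y, 0), 0)
}

#' Simulate one quorum-sensing droplet
#'
#' Integrates the coupled clock/signal system with an adaptive implicit
#' solver (relative tolerance 1e-6); states are clipped at zero inside the
#' right-hand side, keeping all concentrations nonnegative.
#'
#' @param params a [quorum_params()].
#' @param t_end,frame_dt output grid in hours.
#' @param init initial state (default [quorum_init()]).
#' @return A `quorum_traj`: list with `times`, `state` (deSolve matrix),
#'   `ccg` (a cells x frames matrix of the clock output), `signal`
#'   (cells x frames), `external` (vector).
#' @export
simulate_droplet <- function(params, t_end = 240, frame_dt = 0.5,
                             init = quorum_init(params)) {
  stopifnot(inherits(params, "quorum_params"))
  if (any(init < 0)) stop("initial state must be nonnegative")
  p <- params
  p$th <- as.list(params$clock_theta)
  times <- seq(0, t_end, by = frame_dt)
  sol <- deSolve::ode(y = init, times = times, func = quorum_rhs, parms = p,
                      method = "lsoda", rtol = 1e-6, atol = 1e-8)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ", max(sol[, 1]))
  st <- sol[, -1, drop = FALSE]
  st[st < 0 & st > -1e-8] <- 0
  if (any(st < -1e-6)) stop("negative state beyond tolerance")
  ns <- length(quorum_species)
  pick <- function(name) {
    idx <- (seq_len(params$a) - 1) * ns + match(name, quorum_species)
    t(st[, idx, drop = FALSE])
  }
  structure(list(times = times, state = sol,
                 ccg = pick("prot_ccg2"), signal = pick("signal"),
                 external = st[, ns * params$a + 1]),
            class = "quorum_traj")
}

#' ICC surface predicted by the quorum-sensing model
#'
#' Simulates replicate droplets per droplet size with jittered initial
#' conditions and computes the ICC synchronization surface on the clock
#' output pseudo-fluorescence.
#'
#' @param a_values droplet sizes (only `a >= 2` yields ICC values).
#' @param n_droplets replicate droplets per size (>= 2).
#' @param params a [quorum_params()] (its `a` is overridden).
#' @param t_end,frame_dt grid in hours.
#' @param init_jitter_cv initial-condition amplitude jitter between cells.
#' @param phase_jitter_h initial phase dispersion in hours, see
#'   [quorum_init()].
#' @param seed integer seed.
#' @return An `icc_surface`.
#' @export
model_icc_surface <- function(a_values = 2:4, n_droplets = 4,
                              params = quorum_params(), t_end = 240,
                              frame_dt = 0.5, init_jitter_cv = 0.1,
                              phase_jitter_h = 8, seed = 1L) {
  stopifnot(n_droplets >= 2)
  mats <- list(); cells <- list()
  k <- 0
  for (a in a_values) {
    pa <- params
    pa$a <- as.integer(a)
    for (r in seq_len(n_droplets)) {
      k <- k + 1
      tr <- simulate_droplet(pa, t_end, frame_dt,
                             init = quorum_init(pa, init_jitter_cv,
                                                phase_jitter_h,
                                                seed = seed + 1000 * a + r))
      did <- sprintf("qa%02d_r%02d", a, r)
      mats[[k]] <- tr$ccg
      cells[[k]] <- data.frame(
        cell_id = sprintf("%s_c%02d", did, seq_len(a)),
        droplet_id = did)
    }
  }
  mat <- do.call(rbind, mats)
  cells <- do.call(rbind, cells)
  rownames(mat) <- cells$cell_id
  traj <- structure(list(mat = mat, frames = seq_len(ncol(mat)) - 1L,
                         cells = cells, normalized = TRUE, detrended = FALSE,
                         ma_weights = NULL),
                    class = "norm_traj")
  icc_surface(traj)
}

# CCG trajectories for synthesize_experiment(source = "quorum"):
# one ODE solve per droplet, stacked in layout order.
quorum_ensemble <- function(layout, params, t_end, frame_dt, seed = 1L,
                            init_jitter_cv = 0.1, phase_jitter_h = 8) {
  mats <- vector("list", length(layout$droplet_id))
  for (i in seq_along(layout$droplet_id)) {
    pa <- params
    pa$a <- layout$cells_per_droplet[i]
    tr <- simulate_droplet(pa, t_end, frame_dt,
                           init = quorum_init(pa, init_jitter_cv,
                                              phase_jitter_h,
                                              seed = seed + i))
    mats[[i]] <- tr$ccg
  }
  do.call(rbind, mats)
}
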