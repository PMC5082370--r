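#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates a [reaction_network()] exactly: waiting times are exponential
#' with the total propensity, the firing reaction is chosen with probability
#' proportional to its propensity, and the state is recorded on a regular
#' frame grid using the value immediately preceding each frame time
#' (right-continuous step convention).  If the total propensity reaches
#' zero the state is frozen to `t_end`.
#'
#' @param net a [reaction_network()].
#' @param t_end end time in hours (> 0).
#' @param frame_dt frame spacing in hours (> 0), default 0.5.
#' @param seed integer master seed; runs are reproducible given the seed.
#' @param stream stream index (>= 1); ensembles give each cell its own
#'   stream so results do not depend on simulation order.
#' @return An `ssa_trajectory`: list with `frame_times` (hours) and
#'   `counts`, a species x frame integer matrix.
#' @examples
#' bd <- reaction_network("X", c(X = 0), list(
#'   reaction(prod = c(X = 1), rate = 10),
#'   reaction(react = c(X = 1), rate = 0.1)))
#' tr <- gillespie_run(bd, t_end = 100, frame_dt = 0.5, seed = 1)
#' mean(tr$counts["X", -(1:20)])
#' @export
gillespie_run <- function(net, t_end, frame_dt = 0.5, seed = 1L, stream = 1L) {
  stopifnot(inherits(net, "reaction_network"), t_end > 0, frame_dt > 0)
  m <- ssa_matrices(net)
  out <- .ssa_run_cpp(m$nu_react, m$nu_prod, m$kind, m$rate, m$reg, m$K, m$h,
                      m$x0, t_end, frame_dt, as.double(seed), as.double(stream))
  counts <- t(out)
  rownames(counts) <- net$species
  structure(list(frame_times = seq(0, by = frame_dt,
                                   length.out = ncol(counts)),
                 counts = counts),
            class = "ssa_trajectory")
}

#' Ensemble of independent Gillespie runs
#'
#' Runs `n_cells` independent simulations of the same network.  Each cell
#' draws from its own counter-derived random stream, so the ensemble is
#' deterministic given the master seed and independent of evaluation order.
#'
#' @inheritParams gillespie_run
#' @param n_cells number of independent cells (>= 1).
#' @param obs_species optional species name; if given, returns a
#'   cells x frames matrix of that species only (fast path used by the
#'   ensemble fitter), otherwise a list of `ssa_trajectory` objects.
#' @return List of `ssa_trajectory` or a cells x frames matrix.
#' @export
gillespie_ensemble <- function(net, n_cells, t_end, frame_dt = 0.5, seed = 1L,
                               obs_species = NULL) {
  stopifnot(inherits(net, "reaction_network"), n_cells >= 1,
            t_end > 0, frame_dt > 0)
  m <- ssa_matrices(net)
  if (!is.null(obs_species)) {
    obs <- match(obs_species, net$species)
    if (is.na(obs)) stop("unknown species: ", obs_species)
    res <- .ssa_ensemble_cpp(m$nu_react, m$nu_prod, m$kind, m$rate, m$reg,
                             m$K, m$h, m$x0, as.integer(n_cells), t_end,
                             frame_dt, as.double(seed), obs - 1L)
    dimnames(res) <- list(paste0("cell", seq_len(n_cells)), NULL)
    return(res)
  }
  res <- .ssa_ensemble_cpp(m$nu_react, m$nu_prod, m$kind, m$rate, m$reg,
                           m$K, m$h, m$x0, as.integer(n_cells), t_end,
                           frame_dt, as.double(seed), -1L)
  lapply(res, function(out) {
    counts <- t(out)
    rownames(counts) <- net$species
    structure(list(frame_times = seq(0, by = frame_dt,
                                     length.out = ncol(counts)),
                   counts = counts),
              class = "ssa_trajectory")
  })
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("ssa_trajectory:", nrow(x$counts), "species,",
      ncol(x$counts), "frames, t =", min(x$frame_times), "..",
      max(x$frame_times), "h\n")
  invisible(x)
}
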