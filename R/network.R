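#' Stochastic reaction networks
#'
#' A `reaction_network` holds an ordered species list, integer initial counts,
#' and a list of reactions.  Each reaction has nonnegative integer reactant and
#' product stoichiometries, a rate-law kind, and nonnegative rate constants.
#' Supported rate laws are plain mass action and mass action modulated by a
#' Hill activation or repression term in a single regulator species; the Hill
#' kinds are used for gene on/off switching controlled by a transcription
#' factor, so that gene loci toggle stochastically (transcriptional bursting).
#'
#' @param species character vector of species names (molecule counts).
#' @param x0 named integer vector of initial counts, one per species.
#' @param reactions list of reactions as built by [reaction()].
#' @return An object of class `reaction_network`.
#' @seealso [reaction()], [build_default_clock()], [gillespie_run()]
#' @export
reaction_network <- function(species, x0, reactions) {
  stopifnot(is.character(species), length(species) >= 1, !anyDuplicated(species))
  x0 <- x0[species]
  if (anyNA(x0) || any(x0 < 0) || any(x0 != round(x0)))
    stop("x0 must give a nonnegative integer count for every species")
  for (r in reactions) {
    if (!inherits(r, "ssa_reaction")) stop("reactions must be built with reaction()")
    unknown <- setdiff(c(names(r$react), names(r$prod), r$reg), species)
    if (length(unknown))
      stop("reaction references unknown species: ", paste(unknown, collapse = ", "))
  }
  x0 <- stats::setNames(as.integer(round(x0)), species)
  structure(list(species = species, x0 = x0, reactions = reactions),
            class = "reaction_network")
}

#' Define one reaction of a stochastic network
#'
#' @param react named numeric vector of reactant stoichiometries (may be
#'   empty for a source reaction).
#' @param prod named numeric vector of product stoichiometries.
#' @param rate nonnegative rate constant, units 1/h (scaled by
#'   1/(molecule) per extra reactant molecule).
#' @param kind one of `"mass_action"`, `"hill_act"`, `"hill_rep"`.
#' @param reg regulator species name for the Hill kinds.
#' @param K half-saturation constant (molecules) for the Hill kinds.
#' @param h Hill coefficient.
#' @return An object of class `ssa_reaction`.
#' @export
reaction <- function(react = numeric(), prod = numeric(), rate,
                     kind = c("mass_action", "hill_act", "hill_rep"),
                     reg = NULL, K = NULL, h = NULL) {
  kind <- match.arg(kind)
  chk <- function(v, what) {
    if (length(v) && (any(v < 0) || any(v != round(v))))
      stop(what, " stoichiometries must be nonnegative integers")
    v
  }
  chk(react, "reactant"); chk(prod, "product")
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || !is.finite(rate))
    stop("rate must be a single finite nonnegative number")
  if (kind != "mass_action") {
    if (is.null(reg) || is.null(K) || is.null(h))
      stop("Hill rate laws need reg, K and h")
    stopifnot(K > 0, h > 0)
  }
  structure(list(react = react, prod = prod, rate = rate, kind = kind,
                 reg = reg, K = K, h = h),
            class = "ssa_reaction")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) {
    side <- function(v) if (!length(v)) "0" else
      paste(ifelse(v > 1, paste0(v, " "), ""), names(v), sep = "", collapse = " + ")
    law <- if (r$kind == "mass_action") sprintf("mass_action(k=%g)", r$rate)
      else sprintf("%s(k=%g, reg=%s, K=%g, h=%g)", r$kind, r$rate, r$reg, r$K, r$h)
    cat(" ", side(r$react), "->", side(r$prod), "@", law, "\n")
  }
  invisible(x)
}

kind_code <- c(mass_action = 0L, hill_act = 1L, hill_rep = 2L)

# Flatten a reaction_network into the matrices the C++ simulator consumes.
ssa_matrices <- function(net) {
  ns <- length(net$species)
  nr <- length(net$reactions)
  nu_react <- matrix(0L, nr, ns, dimnames = list(NULL, net$species))
  nu_prod <- matrix(0L, nr, ns, dimnames = list(NULL, net$species))
  kind <- integer(nr); rate <- numeric(nr)
  reg <- integer(nr); K <- numeric(nr); h <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    nu_react[j, names(r$react)] <- as.integer(r$react)
    nu_prod[j, names(r$prod)] <- as.integer(r$prod)
    kind[j] <- kind_code[[r$kind]]
    rate[j] <- r$rate
    reg[j] <- if (is.null(r$reg)) -1L else match(r$reg, net$species) - 1L
    K[j] <- if (is.null(r$K)) 1 else r$K
    h[j] <- if (is.null(r$h)) 1 else r$h
  }
  list(nu_react = nu_react, nu_prod = nu_prod, kind = kind, rate = rate,
       reg = reg, K = K, h = h, x0 = stats::setNames(net$x0, net$species))
}

#' Evaluate all reaction propensities at a state
#'
#' Mass-action propensities use falling-factorial combinatorics in the
#' molecule counts; Hill kinds multiply by the activation or repression term.
#'
#' @param net a [reaction_network()].
#' @param x named nonnegative state vector; defaults to the initial counts.
#' @return Numeric vector of propensities, one per reaction.
#' @export
propensities <- function(net, x = net$x0) {
  m <- ssa_matrices(net)
  x <- if (is.null(names(x))) stats::setNames(as.numeric(x), net$species) else x[net$species]
  vapply(seq_along(net$reactions), function(j) {
    a <- m$rate[j]
    for (s in which(m$nu_react[j, ] > 0)) {
      r <- m$nu_react[j, s]
      a <- a * prod((x[s] - seq_len(r) + 1) / seq_len(r))
    }
    a <- max(a, 0)
    if (m$kind[j] != 0L) {
      xr <- x[m$reg[j] + 1L]
      w <- xr^m$h[j] / (m$K[j]^m$h[j] + xr^m$h[j])
      a <- a * if (m$kind[j] == 1L) w else 1 - w
    }
    unname(a)
  }, numeric(1))
}

# Mean-field (deterministic) right-hand side of a reaction network:
# dx/dt = S' a(x) with plain powers in place of falling factorials.
# Gene on/off states become occupancy fractions in [0, 1].
network_meanfield_rhs <- function(net) {
  m <- ssa_matrices(net)
  S <- t(m$nu_prod - m$nu_react)
  function(t, x, parms = NULL) {
    a <- m$rate
    for (j in seq_along(a)) {
      w <- which(m$nu_react[j, ] > 0)
      for (s in w) a[j] <- a[j] * max(x[s], 0)^m$nu_react[j, s]
      if (m$kind[j] != 0L) {
        xr <- max(x[m$reg[j] + 1L], 0)
        hw <- xr^m$h[j] / (m$K[j]^m$h[j] + xr^m$h[j])
        a[j] <- a[j] * if (m$kind[j] == 1L) hw else 1 - hw
      }
    }
    list(as.numeric(S %*% a))
  }
}

#' Write or read a reaction network as structured text
#'
#' Networks and their parameters round-trip through a human-readable YAML
#' file: species, initial counts, and one entry per reaction.
#'
#' @param net a [reaction_network()].
#' @param path file path.
#' @return `read_network()` returns a [reaction_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  lst <- list(species = as.list(net$x0),
              reactions = lapply(net$reactions, function(r) {
                out <- list(react = as.list(r$react), prod = as.list(r$prod),
                            rate = r$rate, kind = r$kind)
                if (r$kind != "mass_action")
                  out <- c(out, list(reg = r$reg, K = r$K, h = r$h))
                out
              }))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lst <- yaml::read_yaml(path)
  x0 <- unlist(lst$species)
  reactions <- lapply(lst$reactions, function(r)
    reaction(react = unlist(r$react) %||% numeric(),
             prod = unlist(r$prod) %||% numeric(),
             rate = r$rate, kind = r$kind,
             reg = r$reg, K = r$K, h = r$h))
  reaction_network(names(x0), x0, reactions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
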