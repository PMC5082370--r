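#' The default stochastic clock network
#'
#' A minimal transcription-translation negative-feedback clock for a fungal
#' circadian oscillator with bursting gene states.  The white-collar proteins
#' WC-1 and WC-2 dimerize into the activating complex WCC; WCC switches the
#' *frq* and *ccg-2* gene loci on (Hill-type activation), FRQ protein
#' inactivates WCC (closing the negative feedback), and the clock-controlled
#' gene *ccg-2* reports the oscillation: its protein is what a fluorescent
#' recorder driven by the *ccg-2* promoter would measure.  All gene loci
#' toggle on/off stochastically, so transcription occurs in bursts.
#'
#' The default rate constants (see [clock_default_theta()]) are calibrated so
#' that detrended CCG-2 trajectories oscillate with a principal period near
#' 21 h and the time-averaged *ccg-2* mRNA count is of order 1e2
#' molecules/cell.
#'
#' @param theta named parameter vector, see [clock_default_theta()].
#' @return A [reaction_network()] with 14 species (including explicit gene
#'   off states) and 23 reactions.
#' @examples
#' net <- build_default_clock()
#' propensities(net)
#' @export
build_default_clock <- function(theta = clock_default_theta()) {
  clock_network(theta)
}

#' Default clock parameters
#'
#' Returns the calibrated parameter vector for [build_default_clock()],
#' read from the versioned parameter file shipped with the package
#' (`extdata/clock_default.yaml`).  Rates are per hour; `K_*` are molecule
#' counts; `h_*` are Hill coefficients; `x0_*` are initial counts.
#'
#' @return Named numeric vector with a `log_scale` attribute marking the
#'   entries that Metropolis proposals perturb on log scale.
#' @export
clock_default_theta <- function() {
  path <- system.file("extdata", "clock_default.yaml", package = "dropclock")
  prm <- yaml::read_yaml(path)
  theta <- unlist(prm$theta)
  attr(theta, "log_scale") <- names(theta) %in% prm$log_scale
  theta
}

#' Build the clock network for a given parameter vector
#'
#' @param theta named numeric vector with the entries of
#'   [clock_default_theta()].
#' @return A [reaction_network()].
#' @export
clock_network <- function(theta) {
  th <- as.list(theta)
  species <- c("gene_frq_off", "gene_frq", "mrna_frq", "prot_frq",
               "gene_wc1_off", "gene_wc1", "mrna_wc1", "prot_wc1",
               "prot_wc2", "wcc",
               "gene_ccg2_off", "gene_ccg2", "mrna_ccg2", "prot_ccg2")
  x0 <- c(gene_frq_off = 1 - th$x0_gene, gene_frq = th$x0_gene,
          mrna_frq = th$x0_mrna_frq, prot_frq = th$x0_prot_frq,
          gene_wc1_off = 1 - th$x0_gene, gene_wc1 = th$x0_gene,
          mrna_wc1 = th$x0_mrna_wc1,
          prot_wc1 = th$x0_prot_wc1, prot_wc2 = th$x0_prot_wc2,
          wcc = th$x0_wcc,
          gene_ccg2_off = 1 - th$x0_gene, gene_ccg2 = th$x0_gene,
          mrna_ccg2 = th$x0_mrna_ccg2, prot_ccg2 = th$x0_prot_ccg2)
  rx <- list(
    # frq locus: WCC switches the gene on; FRQ is made while it is on
    reaction(react = c(gene_frq_off = 1), prod = c(gene_frq = 1),
             rate = th$gon_frq, kind = "hill_act",
             reg = "wcc", K = th$K_frq, h = th$h_frq),
    reaction(react = c(gene_frq = 1), prod = c(gene_frq_off = 1),
             rate = th$goff_frq),
    reaction(react = c(gene_frq = 1), prod = c(gene_frq = 1, mrna_frq = 1),
             rate = th$km_frq),
    reaction(react = c(mrna_frq = 1), rate = th$dm_frq),
    reaction(react = c(mrna_frq = 1), prod = c(mrna_frq = 1, prot_frq = 1),
             rate = th$kp_frq),
    reaction(react = c(prot_frq = 1), rate = th$dp_frq),
    # wc-1 locus: constitutive bursting
    reaction(react = c(gene_wc1_off = 1), prod = c(gene_wc1 = 1),
             rate = th$gon_wc1),
    reaction(react = c(gene_wc1 = 1), prod = c(gene_wc1_off = 1),
             rate = th$goff_wc1),
    reaction(react = c(gene_wc1 = 1), prod = c(gene_wc1 = 1, mrna_wc1 = 1),
             rate = th$km_wc1),
    reaction(react = c(mrna_wc1 = 1), rate = th$dm_wc1),
    reaction(react = c(mrna_wc1 = 1), prod = c(mrna_wc1 = 1, prot_wc1 = 1),
             rate = th$kp_wc1),
    reaction(react = c(prot_wc1 = 1), rate = th$dp_wc1),
    # WC-2 constitutive; WCC assembly and decay; FRQ inactivates WCC
    reaction(prod = c(prot_wc2 = 1), rate = th$k_wc2),
    reaction(react = c(prot_wc2 = 1), rate = th$d_wc2),
    reaction(react = c(prot_wc1 = 1, prot_wc2 = 1), prod = c(wcc = 1),
             rate = th$k_bind),
    reaction(react = c(wcc = 1), rate = th$d_wcc),
    reaction(react = c(prot_frq = 1, wcc = 1), prod = c(prot_frq = 1),
             rate = th$k_inact),
    # ccg-2 locus: clock output, switched on by WCC
    reaction(react = c(gene_ccg2_off = 1), prod = c(gene_ccg2 = 1),
             rate = th$gon_ccg, kind = "hill_act",
             reg = "wcc", K = th$K_ccg, h = th$h_ccg),
    reaction(react = c(gene_ccg2 = 1), prod = c(gene_ccg2_off = 1),
             rate = th$goff_ccg),
    reaction(react = c(gene_ccg2 = 1), prod = c(gene_ccg2 = 1, mrna_ccg2 = 1),
             rate = th$km_ccg),
    reaction(react = c(mrna_ccg2 = 1), rate = th$dm_ccg),
    reaction(react = c(mrna_ccg2 = 1), prod = c(mrna_ccg2 = 1, prot_ccg2 = 1),
             rate = th$kp_ccg),
    reaction(react = c(prot_ccg2 = 1), rate = th$dp_ccg))
  # single-copy loci: explicit off-state species make on-switches exact
  net <- reaction_network(species, x0, rx)
  net$gene_species <- c("gene_frq", "gene_wc1", "gene_ccg2")
  net
}
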