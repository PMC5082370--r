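# small networks and containers shared across tests

birth_death_net <- function(k = 10, d = 0.1, x0 = 0) {
  reaction_network("X", c(X = x0), list(
    reaction(prod = c(X = 1), rate = k),
    reaction(react = c(X = 1), rate = d)))
}

decay_net <- function(d = 0.2, n0 = 200) {
  reaction_network("X", c(X = n0), list(
    reaction(react = c(X = 1), rate = d)))
}

# wrap a cells x frames matrix as a norm_traj
mat_traj <- function(mat, droplet_id = NULL, frames = seq_len(ncol(mat)) - 1L) {
  n <- nrow(mat)
  ids <- rownames(mat) %||% paste0("c", seq_len(n))
  rownames(mat) <- ids
  structure(list(mat = mat, frames = as.integer(frames),
                 cells = data.frame(cell_id = ids,
                                    droplet_id = droplet_id %||%
                                      paste0("d", seq_len(n))),
                 normalized = TRUE, detrended = FALSE, ma_weights = NULL),
            class = "norm_traj")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# summary of per-droplet-size period statistics used in the rank tests
period_size_table <- function() {
  path <- system.file("extdata", "period_by_droplet_size.tsv",
                      package = "dropclock")
  utils::read.table(path, header = TRUE, sep = "\t")
}
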