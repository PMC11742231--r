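# Synthetic drug-response data with known ground truth.
#
# Emulates the shape of the public drug-sensitivity screens the model targets
# (drugs as SMILES, cell lines as binary feature vectors, one normalized
# response per drug-cell pair) at desk scale, with the response generated by
# a known logistic function of interpretable graph descriptors and cell
# features so that learnability can be tested against a recoverable signal.

# Chain-safe SMILES fragments: each unit is valid at the start, middle or end
# of a linear concatenation (rings close internally; branch atoms carry their
# own parentheses). Heavy-atom counts are recorded so molecule sizes can be
# controlled without parsing.
FRAGMENT_ALPHABET <- tibble::tibble(
  smiles = c("C", "CC", "CCC", "N", "O", "S", "C(C)", "C(F)", "C(Cl)",
             "C(=O)", "C(C)(C)", "c1ccccc1", "c1ccncc1", "c1ccsc1",
             "C1CCCCC1", "C1CCNCC1", "C(=O)N", "C(=O)O", "CO", "CN"),
  n_atoms = c(1L, 2L, 3L, 1L, 1L, 1L, 2L, 2L, 2L,
              2L, 3L, 6L, 6L, 5L,
              6L, 6L, 3L, 3L, 2L, 2L)
)

# Interpretable per-molecule descriptors driving the synthetic ground truth.
#' Graph descriptors of a molecule
#'
#' Eight simple, roughly unit-scaled descriptors of a molecular graph used
#' by the synthetic ground-truth response function: scaled atom and bond
#' counts, aromatic / ring / heteroatom / nitrogen / oxygen fractions and
#' scaled mean degree.
#'
#' @param graph A `gf_molgraph` with its `atoms` table.
#' @return Named numeric vector of length 8.
#' @export
graph_descriptors <- function(graph) {
  a <- graph$atoms
  if (is.null(a)) stop("graph carries no atom table")
  c(
    size = graph$num_atoms / 20,
    bonds = sum(graph$adjacency) / 2 / 20,
    aromatic = mean(a$aromatic),
    ring = mean(a$in_ring),
    hetero = mean(a$symbol != "C"),
    nitrogen = mean(a$symbol == "N"),
    oxygen = mean(a$symbol == "O"),
    degree = mean(a$degree) / 4
  )
}

default_w_graph <- function() {
  c(size = 1.0, bonds = -0.8, aromatic = 1.2, ring = 0.6, hetero = 0.9,
    nitrogen = -1.1, oxygen = -0.5, degree = 0.8)
}

default_w_cell <- function(cell_dim) {
  w <- numeric(cell_dim)
  active <- unique(round(seq(1, cell_dim, length.out = 30L)))
  w[active] <- 0.45 * rep_len(c(1, -1), length(active))
  w
}

random_smiles <- function(fragments, min_atoms, max_atoms) {
  repeat {
    k <- sample.int(6L, 1L)
    idx <- sample.int(nrow(fragments), k, replace = TRUE)
    n <- sum(fragments$n_atoms[idx])
    if (n >= min_atoms && n <= max_atoms) {
      return(paste0(fragments$smiles[idx], collapse = ""))
    }
  }
}

#' Generate a synthetic drug-response dataset with known ground truth
#'
#' Drugs are random small molecules assembled from a curated fragment
#' alphabet (5-30 heavy atoms, always parseable); cell lines are Bernoulli
#' binary feature vectors; the noiseless response is
#' `y* = plogis(w_g . descriptors(graph) + w_c . cellfeatures + bias)` with
#' per-dataset centering of the logit, and the observed response is
#' `y = clip(y* + N(0, noise_sd), 0, 1)`. The generating coefficients are
#' returned so recovery can be tested.
#'
#' @param n_drugs,n_cells Numbers of drugs and cell lines (every pair is
#'   measured).
#' @param cell_dim Length of the binary cell-line vector.
#' @param bernoulli_p Activation probability of each cell feature.
#' @param noise_sd Gaussian noise added on the response scale.
#' @param w_graph,w_cell,bias Ground-truth coefficients; defaults are fixed
#'   patterns independent of the seed.
#' @param fragments Fragment alphabet tibble (`smiles`, `n_atoms`).
#' @param min_atoms,max_atoms Molecule size bounds (heavy atoms).
#' @param seed Seed controlling molecules, cell features and noise.
#' @return A `gf_dataset` list: `drugs` (drug_id, smiles), `cells` (cell_id
#'   + cell_dim binary columns), `responses` (drug_id, cell_id, raw_ic50, y),
#'   and `truth` (`w_graph`, `w_cell`, `bias`, per-drug `descriptors`,
#'   noiseless `y_star`).
#' @examples
#' \donttest{
#' ds <- simulate_drug_response(n_drugs = 5, n_cells = 4, seed = 1)
#' nrow(ds$responses)  # 20
#' }
#' @export
simulate_drug_response <- function(n_drugs = 50L, n_cells = 40L,
                                   cell_dim = 735L, bernoulli_p = 0.2,
                                   noise_sd = 0.05,
                                   w_graph = default_w_graph(),
                                   w_cell = NULL, bias = 0,
                                   fragments = FRAGMENT_ALPHABET,
                                   min_atoms = 5L, max_atoms = 30L,
                                   seed = 1L) {
  stopifnot(n_drugs >= 1L, n_cells >= 1L, cell_dim >= 1L, noise_sd >= 0)
  if (is.null(w_cell)) w_cell <- default_w_cell(cell_dim)
  stopifnot(length(w_cell) == cell_dim, length(w_graph) == 8L)
  set.seed(seed)
  smis <- character(0)
  while (length(smis) < n_drugs) {
    s <- random_smiles(fragments, min_atoms, max_atoms)
    if (!s %in% smis) smis <- c(smis, s)
  }
  drug_ids <- sprintf("drug_%03d", seq_len(n_drugs))
  cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
  C <- matrix(stats::rbinom(n_cells * cell_dim, 1L, bernoulli_p),
              n_cells, cell_dim)
  graphs <- lapply(seq_len(n_drugs),
                   function(i) smiles_to_graph(smis[i], drug_id = drug_ids[i]))
  D <- t(vapply(graphs, graph_descriptors, numeric(8L)))
  drug_part <- as.numeric(D %*% w_graph)
  cell_part <- as.numeric(C %*% w_cell)
  raw <- outer(drug_part, cell_part, `+`) + bias  # n_drugs x n_cells
  raw <- raw - mean(raw)                          # center the logit
  y_star <- stats::plogis(raw)
  noise <- matrix(stats::rnorm(n_drugs * n_cells, 0, noise_sd),
                  n_drugs, n_cells)
  y <- pmin(1, pmax(0, y_star + noise))
  responses <- tibble::tibble(
    drug_id = rep(drug_ids, times = n_cells),
    cell_id = rep(cell_ids, each = n_drugs),
    raw_ic50 = exp(6 * as.numeric(y) - 3),
    y = as.numeric(y)
  )
  cells <- tibble::as_tibble(as.data.frame(C))
  names(cells) <- sprintf("f%03d", seq_len(cell_dim))
  cells <- dplyr::bind_cols(tibble::tibble(cell_id = cell_ids), cells)
  structure(
    list(
      drugs = tibble::tibble(drug_id = drug_ids, smiles = smis),
      cells = cells,
      responses = responses,
      truth = list(w_graph = w_graph, w_cell = w_cell, bias = bias,
                   descriptors = D, y_star = as.numeric(y_star),
                   logit_offset = -mean(outer(drug_part, cell_part, `+`) +
                                          bias)),
      seed = as.integer(seed)
    ),
    class = "gf_dataset"
  )
}

#' @export
print.gf_dataset <- function(x, ...) {
  cat("<gf_dataset> ", nrow(x$drugs), " drugs x ", nrow(x$cells),
      " cell lines = ", nrow(x$responses), " response pairs\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `drugs.csv`, `cells.csv` and `responses.csv` into a directory in
#' the same tabular formats the loaders accept, so the pipeline is closed
#' under its own file formats.
#'
#' @param dataset A `gf_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$drugs, file.path(dir, "drugs.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  invisible(dir)
}
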