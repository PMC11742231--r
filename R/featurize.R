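# SMILES featurization: molecular graphs with per-atom feature vectors, and
# hashed circular fingerprints.
#
# Parsing goes through ChemmineR/ChemmineOB (SMILES -> kekulized SDF). The
# heavy-atom graph keeps hydrogens implicit; H counts are recovered from
# standard-valence arithmetic (verified against an independent cheminformatics
# toolkit in the test suite).

# 43 named elements + a reserved "other" slot; the one-hot over this alphabet
# is the first block of the atom feature vector.
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)

# Bonding capacity of the neutral atom, used to infer implicit hydrogens on
# the kekulized heavy-atom graph: H = capacity + formal charge - bond orders.
VALENCE_TABLE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4, Se = 2, As = 3
)

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (!is.na(i)) v[i] <- 1
  v
}

#' Encode one atom as a binary feature vector
#'
#' Builds the fixed 78-dimensional per-atom descriptor used as node features
#' of the molecular graph: a one-hot over a 44-symbol element alphabet
#' (43 named elements plus a reserved "other" slot), one-hot degree 0-10,
#' one-hot total hydrogen count 0-10, one-hot implicit valence 0-10, and an
#' aromaticity flag. With `extended = TRUE` ten further dimensions are
#' appended: formal charge and radical-electron count as integers, a
#' hybridization one-hot (SP, SP2, SP3, SP3D, SP3D2; all zero when not
#' assigned), a ring-membership flag and a chirality one-hot (R, S; all zero
#' when unassigned).
#'
#' @param atom A list or one-row data frame with fields `symbol`, `degree`,
#'   `num_h`, `implicit_valence`, `aromatic`, and (for the extended form)
#'   `charge`, `radical`, `hybridization`, `in_ring`, `chirality`.
#' @param extended Append the extended descriptor block (default `FALSE`).
#' @return A numeric 0/1 vector of length 78 (88 when extended; the two
#'   integer slots may exceed 1 in exotic species).
#' @examples
#' atom_to_features(list(symbol = "C", degree = 4, num_h = 0,
#'                       implicit_valence = 0, aromatic = FALSE))
#' @export
atom_to_features <- function(atom, extended = FALSE) {
  atom <- as.list(atom)
  stopifnot(!is.null(atom$symbol))
  for (f in c("degree", "num_h", "implicit_valence")) {
    x <- atom[[f]]
    if (is.null(x) || is.na(x) || x < 0) {
      stop("invalid atom descriptor: `", f, "` must be a non-negative count")
    }
    if (x > 10) stop("atom `", f, "` out of supported range 0-10")
  }
  sym <- atom$symbol
  if (!sym %in% ATOM_SYMBOLS) sym <- "other"
  v <- c(
    one_hot(sym, c(ATOM_SYMBOLS, "other")),
    one_hot(atom$degree, 0:10),
    one_hot(atom$num_h, 0:10),
    one_hot(atom$implicit_valence, 0:10),
    as.numeric(isTRUE(atom$aromatic))
  )
  if (extended) {
    v <- c(
      v,
      if (is.null(atom$charge)) 0 else atom$charge,
      if (is.null(atom$radical)) 0 else atom$radical,
      one_hot(atom$hybridization %||% NA,
              c("SP", "SP2", "SP3", "SP3D", "SP3D2")),
      as.numeric(isTRUE(atom$in_ring)),
      one_hot(atom$chirality %||% NA, c("R", "S"))
    )
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_smiles_sdf <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string")
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("could not parse SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  sdf <- sdfset[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) {
    stop("SMILES '", smiles, "' parsed to an empty molecule")
  }
  sdf
}

# Aromatic atoms according to the toolkit's own perception: convert to MOL2,
# whose bond records carry an explicit "ar" type.
ob_aromatic_atoms <- function(smiles, n) {
  mol2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", source = smiles),
    error = function(e) ""
  )
  arom <- logical(n)
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1L]]
  b0 <- which(lines == "@<TRIPOS>BOND")
  if (length(b0) == 1L) {
    k <- b0 + 1L
    while (k <= length(lines) && !startsWith(lines[k], "@")) {
      f <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
      if (length(f) >= 4L && f[4L] == "ar") {
        ij <- as.integer(f[2:3])
        arom[ij[ij <= n]] <- TRUE
      }
      k <- k + 1L
    }
  }
  arom
}

# Atoms lying on a cycle: endpoints of non-bridge edges of the bond graph.
ring_atoms <- function(n, edges) {
  in_ring <- logical(n)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::graph_from_edgelist(edges[, 1:2, drop = FALSE],
                                     directed = FALSE)
    br <- igraph::bridges(g)
    non_bridge <- setdiff(seq_len(nrow(edges)), as.integer(br))
    idx <- unique(as.integer(edges[non_bridge, 1:2]))
    in_ring[idx] <- TRUE
  }
  in_ring
}

sdf_atom_table <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  symbols <- sub("_[0-9]+$", "", rownames(ab))
  # formal charges; ChemmineR's bond accessor needs >= 2 bonds, so fall
  # back to neutral atoms for the degenerate tiny molecules
  charge <- tryCatch(ChemmineR::bonds(sdf, type = "bonds")$charge,
                     error = function(e) integer(n))
  deg <- integer(n)
  bond_order <- numeric(n)
  edges <- NULL
  if (!is.null(bb) && length(bb) > 0L && !is.matrix(bb)) {
    bb <- matrix(bb, nrow = 1L)
  }
  # bond-free molecules parse to a degenerate short block
  if (!is.null(bb) && (ncol(bb) < 3L || all(bb[, 1L] == 0))) bb <- NULL
  if (!is.null(bb) && nrow(bb) > 0L) {
    from <- as.integer(bb[, 1L]); to <- as.integer(bb[, 2L])
    ord <- as.numeric(bb[, 3L])
    for (r in seq_along(from)) {
      deg[from[r]] <- deg[from[r]] + 1L
      deg[to[r]] <- deg[to[r]] + 1L
      bond_order[from[r]] <- bond_order[from[r]] + ord[r]
      bond_order[to[r]] <- bond_order[to[r]] + ord[r]
    }
    edges <- cbind(from, to, ord)
  }
  in_ring <- ring_atoms(n, edges)
  # MOL2 also types carboxyl/guanidinium bonds "ar"; true aromaticity
  # additionally requires ring membership
  aromatic <- ob_aromatic_atoms(smiles, n) & in_ring
  cap <- VALENCE_TABLE[symbols]
  num_h <- ifelse(is.na(cap), 0, pmax(0, cap + charge - bond_order))
  # Hypervalent S/P (sulfones, phosphates): bonding capacity grows in steps
  # of 2; recompute against the smallest capacity >= bond order.
  hyper <- symbols %in% c("S", "P") & bond_order > cap
  if (any(hyper)) {
    cap2 <- cap + 2 * ceiling((bond_order - cap) / 2)
    num_h[hyper] <- pmax(0, cap2 + charge - bond_order)[hyper]
  }
  hyb <- rep(NA_character_, n)
  has_order <- function(o, cnt = 1L) {
    out <- integer(n)
    if (!is.null(edges)) {
      for (r in seq_len(nrow(edges))) {
        if (edges[r, 3L] == o) {
          out[edges[r, 1L]] <- out[edges[r, 1L]] + 1L
          out[edges[r, 2L]] <- out[edges[r, 2L]] + 1L
        }
      }
    }
    out
  }
  n_triple <- has_order(3); n_double <- has_order(2)
  organic <- symbols %in% c("C", "N", "O", "S", "P")
  hyb[organic & (n_triple > 0 | n_double >= 2)] <- "SP"
  hyb[organic & is.na(hyb) & (n_double == 1 | aromatic)] <- "SP2"
  hyb[organic & is.na(hyb)] <- "SP3"
  list(
    atoms = tibble::tibble(
      symbol = symbols, degree = as.integer(deg),
      num_h = as.integer(round(num_h)),
      implicit_valence = as.integer(round(num_h)),
      aromatic = aromatic, charge = as.integer(charge),
      radical = 0L, hybridization = hyb, in_ring = in_ring,
      chirality = NA_character_
    ),
    edges = edges
  )
}

graph_components <- function(n, edges) {
  comp <- seq_len(n)
  if (!is.null(edges)) {
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(edges))) {
        a <- edges[r, 1L]; b <- edges[r, 2L]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == comp[a] | comp == comp[b]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, unique(comp))
}

#' Parse a SMILES string into a molecular graph
#'
#' Atoms become nodes carrying the 78-dimensional feature vector of
#' [atom_to_features()]; chemical bonds become undirected, unweighted edges.
#' Hydrogens stay implicit (heavy-atom graph) and the adjacency matrix has a
#' zero diagonal -- self-loops are added only inside the graph convolution.
#' Multi-fragment SMILES (e.g. salts) are reduced to their largest fragment
#' with a warning, or rejected when `keep_largest_fragment = FALSE`.
#'
#' @param smiles A single SMILES string.
#' @param drug_id Optional identifier stored on the graph.
#' @param extended Use the extended atom featurizer (see [atom_to_features()]).
#' @param keep_largest_fragment Keep the largest connected fragment of
#'   multi-fragment inputs (default `TRUE`).
#' @return An object of class `gf_molgraph`: a list with `node_features`
#'   (N x 78 matrix), `adjacency` (symmetric binary N x N, zero diagonal),
#'   `num_atoms`, `atoms` (a tibble of per-atom descriptors), `smiles` and
#'   `drug_id`.
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$num_atoms              # 6
#' rowSums(g$adjacency)     # every ring atom has degree 2
#' @export
smiles_to_graph <- function(smiles, drug_id = NULL, extended = FALSE,
                            keep_largest_fragment = TRUE) {
  sdf <- parse_smiles_sdf(smiles)
  parsed <- sdf_atom_table(sdf, smiles)
  atoms <- parsed$atoms
  edges <- parsed$edges
  n <- nrow(atoms)
  comp <- graph_components(n, edges)
  if (max(comp) > 1L) {
    if (!keep_largest_fragment) {
      stop("SMILES '", smiles, "' contains ", max(comp),
           " disconnected fragments")
    }
    keep_comp <- which.max(tabulate(comp))
    keep <- which(comp == keep_comp)
    warning("SMILES '", smiles, "' has ", max(comp),
            " fragments; keeping the largest (", length(keep), " atoms)")
    remap <- match(seq_len(n), keep)
    atoms <- atoms[keep, , drop = FALSE]
    if (!is.null(edges)) {
      sel <- edges[, 1L] %in% keep & edges[, 2L] %in% keep
      edges <- edges[sel, , drop = FALSE]
      edges[, 1L] <- remap[edges[, 1L]]
      edges[, 2L] <- remap[edges[, 2L]]
      if (nrow(edges) == 0L) edges <- NULL
    }
    n <- nrow(atoms)
  }
  adj <- matrix(0, n, n)
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      adj[edges[r, 1L], edges[r, 2L]] <- 1
      adj[edges[r, 2L], edges[r, 1L]] <- 1
    }
  }
  feats <- t(vapply(seq_len(n),
                    function(i) atom_to_features(atoms[i, ], extended),
                    numeric(if (extended) 88L else 78L)))
  structure(
    list(node_features = feats, adjacency = adj, num_atoms = n,
         atoms = atoms, smiles = smiles, drug_id = drug_id),
    class = "gf_molgraph"
  )
}

#' @export
print.gf_molgraph <- function(x, ...) {
  cat("<gf_molgraph> ", x$smiles, "\n  atoms: ", x$num_atoms,
      "  bonds: ", sum(x$adjacency) / 2,
      "  feature dim: ", ncol(x$node_features), "\n", sep = "")
  invisible(x)
}

# Deterministic polynomial string hash (exact in double arithmetic).
hash_string <- function(s, mod = 2147483647) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% mod
  h
}

#' Hashed circular (Morgan-style) fingerprint of a molecule
#'
#' Iteratively hashes each atom's bonded neighborhood out to `radius` bonds
#' and folds every substructure identifier into a fixed-length bit vector.
#' The computation runs on the molecular graph, so any two SMILES spellings
#' of the same molecule give identical fingerprints.
#'
#' @param smiles A single SMILES string (alternatively pass a `gf_molgraph`).
#' @param n_bits Fingerprint length (default 2048).
#' @param radius Neighborhood radius in bonds (default 2).
#' @return An integer 0/1 vector of length `n_bits` with attributes
#'   `fp_kind` ("circular") and `radius`.
#' @examples
#' fp1 <- smiles_to_fingerprint("CCO")
#' fp2 <- smiles_to_fingerprint("OCC")
#' identical(fp1, fp2)  # TRUE: same molecule, different spelling
#' @export
smiles_to_fingerprint <- function(smiles, n_bits = 2048L, radius = 2L) {
  g <- if (inherits(smiles, "gf_molgraph")) smiles else smiles_to_graph(smiles)
  stopifnot(n_bits >= 1L, radius >= 0L)
  a <- g$atoms
  n <- g$num_atoms
  nbrs <- lapply(seq_len(n), function(i) which(g$adjacency[i, ] > 0))
  ids <- vapply(seq_len(n), function(i) {
    hash_string(paste(a$symbol[i], a$degree[i], a$num_h[i], a$charge[i],
                      as.integer(a$aromatic[i]), as.integer(a$in_ring[i]),
                      sep = "|"))
  }, numeric(1))
  seen <- ids
  if (radius > 0) {
    for (r in seq_len(radius)) {
      ids <- vapply(seq_len(n), function(i) {
        env <- sort(ids[nbrs[[i]]])
        hash_string(paste(c(r, ids[i], env), collapse = "|"))
      }, numeric(1))
      seen <- c(seen, ids)
    }
  }
  bits <- integer(n_bits)
  bits[(unique(seen) %% n_bits) + 1L] <- 1L
  structure(bits, fp_kind = "circular", radius = as.integer(radius))
}

#' Featurize a table of drugs
#'
#' Maps each SMILES in a (drug_id, smiles) table to its molecular graph and
#' fingerprint, returned as list-columns so results pipe into the model
#' builders.
#'
#' @param drugs A data frame with columns `drug_id` and `smiles`.
#' @param n_bits,radius Fingerprint parameters (see [smiles_to_fingerprint()]).
#' @param extended Use the extended atom featurizer.
#' @return A tibble with columns `drug_id`, `smiles`, `graph` (list of
#'   `gf_molgraph`) and `fingerprint` (list of bit vectors).
#' @export
featurize_drugs <- function(drugs, n_bits = 2048L, radius = 2L,
                            extended = FALSE) {
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  graphs <- purrr::map2(drugs$smiles, drugs$drug_id,
                        function(s, id) smiles_to_graph(s, drug_id = id,
                                                        extended = extended))
  fps <- purrr::map(graphs, smiles_to_fingerprint,
                    n_bits = n_bits, radius = radius)
  tibble::tibble(drug_id = drugs$drug_id, smiles = drugs$smiles,
                 graph = graphs, fingerprint = fps)
}

#' Write featurized molecular graphs to a plain-text store
#'
#' Serializes each graph as node-feature and edge-list records in a single
#' JSON file that [read_molgraphs()] restores exactly.
#'
#' @param featurized A tibble from [featurize_drugs()].
#' @param path Output file path (JSON).
#' @export
write_molgraphs <- function(featurized, path) {
  recs <- purrr::map(seq_len(nrow(featurized)), function(i) {
    g <- featurized$graph[[i]]
    ut <- which(upper.tri(g$adjacency) & g$adjacency > 0, arr.ind = TRUE)
    list(
      drug_id = featurized$drug_id[i],
      smiles = g$smiles,
      num_atoms = g$num_atoms,
      node_features = g$node_features,
      edges = if (nrow(ut)) unname(ut) else matrix(0L, 0L, 2L),
      fingerprint = which(featurized$fingerprint[[i]] == 1L),
      n_bits = length(featurized$fingerprint[[i]])
    )
  })
  jsonlite::write_json(recs, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a molecular-graph store written by [write_molgraphs()]
#'
#' @param path JSON file path.
#' @return A tibble with columns `drug_id`, `smiles`, `graph`, `fingerprint`.
#' @export
read_molgraphs <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  rows <- purrr::map(recs, function(r) {
    n <- r$num_atoms
    adj <- matrix(0, n, n)
    edges <- r$edges
    if (length(edges)) {
      edges <- matrix(unlist(edges), ncol = 2L, byrow = !is.matrix(edges))
      if (is.matrix(r$edges)) edges <- r$edges
      for (k in seq_len(nrow(edges))) {
        adj[edges[k, 1L], edges[k, 2L]] <- 1
        adj[edges[k, 2L], edges[k, 1L]] <- 1
      }
    }
    nf <- r$node_features
    if (!is.matrix(nf)) nf <- matrix(unlist(nf), nrow = n, byrow = TRUE)
    fp <- integer(r$n_bits)
    fp[unlist(r$fingerprint)] <- 1L
    g <- structure(
      list(node_features = nf, adjacency = adj, num_atoms = n,
           atoms = NULL, smiles = r$smiles, drug_id = r$drug_id),
      class = "gf_molgraph"
    )
    list(drug_id = r$drug_id, smiles = r$smiles, graph = g,
         fingerprint = structure(fp, fp_kind = "circular"))
  })
  tibble::tibble(
    drug_id = purrr::map_chr(rows, "drug_id"),
    smiles = purrr::map_chr(rows, "smiles"),
    graph = purrr::map(rows, "graph"),
    fingerprint = purrr::map(rows, "fingerprint")
  )
}
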