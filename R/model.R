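# Model configuration, parameter initialization, batched forward pass.
#
# The trainable model runs on the autodiff tape with all drug graphs packed
# into one disjoint union (block-diagonal normalized adjacency, edge lists
# with per-target segments) and unique cell lines / fingerprints encoded once
# per step and gathered into pair rows. model_forward() is the single-sample
# reference path composed from the exported layer functions in R/ops.R; the
# test suite checks the two routes agree to machine precision.

#' Model configuration
#'
#' Collects every architectural and optimization hyperparameter. Defaults
#' follow the published protocol where one is stated (3 graph-convolution
#' layers; attention heads 8 then 1; LeakyReLU slope 0.2; dropout 0.3; Adam
#' with learning rate 5e-4 and weight decay 5e-4; early stopping after 50
#' stale epochs within a 300-epoch budget; Xavier initialization) and
#' desk-scale choices elsewhere (embedding sizes, conv encoder shape; see
#' the package vignette).
#'
#' @param n_layers Number of graph-convolution layers (channels).
#' @param gcn_dim Node embedding width of each graph-convolution layer.
#' @param attn_heads Integer vector of length 2: heads in the first
#'   (concatenating) and final (averaging) attention stage of each channel.
#' @param attn_dim Per-head width of the first attention stage.
#' @param graph_dim Channel/graph embedding width (also the GRU state size).
#' @param q_dim Width of the super-node and layer-attention queries.
#' @param leaky_slope Negative slope of LeakyReLU in all attention logits.
#' @param cell_dim Length of the binary cell-line feature vector.
#' @param fp_bits,fp_radius Fingerprint length and neighborhood radius.
#' @param conv_filters,kernel_size Shared conv-encoder shape for both
#'   branches.
#' @param cell_stride,fp_stride Convolution strides of the cell-line and
#'   fingerprint branch.
#' @param branch_dim Dense output width of each encoder branch.
#' @param fuse_dim Common dimension the two views are projected to before
#'   the fusion gate.
#' @param gate_mode `"complementary"` (g, 1-g) or `"independent"` gates.
#' @param ha_dim Width of the post-fusion attention.
#' @param hidden_dim Hidden width of the dense prediction head.
#' @param dropout Dropout rate (training only).
#' @param learning_rate,weight_decay Adam step size and L2 coefficient.
#' @param max_epochs,patience Epoch budget and early-stopping patience.
#' @param batch_size Pairs per gradient step; `Inf` (default) trains
#'   full-batch.
#' @param variant `"full"`, `"no_multichannel"` (final-layer channel only)
#'   or `"concat_fusion"` (plain concatenation replaces the gate).
#' @param feature_dim Atom feature dimension (78, or 88 extended).
#' @param seed Master seed for initialization, shuffling and dropout.
#' @return A `gf_config` list.
#' @export
gf_config <- function(n_layers = 3L,
                      gcn_dim = 64L,
                      attn_heads = c(8L, 1L),
                      attn_dim = 16L,
                      graph_dim = 128L,
                      q_dim = 64L,
                      leaky_slope = 0.2,
                      cell_dim = 735L,
                      fp_bits = 2048L,
                      fp_radius = 2L,
                      conv_filters = 32L,
                      kernel_size = 8L,
                      cell_stride = 2L,
                      fp_stride = 8L,
                      branch_dim = 128L,
                      fuse_dim = 128L,
                      gate_mode = c("complementary", "independent"),
                      ha_dim = 64L,
                      hidden_dim = 128L,
                      dropout = 0.3,
                      learning_rate = 5e-4,
                      weight_decay = 5e-4,
                      max_epochs = 300L,
                      patience = 50L,
                      batch_size = Inf,
                      variant = c("full", "no_multichannel", "concat_fusion"),
                      feature_dim = 78L,
                      seed = 1L) {
  gate_mode <- match.arg(gate_mode)
  variant <- match.arg(variant)
  stopifnot(n_layers >= 1L, length(attn_heads) == 2L, all(attn_heads >= 1L),
            leaky_slope > 0, dropout >= 0, dropout < 1,
            max_epochs >= 1L, patience >= 1L)
  cfg <- list(
    n_layers = as.integer(n_layers), gcn_dim = as.integer(gcn_dim),
    attn_heads = as.integer(attn_heads), attn_dim = as.integer(attn_dim),
    graph_dim = as.integer(graph_dim), q_dim = as.integer(q_dim),
    leaky_slope = leaky_slope, cell_dim = as.integer(cell_dim),
    fp_bits = as.integer(fp_bits), fp_radius = as.integer(fp_radius),
    conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size),
    cell_stride = as.integer(cell_stride), fp_stride = as.integer(fp_stride),
    branch_dim = as.integer(branch_dim), fuse_dim = as.integer(fuse_dim),
    gate_mode = gate_mode, ha_dim = as.integer(ha_dim),
    hidden_dim = as.integer(hidden_dim), dropout = dropout,
    learning_rate = learning_rate, weight_decay = weight_decay,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    batch_size = batch_size, variant = variant,
    feature_dim = as.integer(feature_dim), seed = as.integer(seed)
  )
  structure(cfg, class = "gf_config")
}

#' @export
print.gf_config <- function(x, ...) {
  cat("<gf_config>\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 14), ": ",
        paste(format(x[[nm]]), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a model configuration file
#'
#' The on-disk schema is a flat JSON object mirroring [gf_config()] field
#' for field.
#'
#' @param path File path.
#' @param config A `gf_config` (for writing).
#' @return `read_config()` returns a `gf_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$batch_size)) {
    vals$batch_size <- as.numeric(vals$batch_size)  # JSON has no Inf literal
  }
  known <- names(formals(gf_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(gf_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

conv_out_len <- function(len, w, stride) {
  if (len < w) stop("input length ", len, " shorter than kernel ", w)
  as.integer((len - w) %/% stride + 1L)
}

xavier <- function(nr, nc) {
  b <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

#' Initialize model parameters
#'
#' Draws every weight matrix with Xavier (Glorot uniform) initialization and
#' zero biases, shaped according to the configuration. Uses the current RNG
#' state; seed it for reproducibility.
#'
#' @param config A [gf_config()].
#' @return Named list of parameter matrices (class `gf_params`) with the
#'   configuration attached as attribute `config`.
#' @export
init_model_params <- function(config) {
  cfg <- config
  K1 <- cfg$attn_heads[1L]; K2 <- cfg$attn_heads[2L]
  th <- list()
  din <- cfg$feature_dim
  for (l in seq_len(cfg$n_layers)) {
    th[[paste0("gcn_W_", l)]] <- xavier(din, cfg$gcn_dim)
    din <- cfg$gcn_dim
  }
  for (l in seq_len(cfg$n_layers)) {
    for (k in seq_len(K1)) {
      th[[paste0("ch", l, "_att1_W", k)]] <- xavier(cfg$gcn_dim, cfg$attn_dim)
      th[[paste0("ch", l, "_att1_phi", k)]] <- xavier(2L * cfg$attn_dim, 1L)
    }
    for (k in seq_len(K2)) {
      th[[paste0("ch", l, "_att2_W", k)]] <-
        xavier(K1 * cfg$attn_dim, cfg$graph_dim)
      th[[paste0("ch", l, "_att2_phi", k)]] <- xavier(2L * cfg$graph_dim, 1L)
    }
    th[[paste0("ch", l, "_sup_Wq")]] <- xavier(cfg$graph_dim, cfg$q_dim)
    th[[paste0("ch", l, "_sup_q")]] <- xavier(cfg$q_dim, 1L)
  }
  d <- cfg$graph_dim
  for (g in c("r", "z", "n")) {
    th[[paste0("gru_W", g)]] <- xavier(d, d)
    th[[paste0("gru_U", g)]] <- xavier(d, d)
    th[[paste0("gru_b", g)]] <- zeros(1L, d)
  }
  th$la_W <- xavier(d, cfg$q_dim)
  th$la_b <- zeros(1L, cfg$q_dim)
  th$la_v <- xavier(cfg$q_dim, 1L)
  p_c <- conv_out_len(cfg$cell_dim, cfg$kernel_size, cfg$cell_stride)
  p_f <- conv_out_len(cfg$fp_bits, cfg$kernel_size, cfg$fp_stride)
  th$cell_conv_W <- xavier(cfg$kernel_size, cfg$conv_filters)
  th$cell_conv_b <- zeros(1L, cfg$conv_filters)
  th$cell_dense_W <- xavier(p_c * cfg$conv_filters, cfg$branch_dim)
  th$cell_dense_b <- zeros(1L, cfg$branch_dim)
  th$fp_conv_W <- xavier(cfg$kernel_size, cfg$conv_filters)
  th$fp_conv_b <- zeros(1L, cfg$conv_filters)
  th$fp_dense_W <- xavier(p_f * cfg$conv_filters, cfg$branch_dim)
  th$fp_dense_b <- zeros(1L, cfg$branch_dim)
  th$proj_h_W <- xavier(cfg$graph_dim, cfg$fuse_dim)
  th$proj_h_b <- zeros(1L, cfg$fuse_dim)
  th$proj_x_W <- xavier(2L * cfg$branch_dim, cfg$fuse_dim)
  th$proj_x_b <- zeros(1L, cfg$fuse_dim)
  if (cfg$variant != "concat_fusion") {
    th$gate_W <- xavier(2L * cfg$fuse_dim, cfg$fuse_dim)
    th$gate_b <- zeros(1L, cfg$fuse_dim)
    if (cfg$gate_mode == "independent") {
      th$gate_W2 <- xavier(2L * cfg$fuse_dim, cfg$fuse_dim)
      th$gate_b2 <- zeros(1L, cfg$fuse_dim)
    }
  }
  th$ha_W <- xavier(cfg$fuse_dim, cfg$ha_dim)
  th$ha_a1 <- xavier(cfg$ha_dim, 1L)
  th$ha_a2 <- xavier(cfg$ha_dim, 1L)
  fused_dim <- if (cfg$variant == "concat_fusion") 2L * cfg$fuse_dim else
    cfg$fuse_dim
  th$fc1_W <- xavier(2L * cfg$ha_dim + fused_dim, cfg$hidden_dim)
  th$fc1_b <- zeros(1L, cfg$hidden_dim)
  th$fc2_W <- xavier(cfg$hidden_dim, 1L)
  th$fc2_b <- zeros(1L, 1L)
  structure(th, class = "gf_params", config = cfg)
}

# ---- parameter views for the numeric reference ops -------------------------

theta_gcn_weights <- function(theta, cfg) {
  lapply(seq_len(cfg$n_layers), function(l) theta[[paste0("gcn_W_", l)]])
}

theta_readout_params <- function(theta, cfg) {
  K1 <- cfg$attn_heads[1L]; K2 <- cfg$attn_heads[2L]
  channels <- lapply(seq_len(cfg$n_layers), function(l) {
    list(
      att1 = lapply(seq_len(K1), function(k) list(
        W = theta[[paste0("ch", l, "_att1_W", k)]],
        phi = theta[[paste0("ch", l, "_att1_phi", k)]]
      )),
      att2 = lapply(seq_len(K2), function(k) list(
        W = theta[[paste0("ch", l, "_att2_W", k)]],
        phi = theta[[paste0("ch", l, "_att2_phi", k)]]
      )),
      sup_Wq = theta[[paste0("ch", l, "_sup_Wq")]],
      sup_q = theta[[paste0("ch", l, "_sup_q")]]
    )
  })
  gru <- list(
    W_r = theta$gru_Wr, U_r = theta$gru_Ur, b_r = theta$gru_br,
    W_z = theta$gru_Wz, U_z = theta$gru_Uz, b_z = theta$gru_bz,
    W_n = theta$gru_Wn, U_n = theta$gru_Un, b_n = theta$gru_bn
  )
  list(channels = channels, gru = gru,
       layer_attn = list(W = theta$la_W, b = theta$la_b, v = theta$la_v))
}

theta_conv_params <- function(theta, cfg, branch = c("cell", "fp")) {
  branch <- match.arg(branch)
  stride <- if (branch == "cell") cfg$cell_stride else cfg$fp_stride
  list(conv_W = theta[[paste0(branch, "_conv_W")]],
       conv_b = theta[[paste0(branch, "_conv_b")]],
       dense_W = theta[[paste0(branch, "_dense_W")]],
       dense_b = theta[[paste0(branch, "_dense_b")]],
       stride = stride)
}

theta_gate_params <- function(theta) {
  list(proj_h_W = theta$proj_h_W, proj_h_b = theta$proj_h_b,
       proj_x_W = theta$proj_x_W, proj_x_b = theta$proj_x_b,
       gate_W = theta$gate_W, gate_b = theta$gate_b,
       gate_W2 = theta$gate_W2, gate_b2 = theta$gate_b2)
}

#' Single-sample model forward pass (reference path)
#'
#' Composes the exported layer operations -- graph convolution stack,
#' multi-channel attention readout, cell-line and fingerprint encoders,
#' adaptive fusion, post-fusion attention and dense head -- to predict the
#' normalized IC50 for one (drug graph, cell profile, fingerprint) triple.
#' Deterministic (evaluation mode: no dropout). The batched training path
#' computes exactly the same function; the test suite holds the two routes
#' together.
#'
#' @param params A `gf_params` from [init_model_params()].
#' @param graph A `gf_molgraph`.
#' @param profile Binary cell-line feature vector.
#' @param fingerprint Binary fingerprint vector.
#' @param config A `gf_config`; defaults to the one attached to `params`.
#' @return Predicted normalized IC50 in \[0, 1\].
#' @export
model_forward <- function(params, graph, profile, fingerprint,
                          config = attr(params, "config")) {
  cfg <- config
  stack <- gcn_forward(graph, theta_gcn_weights(params, cfg))
  ro <- multi_channel_readout(
    stack, theta_readout_params(params, cfg),
    channels = if (cfg$variant == "no_multichannel") "last" else "all",
    leaky_slope = cfg$leaky_slope
  )
  cemb <- encode_cell_line(profile, theta_conv_params(params, cfg, "cell"))
  femb <- encode_fingerprint(fingerprint, theta_conv_params(params, cfg, "fp"))
  X <- concat_embeddings(cemb, femb)
  fus <- adaptive_fusion(
    ro$embedding, X, theta_gate_params(params),
    gate_mode = cfg$gate_mode,
    variant = if (cfg$variant == "concat_fusion") "concat" else "gated"
  )
  ha <- head_attention(
    rbind(fus$h_proj, fus$x_proj),
    list(W = params$ha_W, a = c(params$ha_a1, params$ha_a2),
         leaky_slope = cfg$leaky_slope)
  )
  predict_head(list(ha$h_prime[1L, ], ha$h_prime[2L, ], fus$fused),
               list(fc1_W = params$fc1_W, fc1_b = params$fc1_b,
                    fc2_W = params$fc2_W, fc2_b = params$fc2_b))
}

# ---- batched data preparation ----------------------------------------------

# Flatten-permutation indices mapping a ((n*p) x f) feature-map matrix to an
# (n x (p*f)) matrix with filter outputs contiguous within each position
# (column-major index vector for op_perm).
flatten_perm_idx <- function(n, p, f) {
  col <- rep(seq_len(p * f), each = n)
  i <- rep(seq_len(n), times = p * f)
  pos <- (col - 1L) %/% f + 1L
  filt <- (col - 1L) %% f + 1L
  (filt - 1L) * (n * p) + (i - 1L) * p + pos
}

im2col <- function(X, w, stride) {
  # X: n x len matrix; rows of the result are the sliding windows of sample 1,
  # then sample 2, ... (position fastest within a sample)
  n <- nrow(X); len <- ncol(X)
  starts <- seq.int(1L, len - w + 1L, by = stride)
  p <- length(starts)
  out <- matrix(0, n * p, w)
  for (k in seq_along(starts)) {
    out[(seq_len(n) - 1L) * p + k, ] <-
      X[, starts[k]:(starts[k] + w - 1L), drop = FALSE]
  }
  out
}

#' Assemble model-ready tensors from featurized tables
#'
#' Packs all drug graphs into one disjoint union (block-diagonal normalized
#' adjacency, attention edge lists with self-loops, node-to-graph index),
#' precomputes the sliding-window (im2col) design matrices of both conv
#' encoders, and indexes response pairs against the drug and cell tables.
#'
#' @param featurized Tibble from [featurize_drugs()].
#' @param cells Data frame: `cell_id` column plus the binary feature columns.
#' @param responses Data frame with `drug_id`, `cell_id` and normalized
#'   response `y` (e.g. from [make_split()], whose `part` column is carried
#'   along if present).
#' @param config A [gf_config()].
#' @return A `gf_model_data` list consumed by [gf_train()].
#' @export
gf_model_data <- function(featurized, cells, responses, config) {
  cfg <- config
  stopifnot(all(c("drug_id", "graph", "fingerprint") %in% names(featurized)),
            "cell_id" %in% names(cells),
            all(c("drug_id", "cell_id", "y") %in% names(responses)))
  graphs <- featurized$graph
  n_drugs <- length(graphs)
  sizes <- vapply(graphs, function(g) g$num_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes[-n_drugs]))
  X0 <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  A_hat <- Matrix::bdiag(lapply(graphs,
                                function(g) normalize_adjacency(g$adjacency)))
  graph_id <- rep.int(seq_len(n_drugs), sizes)
  src <- integer(0); dst <- integer(0)
  for (d in seq_len(n_drugs)) {
    adj <- graphs[[d]]$adjacency
    nb <- adj > 0
    diag(nb) <- TRUE  # self-inclusion keeps every neighborhood non-empty
    idx <- which(nb, arr.ind = TRUE)
    dst <- c(dst, idx[, 1L] + offsets[d])
    src <- c(src, idx[, 2L] + offsets[d])
  }
  ord <- order(dst, src)
  src <- src[ord]; dst <- dst[ord]
  fps <- do.call(rbind, lapply(featurized$fingerprint, as.numeric))
  if (ncol(fps) != cfg$fp_bits) {
    stop("fingerprint length ", ncol(fps), " does not match config fp_bits ",
         cfg$fp_bits)
  }
  feat_cols <- setdiff(names(cells), "cell_id")
  C <- as.matrix(cells[, feat_cols, drop = FALSE])
  if (ncol(C) != cfg$cell_dim) {
    stop("cell profile length ", ncol(C), " does not match config cell_dim ",
         cfg$cell_dim)
  }
  n_cells <- nrow(C)
  drug_idx <- match(responses$drug_id, featurized$drug_id)
  cell_idx <- match(responses$cell_id, cells$cell_id)
  if (anyNA(drug_idx) || anyNA(cell_idx)) {
    stop("responses reference drugs or cells absent from the feature tables")
  }
  p_c <- conv_out_len(cfg$cell_dim, cfg$kernel_size, cfg$cell_stride)
  p_f <- conv_out_len(cfg$fp_bits, cfg$kernel_size, cfg$fp_stride)
  list(
    config = cfg,
    n_drugs = n_drugs, n_cells = n_cells, n_nodes = nrow(X0),
    X0 = X0, A_hat = A_hat, graph_id = graph_id, src = src, dst = dst,
    cell_im2col = im2col(C, cfg$kernel_size, cfg$cell_stride),
    cell_perm = flatten_perm_idx(n_cells, p_c, cfg$conv_filters),
    fp_im2col = im2col(fps, cfg$kernel_size, cfg$fp_stride),
    fp_perm = flatten_perm_idx(n_drugs, p_f, cfg$conv_filters),
    p_c = p_c, p_f = p_f,
    drug_idx = drug_idx, cell_idx = cell_idx,
    y = as.numeric(responses$y),
    part = if ("part" %in% names(responses)) responses$part else
      rep("train", nrow(responses)),
    drug_ids = featurized$drug_id, cell_ids = cells$cell_id
  )
}

# ---- batched forward on the autodiff tape ----------------------------------

# Returns list(tape, pred, loss). `rows` selects response pairs. When
# `training` is TRUE dropout masks are drawn from the current RNG.
forward_tape <- function(theta, data, rows, training = FALSE,
                         target = NULL) {
  cfg <- data$config
  tape <- ad_tape()
  P <- function(name) {
    v <- theta[[name]]
    if (is.null(v)) stop("missing parameter '", name, "'")
    ad_param(tape, v, name)
  }
  keep <- 1 - cfg$dropout
  drop_node <- function(node) {
    if (!training || cfg$dropout == 0) return(node)
    mask <- matrix(stats::rbinom(length(node$value), 1L, keep),
                   nrow(node$value), ncol(node$value))
    op_dropout(tape, node, mask, keep)
  }
  K1 <- cfg$attn_heads[1L]; K2 <- cfg$attn_heads[2L]
  src <- data$src; dst <- data$dst
  n_nodes <- data$n_nodes
  gat_layer <- function(Z, l, stage, K, mode) {
    outs <- vector("list", K)
    for (k in seq_len(K)) {
      W <- P(paste0("ch", l, "_att", stage, "_W", k))
      phi <- P(paste0("ch", l, "_att", stage, "_phi", k))
      dpr <- ncol(theta[[paste0("ch", l, "_att", stage, "_W", k)]])
      Zw <- op_mm(tape, Z, W)
      s <- op_mm(tape, Zw, op_rows(tape, phi, seq_len(dpr)))
      t_ <- op_mm(tape, Zw, op_rows(tape, phi, dpr + seq_len(dpr)))
      e <- op_leaky_relu(
        tape,
        op_add(tape, op_rows(tape, s, dst), op_rows(tape, t_, src)),
        cfg$leaky_slope
      )
      al <- op_segment_softmax(tape, e, dst)
      outs[[k]] <- op_edge_aggregate(tape, al, Zw, src, dst, n_nodes)
    }
    if (mode == "concat") {
      op_cbind(tape, lapply(outs, function(o) op_relu(tape, o)))
    } else {
      s <- outs[[1L]]
      if (K > 1L) for (k in 2L:K) s <- op_add(tape, s, outs[[k]])
      op_relu(tape, op_affine(tape, s, scale = 1 / K))
    }
  }
  # drug branch
  Z <- ad_const(tape, data$X0)
  stack <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    Z <- op_relu(tape, op_mm(tape, op_spmm(tape, data$A_hat, Z),
                             P(paste0("gcn_W_", l))))
    stack[[l]] <- Z
  }
  use <- if (cfg$variant == "no_multichannel") cfg$n_layers else
    seq_len(cfg$n_layers)
  states <- vector("list", length(use))
  s_state <- ad_const(tape, matrix(0, data$n_drugs, cfg$graph_dim))
  for (k in seq_along(use)) {
    l <- use[k]
    H1 <- gat_layer(stack[[l]], l, 1L, K1, "concat")
    H2 <- gat_layer(H1, l, 2L, K2, "average")
    sc <- op_mm(tape, op_tanh(tape, op_mm(tape, H2,
                                          P(paste0("ch", l, "_sup_Wq")))),
                P(paste0("ch", l, "_sup_q")))
    gam <- op_segment_softmax(tape, sc, data$graph_id)
    g_l <- op_segment_wsum(tape, gam, H2, data$graph_id, data$n_drugs)
    # GRU update of the super-node state across channels
    r <- op_sigmoid(tape, op_bias(tape, op_add(
      tape, op_mm(tape, g_l, P("gru_Wr")), op_mm(tape, s_state, P("gru_Ur"))),
      P("gru_br")))
    z <- op_sigmoid(tape, op_bias(tape, op_add(
      tape, op_mm(tape, g_l, P("gru_Wz")), op_mm(tape, s_state, P("gru_Uz"))),
      P("gru_bz")))
    nn <- op_tanh(tape, op_bias(tape, op_add(
      tape, op_mm(tape, g_l, P("gru_Wn")),
      op_mm(tape, op_mul(tape, r, s_state), P("gru_Un"))), P("gru_bn")))
    s_state <- op_add(tape, op_mul(tape, z, s_state),
                      op_mul(tape, op_affine(tape, z, -1, 1), nn))
    states[[k]] <- s_state
  }
  us <- lapply(states, function(S) {
    op_mm(tape, op_tanh(tape, op_bias(tape, op_mm(tape, S, P("la_W")),
                                      P("la_b"))), P("la_v"))
  })
  beta <- op_row_softmax(tape, op_cbind(tape, us))
  h_drugs <- NULL
  for (k in seq_along(states)) {
    term <- op_scale_rows(tape, states[[k]], op_cols(tape, beta, k))
    h_drugs <- if (is.null(h_drugs)) term else op_add(tape, h_drugs, term)
  }
  # encoder branches (unique entities, then gathered into pair rows)
  branch <- function(prefix, im2col_mat, perm, n, p) {
    fmap <- op_relu(tape, op_bias(
      tape, op_mm(tape, ad_const(tape, im2col_mat), P(paste0(prefix, "_conv_W"))),
      P(paste0(prefix, "_conv_b"))))
    flat <- op_perm(tape, fmap, perm, n, p * cfg$conv_filters)
    drop_node(op_relu(tape, op_bias(
      tape, op_mm(tape, flat, P(paste0(prefix, "_dense_W"))),
      P(paste0(prefix, "_dense_b")))))
  }
  cell_emb <- branch("cell", data$cell_im2col, data$cell_perm,
                     data$n_cells, data$p_c)
  fp_emb <- branch("fp", data$fp_im2col, data$fp_perm, data$n_drugs, data$p_f)
  di <- data$drug_idx[rows]; ci <- data$cell_idx[rows]
  h <- op_rows(tape, h_drugs, di)
  Xcf <- op_cbind(tape, list(op_rows(tape, cell_emb, ci),
                             op_rows(tape, fp_emb, di)))
  h_proj <- op_relu(tape, op_bias(tape, op_mm(tape, h, P("proj_h_W")),
                                  P("proj_h_b")))
  x_proj <- op_relu(tape, op_bias(tape, op_mm(tape, Xcf, P("proj_x_W")),
                                  P("proj_x_b")))
  if (cfg$variant == "concat_fusion") {
    fused <- op_cbind(tape, list(h_proj, x_proj))
  } else {
    both <- op_cbind(tape, list(h_proj, x_proj))
    g1 <- op_sigmoid(tape, op_bias(tape, op_mm(tape, both, P("gate_W")),
                                   P("gate_b")))
    g2 <- if (cfg$gate_mode == "independent") {
      op_sigmoid(tape, op_bias(tape, op_mm(tape, both, P("gate_W2")),
                               P("gate_b2")))
    } else {
      op_affine(tape, g1, -1, 1)
    }
    fused <- op_add(tape, op_mul(tape, h_proj, g1),
                    op_mul(tape, x_proj, g2))
  }
  # post-fusion attention over the two modality views
  Wh1 <- op_mm(tape, h_proj, P("ha_W"))
  Wh2 <- op_mm(tape, x_proj, P("ha_W"))
  a1 <- P("ha_a1"); a2 <- P("ha_a2")
  s1 <- op_mm(tape, Wh1, a1); t1 <- op_mm(tape, Wh1, a2)
  s2 <- op_mm(tape, Wh2, a1); t2 <- op_mm(tape, Wh2, a2)
  lk <- function(x) op_leaky_relu(tape, x, cfg$leaky_slope)
  A1 <- op_row_softmax(tape, op_cbind(tape, list(
    lk(op_add(tape, s1, t1)), lk(op_add(tape, s1, t2)))))
  A2 <- op_row_softmax(tape, op_cbind(tape, list(
    lk(op_add(tape, s2, t1)), lk(op_add(tape, s2, t2)))))
  hp1 <- drop_node(op_relu(tape, op_add(
    tape, op_scale_rows(tape, Wh1, op_cols(tape, A1, 1L)),
    op_scale_rows(tape, Wh2, op_cols(tape, A1, 2L)))))
  hp2 <- drop_node(op_relu(tape, op_add(
    tape, op_scale_rows(tape, Wh1, op_cols(tape, A2, 1L)),
    op_scale_rows(tape, Wh2, op_cols(tape, A2, 2L)))))
  flat <- op_cbind(tape, list(hp1, hp2, fused))
  hid <- drop_node(op_relu(tape, op_bias(tape, op_mm(tape, flat, P("fc1_W")),
                                         P("fc1_b"))))
  pred <- op_sigmoid(tape, op_bias(tape, op_mm(tape, hid, P("fc2_W")),
                                   P("fc2_b")))
  loss <- if (is.null(target)) NULL else
    op_mse(tape, pred, matrix(target, ncol = 1L))
  list(tape = tape, pred = pred, loss = loss)
}

# Evaluation-mode batched predictions for a set of response rows.
predict_rows <- function(theta, data, rows) {
  fw <- forward_tape(theta, data, rows, training = FALSE)
  as.numeric(fw$pred$value)
}
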