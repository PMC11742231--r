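# Reference implementations of the model's building blocks on plain dense
# matrices. These are the exported, documented forms of each layer; the
# trainable model composes the same arithmetic through the autodiff tape
# (R/model.R), and the test suite checks the two routes against each other
# and against brute-force evaluation.

relu_num <- function(x) pmax(x, 0)
sigmoid_num <- function(x) 1 / (1 + exp(-x))
leaky_relu_num <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

activation_fun <- function(name) {
  switch(name,
    relu = relu_num,
    sigmoid = sigmoid_num,
    tanh = tanh,
    identity = identity,
    stop("unknown activation '", name, "'")
  )
}

#' Normalized self-looped adjacency
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)`, the symmetrically normalized
#' adjacency with self-loops used by the graph convolution.
#'
#' @param adjacency Symmetric binary adjacency matrix with zero diagonal.
#' @return A dense N x N matrix.
#' @export
normalize_adjacency <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (any(abs(adjacency - t(adjacency)) > 1e-12)) {
    stop("adjacency must be symmetric")
  }
  a_tilde <- adjacency + diag(nrow(adjacency))
  d <- rowSums(a_tilde)
  dm <- 1 / sqrt(d)
  a_tilde * outer(dm, dm)
}

#' Graph convolution stack over a molecular graph
#'
#' Runs `L` graph convolution layers
#' `Z^(l) = ReLU(D^(-1/2) (A + I) D^(-1/2) Z^(l-1) W^(l))` and retains the
#' node embeddings of every layer (the per-layer "channels" consumed by the
#' multi-channel attention readout). `Z^(0)` is the input node-feature
#' matrix.
#'
#' @param graph A `gf_molgraph` (or any list with `node_features` and
#'   `adjacency`).
#' @param weights List of `L` weight matrices with chaining dimensions.
#' @return An object of class `gf_gcn_stack`: list with `layers` (length
#'   `L + 1`, including layer 0) and `adjacency`.
#' @examples
#' g <- smiles_to_graph("CC")
#' st <- gcn_forward(g, list(matrix(rnorm(78 * 4), 78, 4)))
#' dim(st$layers[[2]])  # 2 x 4
#' @export
gcn_forward <- function(graph, weights) {
  Z <- graph$node_features
  stopifnot(is.matrix(Z), length(weights) >= 1L)
  A_hat <- normalize_adjacency(graph$adjacency)
  layers <- vector("list", length(weights) + 1L)
  layers[[1L]] <- Z
  for (l in seq_along(weights)) {
    W <- weights[[l]]
    if (ncol(Z) != nrow(W)) {
      stop("gcn weight ", l, " has ", nrow(W), " rows but layer input has ",
           ncol(Z), " columns")
    }
    Z <- relu_num(A_hat %*% Z %*% W)
    layers[[l + 1L]] <- Z
  }
  structure(list(layers = layers, adjacency = graph$adjacency),
            class = "gf_gcn_stack")
}

attention_neighborhoods <- function(adjacency, include_self = TRUE) {
  n <- nrow(adjacency)
  nb <- adjacency > 0
  if (include_self) diag(nb) <- TRUE
  lapply(seq_len(n), function(i) which(nb[i, ]))
}

#' Graph attention scores over a neighborhood structure
#'
#' Computes raw attention logits
#' `e_ij = LeakyReLU(phi^T [W z_i || W z_j])` for every edge and normalizes
#' them with a softmax over each node's neighborhood. Nodes include
#' themselves in their neighborhood so isolated nodes keep a well-defined
#' attention distribution.
#'
#' @param Z Node embedding matrix (N x F).
#' @param W Shared linear transform (F x F').
#' @param phi Attention weight vector of length `2 * F'`.
#' @param adjacency Symmetric binary adjacency (zero diagonal).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.2).
#' @param include_self Include each node in its own neighborhood
#'   (default `TRUE`).
#' @return List with `e` and `alpha` (N x N matrices, `NA` outside the
#'   neighborhood) and `neighborhoods` (list of neighbor index vectors).
#'   `alpha` rows sum to 1 over each neighborhood.
#' @export
gat_scores <- function(Z, W, phi, adjacency, leaky_slope = 0.2,
                       include_self = TRUE) {
  stopifnot(nrow(Z) == nrow(adjacency), ncol(Z) == nrow(W))
  phi <- as.numeric(phi)
  fp <- ncol(W)
  if (length(phi) != 2L * fp) {
    stop("phi must have length 2 * ncol(W) = ", 2L * fp)
  }
  n <- nrow(Z)
  Zw <- Z %*% W
  s <- as.numeric(Zw %*% phi[seq_len(fp)])
  t_ <- as.numeric(Zw %*% phi[fp + seq_len(fp)])
  nbrs <- attention_neighborhoods(adjacency, include_self)
  e <- matrix(NA_real_, n, n)
  alpha <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    js <- nbrs[[i]]
    ei <- leaky_relu_num(s[i] + t_[js], leaky_slope)
    e[i, js] <- ei
    ex <- exp(ei - max(ei))
    alpha[i, js] <- ex / sum(ex)
  }
  list(e = e, alpha = alpha, neighborhoods = nbrs)
}

#' Multi-head graph attention layer
#'
#' Applies `K` attention heads to the node embeddings. In `"concat"` mode
#' the per-head outputs are concatenated (output dimension `K * F'`); in
#' `"average"` mode -- used for the final attention layer -- the heads are
#' averaged before the nonlinearity (output dimension `F'`).
#'
#' @param Z Node embedding matrix (N x F).
#' @param heads List of `K` head parameter lists, each with elements `W`
#'   (F x F') and `phi` (length `2 * F'`).
#' @param adjacency Symmetric binary adjacency.
#' @param mode `"concat"` or `"average"`.
#' @param leaky_slope LeakyReLU slope for the attention logits.
#' @param activation Output nonlinearity (default `"relu"`).
#' @param include_self Include self-loops in the attention neighborhoods.
#' @return Node embedding matrix, N x (K * F') or N x F'.
#' @export
multi_head_layer <- function(Z, heads, adjacency, mode = c("concat", "average"),
                             leaky_slope = 0.2, activation = "relu",
                             include_self = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(heads) >= 1L)
  act <- activation_fun(activation)
  outs <- lapply(heads, function(h) {
    sc <- gat_scores(Z, h$W, h$phi, adjacency, leaky_slope, include_self)
    al <- sc$alpha
    al[is.na(al)] <- 0
    al %*% (Z %*% h$W)
  })
  if (mode == "concat") {
    do.call(cbind, lapply(outs, act))
  } else {
    act(Reduce(`+`, outs) / length(outs))
  }
}

#' Super-node attention readout of a graph
#'
#' Pools node embeddings into one graph embedding using a virtual super node
#' linked to every atom: the trainable super-node state acts as the query,
#' each node receives a score `q^T tanh(W_q^T h_i)`, scores are softmaxed
#' over the graph and the embedding is the attention-weighted sum.
#'
#' @param H Node embedding matrix (N x D).
#' @param W_q Query transform (D x q_dim).
#' @param q Super-node state / query vector (length q_dim).
#' @return List with `embedding` (length D) and `weights` (length N, sums
#'   to 1).
#' @export
readout_supernode <- function(H, W_q, q) {
  stopifnot(ncol(H) == nrow(W_q))
  scores <- as.numeric(tanh(H %*% W_q) %*% as.numeric(q))
  ex <- exp(scores - max(scores))
  w <- ex / sum(ex)
  list(embedding = as.numeric(t(w) %*% H), weights = w)
}

gru_cell_num <- function(x, s, p) {
  x <- matrix(as.numeric(x), nrow = 1L)
  s <- matrix(as.numeric(s), nrow = 1L)
  r <- sigmoid_num(x %*% p$W_r + s %*% p$U_r + p$b_r)
  z <- sigmoid_num(x %*% p$W_z + s %*% p$U_z + p$b_z)
  n <- tanh(x %*% p$W_n + (r * s) %*% p$U_n + p$b_n)
  as.numeric(z * s + (1 - z) * n)
}

#' Multi-channel attention readout of a graph-convolution stack
#'
#' The drug-embedding head: each retained graph-convolution layer ("channel")
#' is refined by a two-stage multi-head graph attention block (first stage
#' concatenating heads, final stage averaging), pooled into a per-layer graph
#' embedding through the virtual super node, passed through a GRU that
#' updates the super-node state across layers in order, and finally combined
#' by an attention over the per-layer states whose weights sum to 1.
#'
#' @param stack A `gf_gcn_stack` from [gcn_forward()].
#' @param params Channel/readout parameters; see [init_model_params()] for
#'   the layout (`channels`, `gru`, `layer_attn` entries).
#' @param channels Which stack layers to use: `"all"` (multi-channel,
#'   default) or `"last"` (final layer only, the no-multichannel ablation).
#' @param leaky_slope LeakyReLU slope inside the attention blocks.
#' @return List with `embedding` (the drug embedding), `layer_weights`
#'   (attention over channels, sums to 1), `channel_embeddings` and
#'   `states` (GRU states).
#' @export
multi_channel_readout <- function(stack, params, channels = c("all", "last"),
                                  leaky_slope = 0.2) {
  channels <- match.arg(channels)
  L <- length(stack$layers) - 1L
  if (L < 1L) stop("stack must contain at least one convolution layer")
  use <- if (channels == "last") L else seq_len(L)
  adj <- stack$adjacency
  ch_emb <- vector("list", length(use))
  for (k in seq_along(use)) {
    l <- use[k]
    cp <- params$channels[[l]]
    H1 <- multi_head_layer(stack$layers[[l + 1L]], cp$att1, adj,
                           mode = "concat", leaky_slope = leaky_slope)
    H2 <- multi_head_layer(H1, cp$att2, adj,
                           mode = "average", leaky_slope = leaky_slope)
    ch_emb[[k]] <- readout_supernode(H2, cp$sup_Wq, cp$sup_q)$embedding
  }
  d <- length(ch_emb[[1L]])
  s <- numeric(d)
  states <- vector("list", length(use))
  for (k in seq_along(use)) {
    s <- gru_cell_num(ch_emb[[k]], s, params$gru)
    states[[k]] <- s
  }
  S <- do.call(rbind, states)
  u <- as.numeric(tanh(sweep(S %*% params$layer_attn$W, 2L,
                             as.numeric(params$layer_attn$b), "+")) %*%
                    as.numeric(params$layer_attn$v))
  ex <- exp(u - max(u))
  beta <- ex / sum(ex)
  list(
    embedding = as.numeric(t(beta) %*% S),
    layer_weights = beta,
    channel_embeddings = ch_emb,
    states = states
  )
}

#' One-dimensional convolutional encoder
#'
#' Applies a valid (no padding) 1-D convolution with `filters` kernels of
#' width `w` to a single-channel input sequence, a nonlinearity, flattening
#' (filter outputs contiguous per position), and a dense layer.
#'
#' @param sequence Numeric input vector (e.g. a binary cell-line profile or
#'   fingerprint).
#' @param params List with `conv_W` (w x filters), `conv_b` (filters),
#'   `dense_W` (M x out), `dense_b` (out), and optionally `stride`
#'   (default 1), `activation` and `dense_activation` (default `"relu"`).
#' @return Numeric vector of length `ncol(dense_W)`.
#' @examples
#' p <- list(conv_W = matrix(c(1, 1), 2, 1), conv_b = 0,
#'           dense_W = matrix(1, 2, 1), dense_b = 0)
#' conv_encode(c(1, 2, 3), p)  # (1+2) + (2+3) = 8
#' @export
conv_encode <- function(sequence, params) {
  x <- as.numeric(sequence)
  W <- params$conv_W
  w <- nrow(W)
  stride <- params$stride %||% 1L
  if (length(x) < w) {
    stop("sequence length ", length(x), " is shorter than kernel width ", w)
  }
  act <- activation_fun(params$activation %||% "relu")
  dact <- activation_fun(params$dense_activation %||% "relu")
  starts <- seq.int(1L, length(x) - w + 1L, by = stride)
  # im2col: each row is one window of the input
  windows <- matrix(x[outer(starts, seq_len(w) - 1L, "+")],
                    length(starts), w)
  fmap <- act(sweep(windows %*% W, 2L, as.numeric(params$conv_b), "+"))
  flat <- as.numeric(t(fmap))  # filters contiguous within each position
  if (length(flat) != nrow(params$dense_W)) {
    stop("dense layer expects ", nrow(params$dense_W),
         " inputs but the flattened feature map has ", length(flat))
  }
  as.numeric(dact(flat %*% params$dense_W + as.numeric(params$dense_b)))
}

#' Encode a binary cell-line profile
#'
#' Convolutional encoder specialization for the 735-dimensional binary
#' genomic feature vector of a cell line.
#'
#' @param profile 0/1 numeric vector (length 735 by default conventions).
#' @param params See [conv_encode()].
#' @return Embedding vector.
#' @export
encode_cell_line <- function(profile, params) {
  if (!all(profile %in% c(0, 1))) {
    stop("cell-line profile must be binary (0/1)")
  }
  conv_encode(profile, params)
}

#' Encode a drug fingerprint
#'
#' Convolutional encoder specialization for the hashed fingerprint bits.
#'
#' @param fp 0/1 fingerprint vector.
#' @param params See [conv_encode()].
#' @return Embedding vector.
#' @export
encode_fingerprint <- function(fp, params) {
  if (!all(fp %in% c(0, 1))) stop("fingerprint must be binary (0/1)")
  conv_encode(fp, params)
}

#' Concatenate cell-line and fingerprint embeddings
#'
#' @param cell_emb,fp_emb Finite numeric vectors.
#' @return Numeric vector `c(cell_emb, fp_emb)`.
#' @export
concat_embeddings <- function(cell_emb, fp_emb) {
  if (length(cell_emb) == 0L || length(fp_emb) == 0L) {
    stop("embeddings must be non-empty")
  }
  if (!all(is.finite(cell_emb)) || !all(is.finite(fp_emb))) {
    stop("embeddings must be finite")
  }
  c(as.numeric(cell_emb), as.numeric(fp_emb))
}

#' Adaptive gated fusion of drug and cell+fingerprint embeddings
#'
#' Projects the drug embedding `h` and the concatenated cell+fingerprint
#' embedding `X` to a common dimension, computes an elementwise control gate
#' `g = sigmoid(W_g [h_proj || X_proj] + b_g)` in (0,1), and blends the two
#' views as the convex combination
#' `H = h_proj * g_out1 + X_proj * g_out2` with complementary gates
#' `g_out1 = g`, `g_out2 = 1 - g` (independent second gate available via
#' `gate_mode = "independent"`). With `variant = "concat"` the gate is
#' bypassed and the fusion is the plain concatenation of the two projections
#' (the concatenation-fusion ablation).
#'
#' @param h Drug embedding vector.
#' @param X Concatenated cell-line + fingerprint embedding vector.
#' @param gate_params List with projections `proj_h_W`, `proj_h_b`,
#'   `proj_x_W`, `proj_x_b`, gate `gate_W`, `gate_b` and optionally
#'   `gate_W2`, `gate_b2` for the independent-gates variant.
#' @param gate_mode `"complementary"` (default) or `"independent"`.
#' @param variant `"gated"` (default) or `"concat"`.
#' @return List with `fused`, `g_out1`, `g_out2`, `h_proj`, `x_proj`.
#' @export
adaptive_fusion <- function(h, X, gate_params,
                            gate_mode = c("complementary", "independent"),
                            variant = c("gated", "concat")) {
  gate_mode <- match.arg(gate_mode)
  variant <- match.arg(variant)
  p <- gate_params
  h <- matrix(as.numeric(h), nrow = 1L)
  X <- matrix(as.numeric(X), nrow = 1L)
  if (ncol(h) != nrow(p$proj_h_W) || ncol(X) != nrow(p$proj_x_W)) {
    stop("embedding dimensions do not match the projection layers")
  }
  h_proj <- relu_num(h %*% p$proj_h_W + as.numeric(p$proj_h_b))
  x_proj <- relu_num(X %*% p$proj_x_W + as.numeric(p$proj_x_b))
  if (variant == "concat") {
    return(list(fused = c(as.numeric(h_proj), as.numeric(x_proj)),
                g_out1 = NULL, g_out2 = NULL,
                h_proj = as.numeric(h_proj), x_proj = as.numeric(x_proj)))
  }
  both <- cbind(h_proj, x_proj)
  g1 <- sigmoid_num(both %*% p$gate_W + as.numeric(p$gate_b))
  g2 <- if (gate_mode == "complementary") {
    1 - g1
  } else {
    sigmoid_num(both %*% p$gate_W2 + as.numeric(p$gate_b2))
  }
  fused <- h_proj * g1 + x_proj * g2
  list(fused = as.numeric(fused),
       g_out1 = as.numeric(g1), g_out2 = as.numeric(g2),
       h_proj = as.numeric(h_proj), x_proj = as.numeric(x_proj))
}

#' Post-fusion attention over the modality views
#'
#' Applies one graph-attention layer
#' (`e_ij = LeakyReLU(a^T [W h_i || W h_j])`, softmax over neighbors,
#' `h'_i = ReLU(sum_j alpha_ij W h_j)`) to a small, fully connected set of
#' embedding vectors -- in the model, the projected drug view and the
#' projected cell+fingerprint view -- so the head can re-weight the most
#' informative view before the dense layers.
#'
#' @param H_set Matrix whose rows are the embedding vectors (m x d).
#' @param params List with `W` (d x d'), `a` (length `2 d'`) and optionally
#'   `leaky_slope`, `activation`.
#' @return List with `h_prime` (m x d'), `alpha` (m x m attention matrix,
#'   rows sum to 1) and `e` (raw logits).
#' @export
head_attention <- function(H_set, params) {
  H_set <- as.matrix(H_set)
  m <- nrow(H_set)
  adj <- matrix(1, m, m) - diag(m)  # fully connected; self added below
  sc <- gat_scores(H_set, params$W, params$a, adj,
                   leaky_slope = params$leaky_slope %||% 0.2,
                   include_self = TRUE)
  act <- activation_fun(params$activation %||% "relu")
  al <- sc$alpha
  al[is.na(al)] <- 0
  list(h_prime = act(al %*% (H_set %*% params$W)), alpha = sc$alpha,
       e = sc$e)
}

#' Dense prediction head
#'
#' Flattens its inputs, applies one hidden dense layer with ReLU and a final
#' dense layer with sigmoid, so the predicted normalized IC50 lies in \[0,1\].
#'
#' @param inputs Numeric vector, matrix, or list of pieces to flatten and
#'   concatenate.
#' @param params List with `fc1_W`, `fc1_b`, `fc2_W`, `fc2_b`.
#' @return A single numeric prediction in \[0,1\].
#' @export
predict_head <- function(inputs, params) {
  if (is.list(inputs) && !is.data.frame(inputs)) {
    flat <- unlist(lapply(inputs, function(x) as.numeric(t(as.matrix(x)))))
  } else {
    flat <- as.numeric(t(as.matrix(inputs)))
  }
  if (!all(is.finite(flat))) stop("prediction head input must be finite")
  if (length(flat) != nrow(params$fc1_W)) {
    stop("prediction head expects ", nrow(params$fc1_W), " inputs, got ",
         length(flat))
  }
  hid <- relu_num(matrix(flat, nrow = 1L) %*% params$fc1_W +
                    as.numeric(params$fc1_b))
  as.numeric(sigmoid_num(hid %*% params$fc2_W + as.numeric(params$fc2_b)))
}
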