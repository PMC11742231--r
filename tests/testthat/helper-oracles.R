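# Independent brute-force oracles: every formula evaluated with explicit
# loops over indices, no shared code with the package implementation.

oracle_gcn <- function(graph, weights) {
  A <- graph$adjacency
  n <- nrow(A)
  At <- A + diag(n)
  d <- rowSums(At)
  Anorm <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) Anorm[i, j] <- At[i, j] / sqrt(d[i] * d[j])
  Z <- graph$node_features
  out <- list(Z)
  for (W in weights) {
    Znew <- matrix(0, n, ncol(W))
    for (i in 1:n) for (f in 1:ncol(W)) {
      acc <- 0
      for (j in 1:n) for (k in 1:ncol(Z)) {
        acc <- acc + Anorm[i, j] * Z[j, k] * W[k, f]
      }
      Znew[i, f] <- max(acc, 0)
    }
    Z <- Znew
    out <- c(out, list(Z))
  }
  out
}

oracle_gat_alpha <- function(Z, W, phi, adj, slope = 0.2) {
  n <- nrow(Z)
  fp <- ncol(W)
  Zw <- matrix(0, n, fp)
  for (i in 1:n) for (f in 1:fp) {
    Zw[i, f] <- sum(Z[i, ] * W[, f])
  }
  lrelu <- function(x) if (x > 0) x else slope * x
  e <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    nb <- c(which(adj[i, ] > 0), i)
    for (j in nb) {
      e[i, j] <- lrelu(sum(phi * c(Zw[i, ], Zw[j, ])))
    }
  }
  alpha <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    nb <- which(!is.na(e[i, ]))
    alpha[i, nb] <- exp(e[i, nb]) / sum(exp(e[i, nb]))
  }
  list(e = e, alpha = alpha, Zw = Zw)
}

oracle_multi_head <- function(Z, heads, adj, mode, slope = 0.2) {
  n <- nrow(Z)
  outs <- lapply(heads, function(h) {
    sc <- oracle_gat_alpha(Z, h$W, h$phi, adj, slope)
    o <- matrix(0, n, ncol(h$W))
    for (i in 1:n) {
      nb <- which(!is.na(sc$alpha[i, ]))
      for (f in 1:ncol(h$W)) {
        o[i, f] <- sum(sc$alpha[i, nb] * sc$Zw[nb, f])
      }
    }
    o
  })
  if (mode == "concat") {
    do.call(cbind, lapply(outs, function(o) pmax(o, 0)))
  } else {
    m <- outs[[1]]
    if (length(outs) > 1) for (k in 2:length(outs)) m <- m + outs[[k]]
    pmax(m / length(outs), 0)
  }
}

oracle_conv_encode <- function(x, conv_W, conv_b, dense_W, dense_b) {
  w <- nrow(conv_W); nf <- ncol(conv_W)
  p <- length(x) - w + 1
  fmap <- matrix(0, p, nf)
  for (i in 1:p) for (j in 1:nf) {
    acc <- conv_b[j]
    for (l in 1:w) acc <- acc + x[i + l - 1] * conv_W[l, j]
    fmap[i, j] <- max(acc, 0)
  }
  flat <- numeric(p * nf)
  idx <- 1
  for (i in 1:p) for (j in 1:nf) { flat[idx] <- fmap[i, j]; idx <- idx + 1 }
  out <- numeric(ncol(dense_W))
  for (o in seq_along(out)) {
    out[o] <- max(sum(flat * dense_W[, o]) + dense_b[o], 0)
  }
  out
}

oracle_fusion <- function(h_proj, x_proj, gate_W, gate_b) {
  z <- c(h_proj, x_proj)
  d <- length(h_proj)
  g <- numeric(d)
  for (k in 1:d) g[k] <- 1 / (1 + exp(-(sum(z * gate_W[, k]) + gate_b[k])))
  g * h_proj + (1 - g) * x_proj
}

# All permutations of 1..n (exhaustive isomorphism search on tiny graphs).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Relabel the atoms of a molecular graph by a permutation.
permute_graph <- function(graph, perm) {
  g <- graph
  g$node_features <- graph$node_features[perm, , drop = FALSE]
  g$adjacency <- graph$adjacency[perm, perm, drop = FALSE]
  if (!is.null(graph$atoms)) g$atoms <- graph$atoms[perm, , drop = FALSE]
  g
}

rand_graph <- function(n, d = 4) {
  repeat {
    A <- matrix(0, n, n)
    if (n > 1) {
      for (i in 2:n) {
        j <- sample.int(i - 1, 1)
        A[i, j] <- A[j, i] <- 1
      }
      extra <- which(upper.tri(A) & A == 0)
      if (length(extra)) {
        on <- extra[stats::runif(length(extra)) < 0.3]
        A[on] <- 1
        A[cbind(col(A)[on], row(A)[on])] <- 1
      }
      A <- pmax(A, t(A))
    }
    diag(A) <- 0
    break
  }
  list(node_features = matrix(stats::rnorm(n * d), n, d), adjacency = A,
       num_atoms = n)
}
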