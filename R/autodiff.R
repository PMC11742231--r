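# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape is an environment collecting nodes in execution order; each node is an
# environment holding its value, an accumulated gradient, its parent nodes and
# a backward closure. Values are always numeric matrices (vectors are stored as
# one-column matrices). The op set is exactly what the model needs: dense and
# sparse matrix products, elementwise arithmetic and nonlinearities, column
# concatenation/slicing, row gather with scatter-add backward, segment softmax
# and segment-weighted sums for batched graphs, and an MSE loss.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    pname = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$pname <- pname
  ad_push(tape, node)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}

ad_const <- function(tape, x) ad_node(tape, as_mat(x))

ad_param <- function(tape, x, name) ad_node(tape, as_mat(x), pname = name)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' @keywords internal
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node)
  }
  grads <- list()
  for (i in seq_len(tape$n)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$pname) && !is.null(node$grad)) {
      grads[[node$pname]] <- if (is.null(grads[[node$pname]])) {
        node$grad
      } else {
        grads[[node$pname]] + node$grad
      }
    }
  }
  grads
}

op_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(node) {
    g <- node$grad
    ad_accum(node$parents[[1]], tcrossprod(g, node$parents[[2]]$value))
    ad_accum(node$parents[[2]], crossprod(node$parents[[1]]$value, g))
  })
}

# S is a constant sparse (or dense) matrix, not a node.
op_spmm <- function(tape, S, x) {
  ad_node(tape, as.matrix(S %*% x$value), list(x), function(node) {
    ad_accum(node$parents[[1]], as.matrix(Matrix::crossprod(S, node$grad)))
  })
}

op_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(node) {
    ad_accum(node$parents[[1]], node$grad)
    ad_accum(node$parents[[2]], node$grad)
  })
}

op_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(node) {
    ad_accum(node$parents[[1]], node$grad)
    ad_accum(node$parents[[2]], -node$grad)
  })
}

# Add a 1 x k bias row to every row of a.
op_bias <- function(tape, a, b) {
  v <- a$value
  ad_node(tape, v + rep(as.numeric(b$value), each = nrow(v)), list(a, b),
          function(node) {
    ad_accum(node$parents[[1]], node$grad)
    ad_accum(node$parents[[2]], matrix(colSums(node$grad), nrow = 1L))
  })
}

op_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(node) {
    ad_accum(node$parents[[1]], node$grad * node$parents[[2]]$value)
    ad_accum(node$parents[[2]], node$grad * node$parents[[1]]$value)
  })
}

# value = scale * a + shift, with constant scalars.
op_affine <- function(tape, a, scale = 1, shift = 0) {
  ad_node(tape, scale * a$value + shift, list(a), function(node) {
    ad_accum(node$parents[[1]], scale * node$grad)
  })
}

op_relu <- function(tape, a) {
  v <- a$value
  v[v < 0] <- 0
  ad_node(tape, v, list(a), function(node) {
    ad_accum(node$parents[[1]], node$grad * (node$value > 0))
  })
}

op_leaky_relu <- function(tape, a, slope = 0.2) {
  v <- a$value
  ad_node(tape, ifelse(v > 0, v, slope * v), list(a), function(node) {
    d <- ifelse(node$parents[[1]]$value > 0, 1, slope)
    ad_accum(node$parents[[1]], node$grad * d)
  })
}

op_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, list(a), function(node) {
    ad_accum(node$parents[[1]], node$grad * node$value * (1 - node$value))
  })
}

op_tanh <- function(tape, a) {
  ad_node(tape, tanh(a$value), list(a), function(node) {
    ad_accum(node$parents[[1]], node$grad * (1 - node$value^2))
  })
}

op_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), nodes, function(node) {
    for (k in seq_along(node$parents)) {
      ad_accum(node$parents[[k]],
               node$grad[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

op_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(node) {
    g <- matrix(0, nrow(node$parents[[1]]$value), ncol(node$parents[[1]]$value))
    g[, idx] <- node$grad
    ad_accum(node$parents[[1]], g)
  })
}

# Row gather (idx may repeat); backward is scatter-add.
op_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(node) {
    p <- node$parents[[1]]
    g <- matrix(0, nrow(p$value), ncol(p$value))
    agg <- rowsum(node$grad, group = idx)
    g[as.integer(rownames(agg)), ] <- agg
    ad_accum(p, g)
  })
}

# Bijective element permutation with a fixed output shape: out[i] = a[idx[i]]
# on the flattened (column-major) values. Used to flatten conv feature maps.
op_perm <- function(tape, a, idx, nrow_out, ncol_out) {
  v <- matrix(a$value[idx], nrow_out, ncol_out)
  ad_node(tape, v, list(a), function(node) {
    p <- node$parents[[1]]
    g <- numeric(length(p$value))
    g[idx] <- as.numeric(node$grad)
    ad_accum(p, matrix(g, nrow(p$value), ncol(p$value)))
  })
}

# Softmax along each row (small, fixed number of columns).
op_row_softmax <- function(tape, a) {
  v <- a$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(node) {
    al <- node$value
    g <- node$grad
    ad_accum(node$parents[[1]], al * (g - rowSums(g * al)))
  })
}

# Softmax of a column vector within segments (e.g. attention over the
# neighbors of each target node, or over the atoms of each molecule).
op_segment_softmax <- function(tape, e, seg) {
  v <- as.numeric(e$value)
  m <- tapply(v, seg, max)[as.character(seg)]
  ex <- exp(v - m)
  tot <- rowsum(ex, group = seg)
  al <- ex / tot[as.character(seg), 1L]
  ad_node(tape, matrix(al, ncol = 1L), list(e), function(node) {
    alv <- as.numeric(node$value)
    g <- as.numeric(node$grad)
    dot <- rowsum(g * alv, group = seg)
    ad_accum(node$parents[[1]],
             matrix(alv * (g - dot[as.character(seg), 1L]), ncol = 1L))
  })
}

# out[d, ] = sum over edges e with dst[e] = d of alpha[e] * feat[src[e], ].
op_edge_aggregate <- function(tape, alpha, feat, src, dst, n_out) {
  contrib <- feat$value[src, , drop = FALSE] * as.numeric(alpha$value)
  agg <- rowsum(contrib, group = dst)
  out <- matrix(0, n_out, ncol(feat$value))
  out[as.integer(rownames(agg)), ] <- agg
  ad_node(tape, out, list(alpha, feat), function(node) {
    a <- node$parents[[1]]
    f <- node$parents[[2]]
    gd <- node$grad[dst, , drop = FALSE]
    fs <- f$value[src, , drop = FALSE]
    ad_accum(a, matrix(rowSums(gd * fs), ncol = 1L))
    gf <- matrix(0, nrow(f$value), ncol(f$value))
    agg2 <- rowsum(gd * as.numeric(a$value), group = src)
    gf[as.integer(rownames(agg2)), ] <- agg2
    ad_accum(f, gf)
  })
}

# out[s, ] = sum over rows i with seg[i] = s of w[i] * x[i, ].
op_segment_wsum <- function(tape, w, x, seg, n_seg) {
  contrib <- x$value * as.numeric(w$value)
  agg <- rowsum(contrib, group = seg)
  out <- matrix(0, n_seg, ncol(x$value))
  out[as.integer(rownames(agg)), ] <- agg
  ad_node(tape, out, list(w, x), function(node) {
    wn <- node$parents[[1]]
    xn <- node$parents[[2]]
    gs <- node$grad[seg, , drop = FALSE]
    ad_accum(wn, matrix(rowSums(gs * xn$value), ncol = 1L))
    ad_accum(xn, gs * as.numeric(wn$value))
  })
}

# Multiply each row i of x by scalar v[i] (v is an n x 1 node).
op_scale_rows <- function(tape, x, v) {
  ad_node(tape, x$value * as.numeric(v$value), list(x, v), function(node) {
    xn <- node$parents[[1]]
    vn <- node$parents[[2]]
    ad_accum(xn, node$grad * as.numeric(vn$value))
    ad_accum(vn, matrix(rowSums(node$grad * xn$value), ncol = 1L))
  })
}

# Inverted dropout with a caller-supplied keep mask (so the caller owns RNG).
op_dropout <- function(tape, a, mask, keep_prob) {
  ad_node(tape, a$value * mask / keep_prob, list(a), function(node) {
    ad_accum(node$parents[[1]], node$grad * mask / keep_prob)
  })
}

op_mse <- function(tape, pred, target) {
  d <- pred$value - target
  ad_node(tape, matrix(mean(d^2), 1L, 1L), list(pred), function(node) {
    n <- length(d)
    ad_accum(node$parents[[1]], node$grad[1L] * 2 * d / n)
  })
}
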