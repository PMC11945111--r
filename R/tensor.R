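# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every tensor is an environment holding a numeric matrix `value`, an
# accumulated `grad`, its `parents` and a `bw` closure that maps the node's
# output gradient onto its parents. A forward pass builds the tape implicitly;
# tn_backward() topologically sorts it and pushes gradients back. Nodes whose
# parents are all constants are not recorded, so inference-only passes carry
# no tape overhead.

.tn_counter <- new.env(parent = emptyenv())
.tn_counter$id <- 0L

tn_next_id <- function() {
  .tn_counter$id <- .tn_counter$id + 1L
  .tn_counter$id
}

#' @noRd
tn <- function(value, parents = list(), bw = NULL, requires_grad = NULL) {
  if (!is.matrix(value)) value <- as.matrix(value)
  node <- new.env(parent = emptyenv())
  node$id <- tn_next_id()
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$bw <- bw
  node$requires_grad <- if (is.null(requires_grad)) {
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  } else {
    requires_grad
  }
  class(node) <- "moldistill_tensor"
  node
}

tn_param <- function(value) tn(value, requires_grad = TRUE)
tn_const <- function(value) tn(value, requires_grad = FALSE)

is_tn <- function(x) inherits(x, "moldistill_tensor")

#' @export
print.moldistill_tensor <- function(x, ...) {
  cat(sprintf(
    "<tensor %dx%d%s>\n", nrow(x$value), ncol(x$value),
    if (x$requires_grad) " grad" else ""
  ))
  invisible(x)
}

# Treat the scaffold-model branch as a constant target (stop-gradient).
tn_detach <- function(x) tn_const(x$value)

tn_accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse pass from a scalar (1x1) root. Gradients accumulate in $grad of
# every requires_grad node reachable from the root.
tn_backward <- function(root, grad = NULL) {
  stopifnot(is_tn(root))
  if (is.null(grad)) {
    stopifnot(length(root$value) == 1L)
    grad <- matrix(1, 1, 1)
  }
  # iterative topological sort (DFS with explicit stack)
  order <- vector("list", 64L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  assign(as.character(root$id), TRUE, envir = seen)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      key <- as.character(p$id)
      if (p$requires_grad && !is.null(p$bw) &&
          !exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- grad
  for (k in seq(n_ord, 1L)) {
    node <- order[[k]]
    if (!is.null(node$bw) && !is.null(node$grad)) node$bw(node, node$grad)
  }
  invisible(NULL)
}

## ---- primitive ops -------------------------------------------------------

tn_matmul <- function(a, b) {
  out <- tn(a$value %*% b$value, parents = list(a, b), bw = function(node, g) {
    tn_accum(node$parents[[1]], g %*% t(node$parents[[2]]$value))
    tn_accum(node$parents[[2]], t(node$parents[[1]]$value) %*% g)
  })
  out
}

# elementwise add; `b` may be a 1 x ncol bias row, broadcast over rows
tn_add <- function(a, b) {
  bv <- b$value
  if (nrow(bv) == 1L && nrow(a$value) > 1L) {
    val <- sweep(a$value, 2L, as.numeric(bv), "+")
    tn(val, parents = list(a, b), bw = function(node, g) {
      tn_accum(node$parents[[1]], g)
      tn_accum(node$parents[[2]], matrix(colSums(g), 1L))
    })
  } else {
    tn(a$value + bv, parents = list(a, b), bw = function(node, g) {
      tn_accum(node$parents[[1]], g)
      tn_accum(node$parents[[2]], g)
    })
  }
}

tn_sub <- function(a, b) {
  tn(a$value - b$value, parents = list(a, b), bw = function(node, g) {
    tn_accum(node$parents[[1]], g)
    tn_accum(node$parents[[2]], -g)
  })
}

tn_mul <- function(a, b) {
  # elementwise; `b` may be an n x 1 column, broadcast over columns
  bv <- b$value
  if (ncol(bv) == 1L && ncol(a$value) > 1L) {
    val <- a$value * as.numeric(bv)
    tn(val, parents = list(a, b), bw = function(node, g) {
      a <- node$parents[[1]]; b <- node$parents[[2]]
      tn_accum(a, g * as.numeric(b$value))
      tn_accum(b, matrix(rowSums(g * a$value), ncol = 1L))
    })
  } else {
    tn(a$value * bv, parents = list(a, b), bw = function(node, g) {
      tn_accum(node$parents[[1]], g * node$parents[[2]]$value)
      tn_accum(node$parents[[2]], g * node$parents[[1]]$value)
    })
  }
}

tn_scale <- function(a, s) {
  tn(a$value * s, parents = list(a), bw = function(node, g) {
    tn_accum(node$parents[[1]], g * s)
  })
}

tn_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  node <- tn(v, parents = list(a), bw = function(node, g) {
    tn_accum(node$parents[[1]], g * node$value * (1 - node$value))
  })
  node
}

tn_tanh <- function(a) {
  v <- tanh(a$value)
  tn(v, parents = list(a), bw = function(node, g) {
    tn_accum(node$parents[[1]], g * (1 - node$value^2))
  })
}

# exact GELU: x * Phi(x)
tn_gelu <- function(a) {
  x <- a$value
  phi <- stats::pnorm(x)
  tn(x * phi, parents = list(a), bw = function(node, g) {
    x <- node$parents[[1]]$value
    tn_accum(node$parents[[1]], g * (stats::pnorm(x) + x * stats::dnorm(x)))
  })
}

tn_exp <- function(a) {
  v <- exp(a$value)
  tn(v, parents = list(a), bw = function(node, g) {
    tn_accum(node$parents[[1]], g * node$value)
  })
}

tn_log <- function(a) {
  tn(log(a$value), parents = list(a), bw = function(node, g) {
    tn_accum(node$parents[[1]], g / node$parents[[1]]$value)
  })
}

tn_clamp <- function(a, lo, hi) {
  v <- pmin(pmax(a$value, lo), hi)
  inside <- (a$value > lo & a$value < hi) * 1
  tn(v, parents = list(a), bw = function(node, g) {
    tn_accum(node$parents[[1]], g * inside)
  })
}

# row-wise log-softmax
tn_log_softmax <- function(a) {
  x <- a$value
  m <- apply(x, 1L, max)
  z <- x - m
  lse <- log(rowSums(exp(z)))
  v <- z - lse
  tn(v, parents = list(a), bw = function(node, g) {
    p <- exp(node$value)
    tn_accum(node$parents[[1]], g - p * rowSums(g))
  })
}

tn_softmax <- function(a) {
  x <- a$value
  z <- exp(x - apply(x, 1L, max))
  v <- z / rowSums(z)
  tn(v, parents = list(a), bw = function(node, g) {
    p <- node$value
    tn_accum(node$parents[[1]], p * (g - rowSums(g * p)))
  })
}

# row-wise layer normalisation with learned gain/bias (1 x d each)
tn_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  var <- rowMeans(xc^2)
  inv <- 1 / sqrt(var + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2L, as.numeric(gamma$value), "*")
  out <- sweep(out, 2L, as.numeric(beta$value), "+")
  node <- tn(out, parents = list(x, gamma, beta), bw = function(node, g) {
    x <- node$parents[[1]]; gamma <- node$parents[[2]]; beta <- node$parents[[3]]
    d <- ncol(x$value)
    tn_accum(beta, matrix(colSums(g), 1L))
    tn_accum(gamma, matrix(colSums(g * node$xhat), 1L))
    gh <- sweep(g, 2L, as.numeric(gamma$value), "*")
    # dL/dx for layernorm: inv * (gh - mean(gh) - xhat * mean(gh * xhat))
    dx <- node$inv * (gh - rowMeans(gh) - node$xhat * rowMeans(gh * node$xhat))
    tn_accum(x, dx)
  })
  node$xhat <- xhat
  node$inv <- inv
  node
}

# gather rows of an embedding table; backward scatter-adds
tn_embed <- function(weight, ids) {
  v <- weight$value[ids, , drop = FALSE]
  tn(v, parents = list(weight), bw = function(node, g) {
    W <- node$parents[[1]]
    if (!W$requires_grad) return(invisible(NULL))
    dW <- matrix(0, nrow(W$value), ncol(W$value))
    agg <- rowsum(g, group = ids)
    dW[as.integer(rownames(agg)), ] <- agg
    tn_accum(W, dW)
  })
}

# select rows (all idx >= 1); backward scatter-adds
tn_rows <- function(a, idx) {
  tn(a$value[idx, , drop = FALSE], parents = list(a), bw = function(node, g) {
    A <- node$parents[[1]]
    dA <- matrix(0, nrow(A$value), ncol(A$value))
    agg <- rowsum(g, group = idx)
    dA[as.integer(rownames(agg)), ] <- agg
    tn_accum(A, dA)
  })
}

# select rows with idx == 0 mapping to zero rows (padding gather)
tn_rows_pad <- function(a, idx) {
  n <- length(idx)
  v <- matrix(0, n, ncol(a$value))
  nz <- idx > 0L
  v[nz, ] <- a$value[idx[nz], , drop = FALSE]
  tn(v, parents = list(a), bw = function(node, g) {
    A <- node$parents[[1]]
    dA <- matrix(0, nrow(A$value), ncol(A$value))
    if (any(nz)) {
      agg <- rowsum(g[nz, , drop = FALSE], group = idx[nz])
      dA[as.integer(rownames(agg)), ] <- agg
    }
    tn_accum(A, dA)
  })
}

tn_cbind <- function(a, b) {
  na <- ncol(a$value)
  tn(cbind(a$value, b$value), parents = list(a, b), bw = function(node, g) {
    tn_accum(node$parents[[1]], g[, seq_len(na), drop = FALSE])
    tn_accum(node$parents[[2]], g[, -seq_len(na), drop = FALSE])
  })
}

tn_cols <- function(a, cols) {
  tn(a$value[, cols, drop = FALSE], parents = list(a), bw = function(node, g) {
    A <- node$parents[[1]]
    dA <- matrix(0, nrow(A$value), ncol(A$value))
    dA[, cols] <- g
    tn_accum(A, dA)
  })
}

# mean over all entries -> 1x1 scalar node
tn_mean <- function(a) {
  n <- length(a$value)
  tn(matrix(mean(a$value), 1L, 1L), parents = list(a), bw = function(node, g) {
    A <- node$parents[[1]]
    tn_accum(A, matrix(as.numeric(g) / n, nrow(A$value), ncol(A$value)))
  })
}

# mean over rows of the row-sums -> 1x1 (used for masked per-position KL)
tn_mean_rowsums <- function(a) {
  n <- nrow(a$value)
  tn(matrix(mean(rowSums(a$value)), 1L, 1L), parents = list(a),
     bw = function(node, g) {
       A <- node$parents[[1]]
       tn_accum(A, matrix(as.numeric(g) / n, nrow(A$value), ncol(A$value)))
     })
}

# negative log-likelihood of target column per row, averaged
tn_nll <- function(logp, targets) {
  n <- nrow(logp$value)
  stopifnot(length(targets) == n)
  picks <- cbind(seq_len(n), targets)
  tn(matrix(-mean(logp$value[picks]), 1L, 1L), parents = list(logp),
     bw = function(node, g) {
       L <- node$parents[[1]]
       dL <- matrix(0, nrow(L$value), ncol(L$value))
       dL[picks] <- -as.numeric(g) / n
       tn_accum(L, dL)
     })
}

# inverted dropout; the keep-mask is drawn from R's RNG so seeded runs are
# reproducible. p = 0 is the identity.
tn_dropout <- function(a, p) {
  if (p <= 0) return(a)
  keep <- matrix(
    (stats::runif(length(a$value)) >= p) / (1 - p),
    nrow(a$value), ncol(a$value)
  )
  tn(a$value * keep, parents = list(a), bw = function(node, g) {
    tn_accum(node$parents[[1]], g * keep)
  })
}

## ---- fused multi-head attention ------------------------------------------

# q, k, v: flattened (sum of per-sequence lengths) x d tensors. `q_seq` and
# `kv_seq` are integer sequence labels per row; attention is computed within
# matching labels only. A single tape node; the per-sequence/per-head loops
# run in plain numeric code for speed.
tn_attention <- function(q, k, v, q_seq, kv_seq, n_heads, causal) {
  d <- ncol(q$value)
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  seqs <- unique(q_seq)
  q_idx <- split(seq_along(q_seq), q_seq)
  kv_idx <- split(seq_along(kv_seq), kv_seq)
  out <- matrix(0, nrow(q$value), d)
  probs <- vector("list", length(seqs) * n_heads)
  pi <- 0L
  for (s in seqs) {
    qi <- q_idx[[as.character(s)]]
    ki <- kv_idx[[as.character(s)]]
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- q$value[qi, cols, drop = FALSE]
      K <- k$value[ki, cols, drop = FALSE]
      V <- v$value[ki, cols, drop = FALSE]
      S <- tcrossprod(Q, K) * scale
      if (causal) S[upper.tri(S)] <- -Inf
      Z <- exp(S - apply(S, 1L, max))
      P <- Z / rowSums(Z)
      out[qi, cols] <- P %*% V
      pi <- pi + 1L
      probs[[pi]] <- P
    }
  }
  node <- tn(out, parents = list(q, k, v), bw = function(node, g) {
    q <- node$parents[[1]]; k <- node$parents[[2]]; v <- node$parents[[3]]
    dQ <- matrix(0, nrow(q$value), d)
    dK <- matrix(0, nrow(k$value), d)
    dV <- matrix(0, nrow(v$value), d)
    pi <- 0L
    for (s in seqs) {
      qi <- q_idx[[as.character(s)]]
      ki <- kv_idx[[as.character(s)]]
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        pi <- pi + 1L
        P <- node$probs[[pi]]
        G <- g[qi, cols, drop = FALSE]
        V <- v$value[ki, cols, drop = FALSE]
        dV[ki, cols] <- dV[ki, cols] + crossprod(P, G)
        dP <- tcrossprod(G, V)
        dS <- P * (dP - rowSums(dP * P))
        dQ[qi, cols] <- dQ[qi, cols] +
          (dS %*% k$value[ki, cols, drop = FALSE]) * scale
        dK[ki, cols] <- dK[ki, cols] +
          crossprod(dS, q$value[qi, cols, drop = FALSE]) * scale
      }
    }
    tn_accum(q, dQ)
    tn_accum(k, dK)
    tn_accum(v, dV)
  })
  node$probs <- probs
  node
}
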