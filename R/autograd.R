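# Minimal reverse-mode tape. Nodes are environments carrying a value, an
# accumulated gradient, parent links, and a pullback closure; only nodes
# reachable from a trainable parameter keep tape structure, so inference
# builds no graph.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$id <- 0

ag_new_id <- function() {
  .ag_counter$id <- .ag_counter$id + 1
  .ag_counter$id
}

ag_leaf <- function(value, requires = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$bw <- NULL
  n$requires <- requires
  n$id <- ag_new_id()
  class(n) <- "ag_node"
  n
}

#' @keywords internal
ag_const <- function(value) {
  if (inherits(value, "ag_node")) return(value)
  ag_leaf(value, FALSE)
}

ag_param <- function(value) ag_leaf(value, TRUE)

# `bw(g)` must return a list of gradients aligned with `parents`
# (NULL entries allowed for parents that do not require grad).
ag_op <- function(value, parents, bw) {
  req <- any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  if (!req) return(ag_leaf(value, FALSE))
  n <- ag_leaf(value, TRUE)
  n$parents <- parents
  n$bw <- bw
  n
}

# Reverse accumulation from a scalar root. Gradients of every node visited
# (parameters included) are reset first, so each backward pass starts clean.
ag_backward <- function(root) {
  topo <- vector("list", 64L)
  nt <- 0L
  seen <- new.env(parent = emptyenv())
  visit <- function(n) {
    key <- as.character(n$id)
    if (!is.null(seen[[key]]) || !isTRUE(n$requires)) return(invisible())
    seen[[key]] <- TRUE
    for (p in n$parents) visit(p)
    nt <<- nt + 1L
    if (nt > length(topo)) length(topo) <<- 2L * nt
    topo[[nt]] <<- n
    invisible()
  }
  visit(root)
  if (nt == 0L) return(invisible())
  for (k in seq_len(nt)) topo[[k]]$grad <- NULL
  root$grad <- 1
  for (k in rev(seq_len(nt))) {
    n <- topo[[k]]
    if (is.null(n$bw)) next
    gs <- n$bw(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (!isTRUE(p$requires) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible()
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

# ---- differentiable operations ------------------------------------------

ag_conv2d <- function(x, w, b, pad = c(0L, 0L), dilation = 1L) {
  x <- ag_const(x); w <- ag_const(w); b <- ag_const(b)
  pad <- rep(as.integer(pad), length.out = 2L)
  v <- cpp_conv2d_fwd(x$value, w$value, b$value, pad[1], pad[2],
                      as.integer(dilation))
  ag_op(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(x$value, w$value, g, pad[1], pad[2],
                        as.integer(dilation), isTRUE(x$requires))
    list(if (isTRUE(x$requires)) r$gx else NULL, r$gw, r$gb)
  })
}

ag_maxpool2 <- function(x) {
  x <- ag_const(x)
  r <- cpp_maxpool2_fwd(x$value)
  xdim <- dim(x$value)
  ag_op(r$y, list(x), function(g) list(cpp_maxpool2_bwd(r$idx, g, xdim)))
}

ag_upsample2 <- function(x) {
  x <- ag_const(x)
  xdim <- dim(x$value)
  ag_op(cpp_upsample2_fwd(x$value), list(x),
        function(g) list(cpp_upsample2_bwd(g, xdim)))
}

ag_relu <- function(x) {
  x <- ag_const(x)
  v <- x$value
  v[v < 0] <- 0
  ag_op(v, list(x), function(g) list(g * (x$value > 0)))
}

ag_sigmoid <- function(x) {
  x <- ag_const(x)
  s <- 1 / (1 + exp(-x$value))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_op(a$value * b$value, list(a, b),
        function(g) list(g * b$value, g * a$value))
}

# channel concatenation (dim 3 of H,W,C,N)
ag_concat <- function(nodes) {
  nodes <- lapply(nodes, ag_const)
  vals <- lapply(nodes, function(n) n$value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  ends <- cumsum(cs)
  starts <- c(1, head(ends, -1) + 1)
  ag_op(out, nodes, function(g) {
    lapply(seq_along(nodes), function(j)
      g[, , starts[j]:ends[j], , drop = FALSE])
  })
}

# mean over columns of each row -> H x 1 x C x N
ag_rowmean <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value)
  m <- rowMeans(aperm(x$value, c(1, 3, 4, 2)), dims = 3)
  dim(m) <- c(d[1], 1, d[3], d[4])
  ag_op(m, list(x), function(g) {
    gx <- g[, rep(1, d[2]), , , drop = FALSE] / d[2]
    list(gx)
  })
}

# mean over rows of each column -> 1 x W x C x N
ag_colmean <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value)
  m <- colMeans(x$value, dims = 1)
  dim(m) <- c(1, d[2], d[3], d[4])
  ag_op(m, list(x), function(g) {
    gx <- g[rep(1, d[1]), , , , drop = FALSE] / d[1]
    list(gx)
  })
}

# broadcast H x 1 -> H x W ("expand left-right")
ag_expand_w <- function(x, w) {
  x <- ag_const(x)
  v <- x$value[, rep(1, w), , , drop = FALSE]
  ag_op(v, list(x), function(g) {
    s <- rowSums(aperm(g, c(1, 3, 4, 2)), dims = 3)
    dim(s) <- dim(x$value)
    list(s)
  })
}

# broadcast 1 x W -> H x W ("expand up-down")
ag_expand_h <- function(x, h) {
  x <- ag_const(x)
  v <- x$value[rep(1, h), , , , drop = FALSE]
  ag_op(v, list(x), function(g) {
    s <- colSums(g, dims = 1)
    dim(s) <- dim(x$value)
    list(s)
  })
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# holding running mean/var used at inference time.
ag_batchnorm <- function(x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  x <- ag_const(x); gamma <- ag_const(gamma); beta <- ag_const(beta)
  d <- dim(x$value)
  C <- d[3]
  m <- prod(d[c(1, 2, 4)])
  xp <- aperm(x$value, c(1, 2, 4, 3))
  M <- matrix(xp, ncol = C)
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  Mh <- sweep(M, 2, mu) * rep(istd, each = m)
  Y <- sweep(Mh * rep(gamma$value, each = m), 2, beta$value, `+`)
  y <- aperm(array(Y, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  ag_op(y, list(x, gamma, beta), function(g) {
    Gp <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    dgamma <- colSums(Gp * Mh)
    dbeta <- colSums(Gp)
    Dh <- Gp * rep(gamma$value, each = m)
    if (training) {
      Dx <- sweep(Dh, 2, colMeans(Dh)) - Mh * rep(colMeans(Dh * Mh), each = m)
      Dx <- Dx * rep(istd, each = m)
    } else {
      Dx <- Dh * rep(istd, each = m)
    }
    gx <- aperm(array(Dx, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(gx, dgamma, dbeta)
  })
}

# 2x2/stride-2 transposed convolution: each input pixel maps linearly onto a
# 2x2 output block; implemented as four 1x1 projections + interleave.
ag_conv_transpose2 <- function(x, w, b) {
  x <- ag_const(x); w <- ag_const(w); b <- ag_const(b)
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(w$value)[4]
  Mx <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = Cin)
  y <- array(0, c(2 * H, 2 * W, Cout, N))
  for (a in 1:2) for (bb in 1:2) {
    Wab <- matrix(w$value[a, bb, , ], Cin, Cout)
    Yab <- sweep(Mx %*% Wab, 2, b$value, `+`)
    y[seq(a, 2 * H, 2), seq(bb, 2 * W, 2), , ] <-
      aperm(array(Yab, c(H, W, N, Cout)), c(1, 2, 4, 3))
  }
  ag_op(y, list(x, w, b), function(g) {
    gxM <- matrix(0, nrow(Mx), Cin)
    gw <- array(0, dim(w$value))
    gb <- numeric(Cout)
    for (a in 1:2) for (bb in 1:2) {
      Gab <- matrix(aperm(g[seq(a, 2 * H, 2), seq(bb, 2 * W, 2), , ,
                            drop = FALSE], c(1, 2, 4, 3)), ncol = Cout)
      Wab <- matrix(w$value[a, bb, , ], Cin, Cout)
      gw[a, bb, , ] <- crossprod(Mx, Gab)
      gb <- gb + colSums(Gab)
      gxM <- gxM + Gab %*% t(Wab)
    }
    gx <- aperm(array(gxM, c(H, W, N, Cin)), c(1, 2, 4, 3))
    list(gx, gw, gb)
  })
}

# Mean softmax cross-entropy over all pixels; labels in 0..K-1, layout H,W,N.
ag_softmax_ce <- function(logits, labels) {
  logits <- ag_const(logits)
  d <- dim(logits$value)
  K <- d[3]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= K))
    stop("labels must lie in 0..", K - 1L, call. = FALSE)
  M <- matrix(aperm(logits$value, c(1, 2, 4, 3)), ncol = K)
  P <- nrow(M)
  mx <- as.vector(Reduce(pmax, asplit(M, 2)))
  lse <- mx + log(rowSums(exp(M - mx)))
  picked <- M[cbind(seq_len(P), lab + 1L)]
  loss <- mean(lse - picked)
  ag_op(loss, list(logits), function(g) {
    S <- exp(M - lse)
    S[cbind(seq_len(P), lab + 1L)] <- S[cbind(seq_len(P), lab + 1L)] - 1
    S <- S * (g / P)
    gx <- aperm(array(S, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
    list(gx)
  })
}
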