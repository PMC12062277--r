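# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every node is an environment holding `value` (a numeric matrix), its
# `parents`, and a `backfn` mapping the incoming gradient to one gradient per
# parent. Leaves created with ad_param()/ad_input() retain their gradient
# after ad_backward(); ad_const() leaves do not. Node ids increase at
# creation, so parents always precede children and sorting reachable nodes by
# decreasing id yields a reverse topological order.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_new <- function(value, parents = list(), backfn = NULL, track = FALSE) {
  # force promises before taking an id: R evaluates arguments lazily, and a
  # nested constructor call must create its subtree (smaller ids) first for
  # the decreasing-id backward order to be topological
  force(parents)
  force(value)
  .ad_env$counter <- .ad_env$counter + 1L
  node <- new.env(parent = emptyenv())
  node$id <- .ad_env$counter
  node$value <- value
  node$parents <- parents
  node$backfn <- backfn
  node$grad <- NULL
  node$track <- track
  class(node) <- "adnode"
  node
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

#' @keywords internal
ad_const <- function(x) ad_new(as_mat(x))

#' @keywords internal
ad_param <- function(x) ad_new(as_mat(x), track = TRUE)

ad_input <- ad_param

is_adnode <- function(x) inherits(x, "adnode")

ad_value <- function(x) if (is_adnode(x)) x$value else x

#' Run reverse-mode differentiation from an output node
#'
#' Accumulates gradients into every tracked leaf reachable from `out`.
#' @param out an `adnode`; `seed` a matrix conformable with `out$value`
#'   (defaults to all ones, i.e. the gradient of `sum(out)`).
#' @keywords internal
ad_backward <- function(out, seed = NULL) {
  if (is.null(seed)) seed <- matrix(1, nrow(out$value), ncol(out$value))
  # collect reachable nodes
  stack <- list(out)
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n_nodes)]
  ord <- order(vapply(nodes, function(nd) nd$id, integer(1)), decreasing = TRUE)
  nodes <- nodes[ord]
  out$grad <- seed
  for (nd in nodes) {
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(out)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive operations ---------------------------------------------------

ad_mm <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_new(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ad_spmm <- function(M, a) {
  # M: constant sparse (or dense) matrix, not differentiated
  ad_new(as.matrix(M %*% a$value), list(a), function(g) {
    list(as.matrix(Matrix::crossprod(M, g)))
  })
}

ad_add <- function(a, b) {
  ad_new(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_new(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_neg <- function(a) ad_new(-a$value, list(a), function(g) list(-g))

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_new(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_new(av / bv, list(a, b), function(g) list(g / bv, -g * av / bv^2))
}

ad_smul <- function(a, s) ad_new(a$value * s, list(a), function(g) list(g * s))

ad_sadd <- function(a, s) ad_new(a$value + s, list(a), function(g) list(g))

# add a 1 x C (or length C) node row-wise to an n x C node
ad_addrow <- function(a, v) {
  vv <- as.vector(v$value)
  n <- nrow(a$value)
  vdim <- dim(v$value)
  ad_new(a$value + matrix(vv, n, length(vv), byrow = TRUE), list(a, v),
         function(g) list(g, array(colSums(g), vdim)))
}

# add an n x 1 node column-wise (broadcast across columns)
ad_addcol <- function(a, v) {
  ad_new(a$value + as.vector(v$value), list(a, v), function(g) {
    list(g, matrix(rowSums(g), ncol = 1L))
  })
}

# scale row i of a by v[i] (v: n x 1 node)
ad_rowscale <- function(a, v) {
  av <- a$value; vv <- as.vector(v$value)
  ad_new(av * vv, list(a, v), function(g) {
    list(g * vv, matrix(rowSums(g * av), ncol = 1L))
  })
}

# scale column j of a by v[j] (v: 1 x C node)
ad_colscale <- function(a, v) {
  av <- a$value; vv <- as.vector(v$value)
  n <- nrow(av)
  vdim <- dim(v$value)
  vm <- matrix(vv, n, length(vv), byrow = TRUE)
  ad_new(av * vm, list(a, v), function(g) {
    list(g * vm, array(colSums(g * av), vdim))
  })
}

ad_relu <- function(a) {
  m <- a$value > 0
  ad_new(a$value * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_new(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_new(v, list(a), function(g) list(g * (1 - v^2)))
}

ad_exp <- function(a) {
  v <- exp(a$value)
  ad_new(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  av <- a$value
  ad_new(log(av), list(a), function(g) list(g / av))
}

ad_sq <- function(a) {
  av <- a$value
  ad_new(av^2, list(a), function(g) list(2 * g * av))
}

ad_powc <- function(a, p) {
  av <- a$value
  ad_new(av^p, list(a), function(g) list(g * p * av^(p - 1)))
}

ad_abs <- function(a) {
  av <- a$value
  ad_new(abs(av), list(a), function(g) list(g * sign(av)))
}

ad_sum <- function(a) {
  d <- dim(a$value)
  ad_new(matrix(sum(a$value)), list(a), function(g) {
    matrix_g <- matrix(as.numeric(g), d[1], d[2])
    list(matrix_g)
  })
}

ad_mean <- function(a) {
  d <- dim(a$value); n <- prod(d)
  ad_new(matrix(mean(a$value)), list(a), function(g) {
    list(matrix(as.numeric(g) / n, d[1], d[2]))
  })
}

ad_rowsums <- function(a) {
  C <- ncol(a$value)
  ad_new(matrix(rowSums(a$value), ncol = 1L), list(a), function(g) {
    list(matrix(as.vector(g), nrow(a$value), C))
  })
}

ad_colsums <- function(a) {
  n <- nrow(a$value)
  ad_new(matrix(colSums(a$value), 1L), list(a), function(g) {
    list(matrix(as.vector(g), n, ncol(a$value), byrow = TRUE))
  })
}

ad_rowmeans <- function(a) ad_smul(ad_rowsums(a), 1 / ncol(a$value))

ad_colmeans <- function(a) ad_smul(ad_colsums(a), 1 / nrow(a$value))

ad_t <- function(a) ad_new(t(a$value), list(a), function(g) list(t(g)))

ad_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ad_new(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

ad_logsumexp_rows <- function(a) {
  mx <- apply(a$value, 1L, max)
  z <- a$value - mx
  e <- exp(z)
  se <- rowSums(e)
  soft <- e / se
  ad_new(matrix(log(se) + mx, ncol = 1L), list(a), function(g) {
    list(as.vector(g) * soft)
  })
}

ad_rows <- function(a, idx) {
  n <- nrow(a$value); C <- ncol(a$value)
  ad_new(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, n, C)
    agg <- rowsum(g, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

# pick a[i, j[i]] for each row i -> n x 1
ad_select <- function(a, j) {
  n <- nrow(a$value); C <- ncol(a$value)
  ii <- cbind(seq_len(n), j)
  ad_new(matrix(a$value[ii], ncol = 1L), list(a), function(g) {
    out <- matrix(0, n, C)
    out[ii] <- as.vector(g)
    list(out)
  })
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(nd) nd$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_new(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_rbind <- function(nodes) {
  vals <- lapply(nodes, function(nd) nd$value)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_new(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

# rowSums(a * b) -> n x 1
ad_rowdot <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_new(matrix(rowSums(av * bv), ncol = 1L), list(a, b), function(g) {
    gv <- as.vector(g)
    list(gv * bv, gv * av)
  })
}

# sum rows of a within groups; group: integer vector 1..ngroups, one per row
ad_rowsum_group <- function(a, group, ngroups) {
  ad_new({
    out <- matrix(0, ngroups, ncol(a$value))
    agg <- rowsum(a$value, group = group)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }, list(a), function(g) {
    list(g[group, , drop = FALSE])
  })
}

# ---- numerical gradient check (used by the test suite) ----------------------

ad_num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(as_mat(x)))
  xm <- as_mat(x)
  for (i in seq_along(xm)) {
    xp <- xm; xp[i] <- xp[i] + eps
    xn <- xm; xn[i] <- xn[i] - eps
    g[i] <- (f(xp) - f(xn)) / (2 * eps)
  }
  g
}

# multiply a node elementwise by a 1x1 node (scalar broadcast)
ad_scale1 <- function(a, s) {
  sv <- as.numeric(s$value)
  av <- a$value
  ad_new(av * sv, list(a, s), function(g) {
    list(g * sv, matrix(sum(g * av)))
  })
}
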