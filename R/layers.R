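# Layer building blocks on top of the autodiff engine. Parameters are
# persistent ad_param leaves collected into flat named lists so the optimizer
# can walk them; forward passes build a fresh graph over the same leaves.

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

new_param <- function(value) ad_param(as_mat(value))

# flatten a nested list of adnodes into a named flat list; unnamed list
# elements are keyed by position
collect_params <- function(x, prefix = "") {
  out <- list()
  keys <- names(x) %||% rep("", length(x))
  for (i in seq_along(x)) {
    el <- x[[i]]
    nm <- if (nzchar(keys[i])) keys[i] else as.character(i)
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is_adnode(el)) {
      out[[key]] <- el
    } else if (is.list(el)) {
      out <- c(out, collect_params(el, key))
    }
  }
  out
}

linear_fw <- function(x, W, b = NULL) {
  out <- ad_mm(x, W)
  if (!is.null(b)) out <- ad_addrow(out, b)
  out
}

# layer normalization across columns of each row, with learnable gain/bias
layernorm_fw <- function(x, gain, bias, eps = 1e-5) {
  mu <- ad_rowmeans(x)
  xc <- ad_addcol(x, ad_neg(mu))
  v <- ad_rowmeans(ad_sq(xc))
  inv <- ad_powc(ad_sadd(v, eps), -0.5)
  xn <- ad_rowscale(xc, inv)
  ad_addrow(ad_colscale(xn, gain), bias)
}

# batch normalization over (optionally mask-weighted) rows, per column.
# `state` is an environment carrying running statistics; in eval mode the
# running statistics are used so outputs are deterministic per sample.
batchnorm_fw <- function(x, gain, bias, state, training, weights = NULL,
                         eps = 1e-5, momentum = 0.1) {
  C <- ncol(x$value)
  if (is.null(state$mean)) {
    state$mean <- rep(0, C)
    state$var <- rep(1, C)
  }
  if (training) {
    if (is.null(weights)) {
      mu <- ad_colmeans(x)
      xc <- ad_addrow(x, ad_neg(mu))
      v <- ad_colmeans(ad_sq(xc))
    } else {
      wrow <- matrix(weights / sum(weights), 1L)
      mu <- ad_mm(ad_const(wrow), x)
      xc <- ad_addrow(x, ad_neg(mu))
      v <- ad_mm(ad_const(wrow), ad_sq(xc))
    }
    state$mean <- (1 - momentum) * state$mean + momentum * as.vector(mu$value)
    state$var <- (1 - momentum) * state$var + momentum * as.vector(v$value)
    inv <- ad_powc(ad_sadd(v, eps), -0.5)   # 1 x C in both branches
    xn <- ad_colscale(xc, inv)
  } else {
    # constant shift: gradient passes through unchanged
    xc <- ad_new(sweep(x$value, 2L, state$mean, "-"), list(x), function(g) list(g))
    scale <- 1 / sqrt(state$var + eps)
    xn <- ad_new(sweep(xc$value, 2L, scale, "*"), list(xc), function(g) {
      list(sweep(g, 2L, scale, "*"))
    })
  }
  ad_addrow(ad_colscale(xn, gain), bias)
}

# select columns of a node
ad_cols <- function(a, idx) {
  n <- nrow(a$value); C <- ncol(a$value)
  ad_new(a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, n, C)
    out[, idx] <- out[, idx] + g
    list(out)
  })
}

# flatten an n x d node row-major into an (n*d) x 1 node
ad_flatten_rows <- function(a) {
  n <- nrow(a$value); d <- ncol(a$value)
  ad_new(matrix(as.vector(t(a$value)), ncol = 1L), list(a), function(g) {
    list(matrix(as.vector(g), n, d, byrow = TRUE))
  })
}

# ---- optimizer --------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p$value)))
  st$v <- lapply(params, function(p) array(0, dim(p$value)))
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (k in seq_along(st$params)) {
    p <- st$params[[k]]
    if (is.null(p$grad)) next
    g <- p$grad
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g^2
    mhat <- st$m[[k]] / c1
    vhat <- st$v[[k]] / c2
    p$value <- p$value - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  ad_zero_grads(st$params)
  invisible(st)
}

# numeric snapshot / restore of parameter values (checkpointing)
params_snapshot <- function(params) lapply(params, function(p) p$value)

params_restore <- function(params, snap) {
  for (k in names(snap)) params[[k]]$value <- snap[[k]]
  invisible(params)
}
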