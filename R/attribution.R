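#' Wrap a plain function as an attributable model
#'
#' Adapts any (twice-)differentiable function `f(x) -> scores` for
#' [integrated_gradients()] and [integrated_hessians()]. Analytic `grad`
#' and `hess` may be supplied; otherwise central finite differences of `f`
#' (and of `grad`) are used.
#'
#' @param f function mapping a numeric vector to a score vector.
#' @param grad optional `function(x, class)` returning the gradient of the
#'   class score.
#' @param hess optional `function(x, class)` returning the Hessian.
#' @param eps finite-difference step.
#' @return an object of class `ig_model`.
#' @export
ig_model <- function(f, grad = NULL, hess = NULL, eps = 1e-5) {
  force(f); force(eps)
  g <- grad %||% function(x, class) {
    vapply(seq_along(x), function(i) {
      xp <- x; xp[i] <- xp[i] + eps
      xn <- x; xn[i] <- xn[i] - eps
      (f(xp)[class] - f(xn)[class]) / (2 * eps)
    }, numeric(1))
  }
  h <- hess %||% function(x, class) {
    d <- length(x)
    H <- matrix(0, d, d)
    for (j in seq_len(d)) {
      xp <- x; xp[j] <- xp[j] + eps
      xn <- x; xn[j] <- xn[j] - eps
      H[, j] <- (g(xp, class) - g(xn, class)) / (2 * eps)
    }
    (H + t(H)) / 2
  }
  structure(list(f = f, grad = g, hess = h), class = "ig_model")
}

#' Per-feature baseline from training controls
#'
#' The reference input for path attributions: the feature-wise mean over
#' the control (label 0) samples of the training set.
#'
#' @param training_data samples x features matrix.
#' @param labels 0/1 labels aligned to rows.
#' @return numeric baseline vector (length = features).
#' @export
control_mean_baseline <- function(training_data, labels) {
  training_data <- as.matrix(training_data)
  ctrl <- labels == 0
  if (!any(ctrl)) abort("no control samples to build a baseline from.")
  colMeans(training_data[ctrl, , drop = FALSE])
}

midpoints <- function(n_steps) (seq_len(n_steps) - 0.5) / n_steps

#' Integrated gradients attribution
#'
#' Path-integral attribution of a model's class score to its input
#' features: `phi_i = (x_i - x'_i) * integral_0^1 df_c/dx_i` along the
#' straight path from the baseline `x'` to `x`, approximated with a
#' midpoint Riemann sum over `n_steps` interpolants. The attributions
#' satisfy completeness: they sum (up to quadrature error) to
#' `f_c(x) - f_c(x')`.
#'
#' @param model an `ig_model`, trained `omics_gnn`, or `token_transformer`.
#' @param x input: numeric vector (`ig_model`), named list of modality
#'   vectors (`omics_gnn`), or K x m token matrix (`token_transformer`).
#' @param baseline same shape as `x` (e.g. [control_mean_baseline()]).
#' @param class_label 0-based class attributed (1 = disease class).
#' @param n_steps quadrature steps.
#' @param ... method-specific arguments.
#' @return numeric vector of per-feature attributions `phi` (for
#'   `omics_gnn`, a tibble with `modality`, `feature`, `phi`).
#' @export
integrated_gradients <- function(model, x, baseline, class_label = 1L,
                                 n_steps = 50L, ...) {
  UseMethod("integrated_gradients")
}

#' @export
integrated_gradients.ig_model <- function(model, x, baseline, class_label = 1L,
                                          n_steps = 50L, ...) {
  stopifnot(length(x) == length(baseline), n_steps >= 1L)
  cls <- class_label + 1L
  u <- x - baseline
  alphas <- midpoints(n_steps)
  gsum <- rep(0, length(x))
  for (a in alphas) {
    gi <- model$grad(baseline + a * u, cls)
    if (any(!is.finite(gi))) {
      abort(sprintf("non-finite gradient at interpolation alpha=%.4f", a),
            class = "graphomix_numeric_error")
    }
    gsum <- gsum + gi
  }
  phi <- u * gsum / n_steps
  attr(phi, "baseline") <- baseline
  attr(phi, "n_steps") <- n_steps
  attr(phi, "class_label") <- class_label
  phi
}

# gradient of the chosen score wrt every modality input for a batch;
# x: named list of n x d_i matrices. Returns list of gradient matrices.
model_input_gradients <- function(model, x, source, class_label) {
  fw <- model_forward(model, x, training = FALSE)
  logits <- if (source == "integrated") {
    if (is.null(fw$int)) abort("integrated score requires all modalities.")
    fw$int$logits
  } else fw$uni[[source]]
  seed <- matrix(0, nrow(logits$value), ncol(logits$value))
  seed[, class_label + 1L] <- 1
  ad_backward(logits, seed)
  grads <- lapply(fw$x_nodes, function(nd) nd$grad)
  ad_zero_grads(model$flat)
  grads
}

#' @export
integrated_gradients.omics_gnn <- function(model, x, baseline, class_label = 1L,
                                           n_steps = 50L,
                                           source = "integrated", ...) {
  if (!is.list(x)) abort("`x` must be a named list of modality vectors.")
  mods <- names(x)
  alphas <- midpoints(n_steps)
  # batch all interpolants in one forward/backward
  xin <- lapply(mods, function(nm) {
    u <- x[[nm]] - baseline[[nm]]
    do.call(rbind, lapply(alphas, function(a) baseline[[nm]] + a * u))
  })
  names(xin) <- mods
  grads <- model_input_gradients(model, xin, source, class_label)
  out <- lapply(mods, function(nm) {
    u <- x[[nm]] - baseline[[nm]]
    phi <- u * colMeans(grads[[nm]])
    tibble(modality = nm,
           feature = model$encoders[[nm]]$spec$feature_ids,
           phi = as.vector(phi))
  })
  dplyr::bind_rows(out)
}

#' Integrated-gradient attributions for many cohort samples
#'
#' Computes per-sample, per-feature attributions of the chosen score
#' against a control-mean baseline, batching samples and interpolation
#' steps through the model.
#'
#' @param model trained `omics_gnn`.
#' @param cohort an `omics_cohort`.
#' @param ids samples to attribute (must carry the required modalities).
#' @param baselines named list of per-modality baseline vectors.
#' @param source `"integrated"` or a modality name.
#' @param class_label 0-based class (default 1 = disease).
#' @param n_steps quadrature steps.
#' @param chunk maximum forward-batch rows.
#' @return tibble: `sample_id`, `modality`, `feature`, `phi`.
#' @export
attribute_cohort <- function(model, cohort, ids, baselines,
                             source = "integrated", class_label = 1L,
                             n_steps = 16L, chunk = 4096L) {
  mods <- if (source == "integrated") model$modalities else source
  alphas <- midpoints(n_steps)
  n <- length(ids)
  per_chunk <- max(1L, chunk %/% n_steps)
  out <- vector("list", 0L)
  for (start in seq(1L, n, by = per_chunk)) {
    cids <- ids[start:min(start + per_chunk - 1L, n)]
    nc <- length(cids)
    xin <- lapply(mods, function(nm) {
      X <- cohort$features[[nm]][match(cids, rownames(cohort$features[[nm]])), , drop = FALSE]
      U <- sweep(X, 2L, baselines[[nm]], "-")
      # rows ordered sample-major: sample 1's steps, then sample 2's ...
      rows <- U[rep(seq_len(nc), each = n_steps), , drop = FALSE] *
        rep(alphas, times = nc)
      sweep(rows, 2L, baselines[[nm]], "+")
    })
    names(xin) <- mods
    grads <- model_input_gradients(model, xin, source, class_label)
    for (nm in mods) {
      X <- cohort$features[[nm]][match(cids, rownames(cohort$features[[nm]])), , drop = FALSE]
      U <- sweep(X, 2L, baselines[[nm]], "-")
      gmean <- rowsum(grads[[nm]], rep(seq_len(nc), each = n_steps)) / n_steps
      phi <- U * gmean
      out[[length(out) + 1L]] <- tibble(
        sample_id = rep(cids, each = ncol(phi)),
        modality = nm,
        feature = rep(colnames(X), times = nc),
        phi = as.vector(t(phi))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Integrated Hessians: pairwise feature interactions
#'
#' Extends integrated gradients to pairwise interactions: the off-diagonal
#' interaction of features i and j is the double path integral of the
#' Hessian of the class score, weighted by `alpha * beta` and the feature
#' displacements, approximated by a nested midpoint rule; the
#' self-interaction is defined as the feature's integrated gradient minus
#' all its pairwise interactions, so every row of the interaction matrix
#' sums to the feature's attribution.
#'
#' @inheritParams integrated_gradients
#' @param n_steps quadrature steps per axis.
#' @return object of class `interaction_matrix`: list with `Gamma`
#'   (features x features), `phi`, `baseline`, `n_steps`.
#' @export
integrated_hessians <- function(model, x, baseline, class_label = 1L,
                                n_steps = 50L, ...) {
  UseMethod("integrated_hessians")
}

#' @export
integrated_hessians.ig_model <- function(model, x, baseline, class_label = 1L,
                                         n_steps = 50L, ...) {
  cls <- class_label + 1L
  d <- length(x)
  u <- x - baseline
  ab <- midpoints(n_steps)
  Hacc <- matrix(0, d, d)
  for (a in ab) {
    for (b in ab) {
      Hacc <- Hacc + a * b * model$hess(baseline + a * b * u, cls)
    }
  }
  Gamma <- outer(u, u) * Hacc / n_steps^2
  phi <- as.numeric(integrated_gradients(model, x, baseline, class_label, n_steps))
  diag(Gamma) <- 0
  diag(Gamma) <- phi - rowSums(Gamma)
  structure(list(Gamma = Gamma, phi = phi, baseline = baseline,
                 n_steps = n_steps), class = "interaction_matrix")
}

# ---- token-level models -----------------------------------------------------

# logits for flattened token inputs (rows = samples, K*m columns)
token_logits_fw <- function(int, flat_node, K, m) {
  tokens <- lapply(seq_len(K), function(i) {
    ad_cols(flat_node, ((i - 1L) * m + 1L):(i * m))
  })
  integrator_logits_fw(int, tokens)
}

#' A set transformer over fixed token inputs
#'
#' A standalone classifier whose inputs are K fixed-length tokens (for
#' example per-biodomain class-token embeddings); a learnable class token
#' is prepended and the transformer's class-token output is mapped to class
#' scores. Used as the auxiliary model for cross-graph interaction
#' analysis.
#'
#' @param K number of input tokens.
#' @param m token dimension.
#' @param cfg an [integrator_config()].
#' @param seed initialization seed.
#' @return an object of class `token_transformer`.
#' @export
token_transformer <- function(K, m, cfg = integrator_config(), seed = 1L) {
  int <- integrator_new(m, cfg, seed = seed)
  structure(list(int = int, K = K, m = m, flat = int$flat,
                 trained = FALSE), class = "token_transformer")
}

#' Train a token-level set transformer
#'
#' @param model a [token_transformer()].
#' @param tokens n x (K*m) matrix of flattened token sets.
#' @param labels 0/1 labels.
#' @param epochs,batch_size,lr optimizer settings.
#' @param seed shuffling seed.
#' @param class_weights optional per-class weights.
#' @return the trained model (with a `log` tibble).
#' @export
train_token_transformer <- function(model, tokens, labels, epochs = 50L,
                                    batch_size = 32L, lr = 1e-3, seed = 1L,
                                    class_weights = NULL) {
  tokens <- as.matrix(tokens)
  n <- nrow(tokens)
  class_w <- class_weights %||% class_weights_from_labels(labels)
  opt <- adam_new(model$flat, lr = lr)
  logs <- list()
  for (ep in seq_len(epochs)) {
    perm <- with_seed(child_seed(seed, ep), sample.int(n))
    for (b in seq_len(ceiling(n / batch_size))) {
      bi <- perm[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      flat_node <- ad_const(tokens[bi, , drop = FALSE])
      out <- token_logits_fw(model$int, flat_node, model$K, model$m)
      loss <- ce_loss_fw(out$logits, labels[bi], class_w)
      ad_backward(loss)
      adam_step(opt)
      logs[[length(logs) + 1L]] <- tibble(epoch = ep, batch = b,
                                          loss = as.numeric(loss$value))
    }
  }
  model$log <- dplyr::bind_rows(logs)
  model$trained <- TRUE
  model
}

# batched gradients of the class score of a token transformer wrt inputs
token_input_gradients <- function(model, rows, class_label) {
  nd <- ad_input(rows)
  out <- token_logits_fw(model$int, nd, model$K, model$m)
  seed <- matrix(0, nrow(rows), ncol(out$logits$value))
  seed[, class_label + 1L] <- 1
  ad_backward(out$logits, seed)
  g <- nd$grad
  ad_zero_grads(model$flat)
  g
}

#' @export
integrated_gradients.token_transformer <- function(model, x, baseline,
                                                   class_label = 1L,
                                                   n_steps = 50L, ...) {
  xv <- as.vector(t(x)); bv <- as.vector(t(baseline))
  u <- xv - bv
  rows <- do.call(rbind, lapply(midpoints(n_steps), function(a) bv + a * u))
  g <- token_input_gradients(model, rows, class_label)
  u * colMeans(g)
}

#' Token-level interaction scores from integrated Hessians
#'
#' Computes the full interaction matrix over the flattened token dimensions
#' (Hessian entries estimated by forward differences of the batched
#' analytic gradient along the quadrature path) and aggregates it to token
#' level by summing all entries between the dimensions of each token pair.
#' Token-level row sums equal the token-level integrated-gradient
#' attributions by construction.
#'
#' @param model a trained [token_transformer()].
#' @param token_inputs K x m matrix of input tokens.
#' @param baseline_tokens K x m baseline.
#' @param class_label 0-based class attributed.
#' @param n_steps quadrature steps per axis.
#' @param fd_eps forward-difference step.
#' @return list with `token_matrix` (K x K), `Gamma` (d x d over flattened
#'   dims), `phi` (flattened IG), and `token_phi`.
#' @export
token_interactions <- function(model, token_inputs, baseline_tokens,
                               class_label = 1L, n_steps = 10L,
                               fd_eps = 1e-4) {
  K <- model$K; m <- model$m
  xv <- as.vector(t(token_inputs)); bv <- as.vector(t(baseline_tokens))
  d <- length(xv)
  u <- xv - bv
  ab <- midpoints(n_steps)
  pts <- as.vector(outer(ab, ab))          # alpha*beta products
  wts <- pts                                # alpha*beta weights
  # evaluate gradient at each path point and at d forward-shifted copies
  base_rows <- do.call(rbind, lapply(pts, function(t) bv + t * u))
  Hacc <- matrix(0, d, d)
  g0 <- token_input_gradients(model, base_rows, class_label)
  for (j in seq_len(d)) {
    shifted <- base_rows
    shifted[, j] <- shifted[, j] + fd_eps
    gj <- token_input_gradients(model, shifted, class_label)
    Hcol <- colSums(wts * (gj - g0)) / fd_eps   # sum over path points
    Hacc[, j] <- Hacc[, j] + Hcol
  }
  Hacc <- (Hacc + t(Hacc)) / 2
  Gamma <- outer(u, u) * Hacc / n_steps^2
  phi <- integrated_gradients(model, token_inputs, baseline_tokens,
                              class_label, n_steps = n_steps^2)
  diag(Gamma) <- 0
  diag(Gamma) <- phi - rowSums(Gamma)
  grp <- rep(seq_len(K), each = m)
  token_matrix <- unname(rowsum(t(rowsum(Gamma, grp)), grp))
  token_phi <- as.vector(rowsum(matrix(phi, ncol = 1), grp))
  list(token_matrix = token_matrix, Gamma = Gamma, phi = phi,
       token_phi = token_phi)
}
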