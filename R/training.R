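#' Loss configuration
#'
#' The training objective is the sum of the per-modality classification
#' losses, plus `lambda1` times the integrated classifier's loss, `lambda2`
#' times the pairwise embedding-alignment losses, and `lambda3` times an L2
#' penalty over the learnable weight matrices (biases and normalization
#' parameters are not penalized). Classification losses are class-weighted
#' cross entropy; by default class weights are the inverse class
#' frequencies normalized to mean one.
#'
#' @param lambda1,lambda2,lambda3 non-negative trade-off weights.
#' @param class_weights optional positive per-class weights (length =
#'   number of classes); `NULL` = inverse frequency from the training labels.
#' @param alignment_mode `"complete_only"` (dimension-wise correlation over
#'   complete samples; the default) or `"complete_plus_crosspair"` (adds the
#'   cross-sample same-label pair loss within complete batches).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(lambda1 = 1, lambda2 = 0.1, lambda3 = 1e-4,
                        class_weights = NULL,
                        alignment_mode = c("complete_only", "complete_plus_crosspair")) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) abort("lambda weights must be >= 0.")
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    abort("class weights must be positive.")
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 class_weights = class_weights,
                 alignment_mode = match.arg(alignment_mode)),
            class = "loss_config")
}

class_weights_from_labels <- function(labels, n_classes = 2L) {
  f <- tabulate(labels + 1L, nbins = n_classes) / length(labels)
  w <- ifelse(f > 0, 1 / f, 0)
  w / mean(w[f > 0])
}

# class-weighted cross entropy from logits (adnode) and 0-based labels
ce_loss_fw <- function(logits, labels, class_w) {
  n <- nrow(logits$value)
  w <- class_w[labels + 1L]
  lse <- ad_logsumexp_rows(logits)
  picked <- ad_select(logits, labels + 1L)
  nll <- ad_sub(lse, picked)
  ad_mm(ad_const(matrix(w / sum(w), 1L)), nll)
}

# dimension-wise alignment loss over a complete batch (adnode version)
alignment_complete_fw <- function(z1, z2) {
  n <- nrow(z1$value)
  if (n < 3L) {
    warn("fewer than 3 complete samples in batch; alignment loss is 0.")
    return(ad_const(matrix(0)))
  }
  c1 <- ad_addrow(z1, ad_neg(ad_colmeans(z1)))
  c2 <- ad_addrow(z2, ad_neg(ad_colmeans(z2)))
  cov <- ad_smul(ad_colsums(ad_mul(c1, c2)), 1 / n)
  v1 <- ad_smul(ad_colsums(ad_sq(c1)), 1 / n)
  v2 <- ad_smul(ad_colsums(ad_sq(c2)), 1 / n)
  # zero-variance dimensions contribute 0; elsewhere the correlation is exact
  mask <- (v1$value > 1e-12) & (v2$value > 1e-12)
  denom <- ad_sadd(ad_mul(ad_powc(ad_sadd(v1, 1e-300), 0.5),
                          ad_powc(ad_sadd(v2, 1e-300), 0.5)),
                   as.numeric(!mask))
  r <- ad_mul(ad_div(cov, denom), ad_const(matrix(as.numeric(mask), 1L)))
  ad_neg(ad_mean(ad_abs(r)))
}

# cross-modality same-label pair loss (adnode version)
alignment_crosspair_fw <- function(z1, z2, labels1, labels2) {
  mask <- outer(labels1, labels2, "==") * 1
  npairs <- sum(mask)
  if (npairs < 1) {
    warn("no same-label cross-modality pair; alignment loss is 0.")
    return(ad_const(matrix(0)))
  }
  u1 <- ad_addcol(z1, ad_neg(ad_rowmeans(z1)))
  u2 <- ad_addcol(z2, ad_neg(ad_rowmeans(z2)))
  s1 <- ad_rowsums(ad_sq(u1)); s2 <- ad_rowsums(ad_sq(u2))
  # zero-variance samples are masked out of the correlation, not regularized
  m1 <- as.numeric(s1$value > 1e-12); m2 <- as.numeric(s2$value > 1e-12)
  n1 <- ad_mul(ad_powc(ad_sadd(s1, 1 - m1), -0.5), ad_const(matrix(m1, ncol = 1L)))
  n2 <- ad_mul(ad_powc(ad_sadd(s2, 1 - m2), -0.5), ad_const(matrix(m2, ncol = 1L)))
  R <- ad_mm(ad_rowscale(u1, n1), ad_t(ad_rowscale(u2, n2)))
  ad_neg(ad_smul(ad_sum(ad_mul(ad_abs(R), ad_const(mask))), 1 / npairs))
}

#' Alignment loss between two modalities' embeddings (complete samples)
#'
#' For each embedding dimension, the Pearson correlation across the batch
#' between the two modalities is computed; the loss is the negative mean of
#' their absolute values, in `[-1, 0]`, equal to -1 exactly when every
#' dimension is perfectly (anti)correlated. Dimensions with zero variance
#' contribute 0. Batches with fewer than 3 complete samples return 0 with a
#' warning.
#'
#' @param z1,z2 n x m embedding matrices over the same samples.
#' @return scalar loss.
#' @export
alignment_loss_complete <- function(z1, z2) {
  z1 <- as_mat(z1); z2 <- as_mat(z2)
  if (!all(dim(z1) == dim(z2))) abort("embedding matrices must share a shape.")
  as.numeric(alignment_complete_fw(ad_const(z1), ad_const(z2))$value)
}

#' Alignment loss between cross-modality same-label sample pairs
#'
#' For every pair of samples drawn from different modalities but carrying
#' the same class label, the Pearson correlation across the m embedding
#' dimensions is computed; the loss is the negative mean absolute
#' correlation over all such pairs, in `[-1, 0]`. Intended for batches where
#' the two modalities cover different samples.
#'
#' @param z1_samples,z2_samples embedding matrices (rows = samples).
#' @param labels1,labels2 class labels aligned to the rows.
#' @return scalar loss.
#' @export
alignment_loss_crosspair <- function(z1_samples, z2_samples, labels1, labels2) {
  z1 <- as_mat(z1_samples); z2 <- as_mat(z2_samples)
  if (ncol(z1) != ncol(z2)) abort("embedding dimensions must match.")
  as.numeric(alignment_crosspair_fw(ad_const(z1), ad_const(z2),
                                    labels1, labels2)$value)
}

# L2 penalty over weight matrices (biases / normalization params excluded)
reg_loss_fw <- function(flat) {
  skip <- "(^|\\.)(b|b1|b2|bn_gain|bn_bias|ln1_g|ln1_b|ln2_g|ln2_b|ffn_b1|ffn_b2|pool_b|out_b)$"
  terms <- list()
  for (nm in names(flat)) {
    if (grepl(skip, nm)) next
    terms[[length(terms) + 1L]] <- ad_sum(ad_sq(flat[[nm]]))
  }
  Reduce(ad_add, terms)
}

# composite loss over a uniform-availability batch (adnode version)
total_loss_fw <- function(model, fw_out, labels, cfg, class_w) {
  comp <- list()
  loss <- NULL
  add <- function(loss, term) if (is.null(loss)) term else ad_add(loss, term)
  for (nm in names(fw_out$uni)) {
    li <- ce_loss_fw(fw_out$uni[[nm]], labels, class_w)
    comp[[paste0("loss_", nm)]] <- as.numeric(li$value)
    loss <- add(loss, li)
  }
  if (!is.null(fw_out$int)) {
    li <- ce_loss_fw(fw_out$int$logits, labels, class_w)
    comp[["loss_int"]] <- as.numeric(li$value)
    if (cfg$lambda1 > 0) loss <- add(loss, ad_smul(li, cfg$lambda1))
    mods <- names(fw_out$z)
    if (length(mods) > 1L && cfg$lambda2 > 0) {
      al <- NULL
      for (a in seq_len(length(mods) - 1L)) {
        for (b in (a + 1L):length(mods)) {
          term <- alignment_complete_fw(fw_out$z[[a]], fw_out$z[[b]])
          if (cfg$alignment_mode == "complete_plus_crosspair") {
            term <- ad_add(term, alignment_crosspair_fw(fw_out$z[[a]], fw_out$z[[b]],
                                                        labels, labels))
          }
          al <- if (is.null(al)) term else ad_add(al, term)
        }
      }
      comp[["loss_align"]] <- as.numeric(al$value)
      loss <- add(loss, ad_smul(al, cfg$lambda2))
    } else comp[["loss_align"]] <- 0
  } else {
    comp[["loss_int"]] <- 0
    comp[["loss_align"]] <- 0
  }
  if (cfg$lambda3 > 0) {
    # penalize only the modules exercised by this batch, so that e.g. a
    # single-modality pass leaves the integrator untouched
    prefixes <- c(paste0(names(fw_out$uni), "."),
                  paste0("uni.", names(fw_out$uni), "."))
    if (!is.null(fw_out$int)) prefixes <- c(prefixes, "integrator.")
    sel <- Reduce(`|`, lapply(prefixes, function(p) startsWith(names(model$flat), p)))
    lr_ <- reg_loss_fw(model$flat[sel])
    comp[["loss_reg"]] <- as.numeric(lr_$value)
    loss <- add(loss, ad_smul(lr_, cfg$lambda3))
  } else comp[["loss_reg"]] <- 0
  comp[["loss_total"]] <- as.numeric(loss$value)
  list(loss = loss, components = comp)
}

#' Composite training loss for one batch
#'
#' Evaluates the full objective (per-modality cross entropy, integrated
#' cross entropy, alignment, L2 penalty) on a uniform-availability batch.
#' For single-modality batches the integration and alignment components are
#' exactly zero.
#'
#' @param model an `omics_gnn`.
#' @param x named list of per-modality feature matrices (the batch).
#' @param labels 0/1 labels for the batch rows.
#' @param cfg a [loss_config()].
#' @return list with `total` (scalar) and `components` (named numerics).
#' @export
total_loss <- function(model, x, labels, cfg = loss_config()) {
  class_w <- cfg$class_weights %||% class_weights_from_labels(labels)
  fw <- model_forward(model, x, training = FALSE)
  res <- total_loss_fw(model, fw, labels, cfg, class_w)
  list(total = as.numeric(res$loss$value), components = res$components)
}

#' Stratified k-fold assignment
#'
#' Splits samples into `k` folds, keeping each fold's class counts within
#' one sample of `n_class / k`.
#'
#' @param labels 0/1 (or small-integer) class labels.
#' @param k number of folds (3 in the reference protocol).
#' @param seed shuffling seed.
#' @param n_seeds_per_split weight-initialization seeds per split used by
#'   [grid_search()].
#' @return an object of class `cv_plan` with a `fold` assignment per sample.
#' @export
stratified_kfold <- function(labels, k = 3L, seed = 1L, n_seeds_per_split = 3L) {
  k <- check_count(k, "k", 1L)
  classes <- sort(unique(labels))
  for (cl in classes) {
    if (sum(labels == cl) < k) abort("every class needs at least k members.")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(n_folds = k, fold = fold, labels = labels,
                 n_seeds_per_split = n_seeds_per_split, seed = seed),
            class = "cv_plan")
}

#' Adam optimizer over a model's parameters
#' @param model an `omics_gnn`.
#' @param lr learning rate.
#' @return optimizer state (environment).
#' @export
optimizer_adam <- function(model, lr = 1e-3) {
  adam_new(model$flat, lr = lr)
}

# split training ids into availability subsets (complete first, then each
# single-modality group); empty subsets dropped
availability_subsets <- function(cohort, modalities, ids) {
  masks <- cohort$masks[match(ids, cohort$masks$sample_id), , drop = FALSE]
  have <- sapply(modalities, function(nm) masks[[nm]])
  have <- matrix(have, ncol = length(modalities),
                 dimnames = list(NULL, modalities))
  subs <- list()
  if (length(modalities) > 1L) {
    complete <- ids[rowSums(have) == length(modalities)]
    if (length(complete)) subs[["complete"]] <- complete
    for (nm in modalities) {
      only <- ids[have[, nm] & rowSums(have) == 1L]
      if (length(only)) subs[[paste0(nm, "_only")]] <- only
    }
  } else {
    subs[[modalities]] <- ids[have[, 1]]
  }
  subs
}

batch_features <- function(cohort, modalities, ids) {
  x <- lapply(modalities, function(nm) {
    cohort$features[[nm]][match(ids, rownames(cohort$features[[nm]])), , drop = FALSE]
  })
  names(x) <- modalities
  x
}

#' One training epoch over an incomplete multi-omics dataset
#'
#' The training set is partitioned into disjoint availability subsets
#' (complete samples, then each single-modality group); one epoch makes one
#' full pass over every subset, in an order drawn from the seeded generator,
#' with the loss masked to each subset's available modalities (integration
#' and alignment terms are zero for single-modality subsets).
#'
#' @param model an `omics_gnn`.
#' @param cohort an `omics_cohort`.
#' @param optimizer from [optimizer_adam()].
#' @param cfg a [loss_config()].
#' @param batch_size minibatch size.
#' @param seed epoch seed (controls subset order and shuffling).
#' @param sample_ids training subset (default: all samples).
#' @return tibble epoch log: one row per (subset, batch) with loss
#'   components and the number of optimizer steps taken.
#' @export
train_epoch_incomplete <- function(model, cohort, optimizer, cfg = loss_config(),
                                   batch_size = 16L, seed = 1L,
                                   sample_ids = NULL) {
  ids <- sample_ids %||% cohort$sample_ids
  subs <- availability_subsets(cohort, model$modalities, ids)
  if (!length(subs)) abort("all availability subsets are empty.")
  labels_all <- setNames(cohort$labels, cohort$sample_ids)
  class_w <- cfg$class_weights %||%
    class_weights_from_labels(unname(labels_all[ids]))
  log <- list()
  with_seed(seed, {
    for (sub_nm in sample(names(subs))) {
      sub_ids <- sample(subs[[sub_nm]])
      mods <- if (sub_nm == "complete") model$modalities else sub("_only$", "", sub_nm)
      nb <- ceiling(length(sub_ids) / batch_size)
      for (b in seq_len(nb)) {
        bids <- sub_ids[((b - 1L) * batch_size + 1L):min(b * batch_size, length(sub_ids))]
        x <- batch_features(cohort, mods, bids)
        fw <- model_forward(model, x, training = TRUE)
        res <- total_loss_fw(model, fw, unname(labels_all[bids]), cfg, class_w)
        ad_backward(res$loss)
        adam_step(optimizer)
        log[[length(log) + 1L]] <- tibble(subset = sub_nm, batch = b,
                                          n = length(bids),
                                          !!!res$components)
      }
    }
  })
  dplyr::bind_rows(log)
}

#' Train a multi-omics (or unimodal) graph model
#'
#' Builds the model over the cohort's prior graphs and trains it with Adam
#' on minibatches, handling incomplete samples by disjoint availability
#' subsets. When `modalities` selects a single modality, the result is a
#' unimodal model (GNN encoder + MLP head) trained only on samples carrying
#' that modality.
#'
#' @param cohort an `omics_cohort` with graphs attached (or pass `specs`).
#' @param modalities modalities to use (default: all in the cohort).
#' @param specs optional named list of `graph_spec` (overrides cohort graphs).
#' @param encoder_cfg,integrator_cfg,loss_cfg configuration objects.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed controls weight initialization and epoch shuffling.
#' @param train_ids samples to train on (default: all).
#' @param verbose print epoch summaries.
#' @return a trained `omics_gnn` with a `log` tibble (epoch, subset, loss
#'   components).
#' @export
train_multiomics <- function(cohort, modalities = NULL, specs = NULL,
                             encoder_cfg = encoder_config(),
                             integrator_cfg = integrator_config(),
                             loss_cfg = loss_config(),
                             epochs = 200L, batch_size = 16L, lr = 1e-3,
                             seed = 1L, train_ids = NULL, verbose = FALSE) {
  modalities <- modalities %||% names(cohort$features)
  if (is.null(specs)) {
    if (is.null(cohort$graphs)) abort("cohort has no graphs; supply `specs`.")
    specs <- lapply(cohort$graphs[modalities], as_graph_spec)
    names(specs) <- modalities
  }
  specs <- specs[modalities]
  model <- model_new(specs, encoder_cfg, integrator_cfg, seed = seed)
  ids <- train_ids %||% cohort$sample_ids
  # restrict to samples carrying at least one of the model's modalities
  masks <- cohort$masks[match(ids, cohort$masks$sample_id), , drop = FALSE]
  carry <- Reduce(`|`, lapply(modalities, function(nm) masks[[nm]]))
  ids <- ids[carry]
  labels <- cohort$labels[match(ids, cohort$sample_ids)]
  if (is.null(loss_cfg$class_weights)) {
    loss_cfg$class_weights <- class_weights_from_labels(labels)
  }
  opt <- optimizer_adam(model, lr = lr)
  logs <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    el <- train_epoch_incomplete(model, cohort, opt, loss_cfg,
                                 batch_size = batch_size,
                                 seed = child_seed(seed, 10000L + ep),
                                 sample_ids = ids)
    el$epoch <- ep
    logs[[ep]] <- el
    if (verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("epoch %d: mean total loss %.4f", ep, mean(el$loss_total)))
    }
  }
  model$log <- dplyr::bind_rows(logs)
  model$trained <- TRUE
  model$train_ids <- ids
  model$loss_cfg <- loss_cfg
  model
}

#' Validation accuracy of a trained model on a cohort subset
#'
#' Complete samples are scored by the integrated classifier, incomplete
#' samples by their modality's unimodal head (matching the evaluation
#' protocol for incomplete cohorts).
#'
#' @param model a trained `omics_gnn`.
#' @param cohort an `omics_cohort`.
#' @param ids samples to score (default: all).
#' @param source see [predict.omics_gnn()].
#' @return list with `accuracy` and the `predictions` tibble.
#' @export
evaluate_accuracy <- function(model, cohort, ids = NULL, source = "auto") {
  preds <- predict(model, cohort, source = source)
  if (!is.null(ids)) preds <- preds[preds$sample_id %in% ids, , drop = FALSE]
  list(accuracy = mean(preds$predicted == preds$label), predictions = preds)
}

#' Hyperparameter grid search with repeated stratified validation
#'
#' For every configuration in the grid the model is trained on each of the
#' plan's splits (training folds = all but one) with
#' `plan$n_seeds_per_split` different weight-initialization seeds, and the
#' mean validation accuracy over those trials (3 splits x 3 seeds = 9 in
#' the reference protocol) scores the configuration. Ties are broken by
#' grid order.
#'
#' @param grid list of named lists of overrides; recognized keys:
#'   `lr`, `epochs`, `batch_size`, `lambda1`, `lambda2`, `lambda3`, plus any
#'   [encoder_config()] field.
#' @param cohort an `omics_cohort`.
#' @param plan a [stratified_kfold()] plan over `cohort`'s samples.
#' @param epochs,batch_size,lr defaults for keys a grid entry omits.
#' @param seed base seed for trial weight initialization.
#' @param ... passed to [train_multiomics()].
#' @return list with `best` (the winning config), `best_index`, and
#'   `trials` (tibble: config, split, init seed, accuracy).
#' @export
grid_search <- function(grid, cohort, plan, epochs = 20L, batch_size = 16L,
                        lr = 1e-3, seed = 1L, ...) {
  if (!length(grid)) abort("`grid` must not be empty.")
  trials <- list()
  scores <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    cfg <- grid[[gi]]
    enc_keys <- intersect(names(cfg), names(formals(encoder_config)))
    enc_cfg <- do.call(encoder_config, cfg[enc_keys])
    ls_keys <- intersect(names(cfg), c("lambda1", "lambda2", "lambda3"))
    loss_cfg <- do.call(loss_config, cfg[ls_keys])
    accs <- c()
    for (split in seq_len(plan$n_folds)) {
      val_ids <- cohort$sample_ids[plan$fold == split]
      tr_ids <- cohort$sample_ids[plan$fold != split]
      for (si in seq_len(plan$n_seeds_per_split)) {
        mseed <- child_seed(seed, gi * 1000L + split * 10L + si)
        model <- train_multiomics(cohort, encoder_cfg = enc_cfg,
                                  loss_cfg = loss_cfg,
                                  epochs = cfg$epochs %||% epochs,
                                  batch_size = cfg$batch_size %||% batch_size,
                                  lr = cfg$lr %||% lr,
                                  seed = mseed, train_ids = tr_ids, ...)
        acc <- evaluate_accuracy(model, cohort, ids = val_ids)$accuracy
        accs <- c(accs, acc)
        trials[[length(trials) + 1L]] <- tibble(config = gi, split = split,
                                                init_seed = si, accuracy = acc)
      }
    }
    scores[gi] <- mean(accs)
  }
  best <- which.max(scores)  # which.max takes the first maximum: grid order
  list(best = grid[[best]], best_index = best, scores = scores,
       trials = dplyr::bind_rows(trials))
}
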