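# Higher-level analysis pipelines built from the module functions; these are
# what the command-line interface and the reproduction script drive.

#' Class-token representations for complete samples
#'
#' Runs complete samples through the trained model and returns the final
#' class-token embedding of the set transformer (the fused multi-omics
#' representation of each sample).
#'
#' @param model trained `omics_gnn`.
#' @param cohort an `omics_cohort`.
#' @param ids complete samples to embed (default: all complete samples).
#' @return n x m matrix with sample ids as rownames.
#' @export
collect_class_tokens <- function(model, cohort, ids = NULL) {
  mods <- model$modalities
  complete <- cohort$sample_ids[Reduce(`&`, lapply(mods, function(nm) cohort$masks[[nm]]))]
  ids <- ids %||% complete
  ids <- intersect(ids, complete)
  x <- batch_features(cohort, mods, ids)
  fw <- model_forward(model, x, training = FALSE)
  ct <- fw$int$class_token$value
  rownames(ct) <- ids
  ct
}

#' Informative-marker discovery with permutation FDR
#'
#' End-to-end marker analysis for a trained model: control-mean baselines
#' are computed from the training samples, integrated-gradient attributions
#' of the disease-class score are derived for the validation samples, a
#' null score pool is built by retraining the model on label-permuted data
#' `B` times, a per-modality threshold controlling the empirical FDR is
#' selected, features are called informative in correctly predicted
#' validation samples, and markers are ranked by their informative-sample
#' fraction.
#'
#' @param model trained `omics_gnn`.
#' @param cohort an `omics_cohort`.
#' @param train_ids,val_ids training and validation sample ids.
#' @param B number of label permutations.
#' @param pi0 prior null probability.
#' @param target FDR target.
#' @param n_steps integrated-gradient quadrature steps.
#' @param null_epochs,null_lr,null_batch training budget for each null
#'   model.
#' @param score_mode `"magnitude"` (default, `|phi|`) or `"signed"`.
#' @param study label for the ranking table.
#' @param null_pools optional cached per-modality score pools (named list
#'   of [train_null_models()] results) to reuse across analyses.
#' @param seed base seed.
#' @return list: `attributions`, `predictions`, `decisions` (per modality),
#'   `informative`, `ranking`, `null_pools`, `n_correct`.
#' @export
discover_markers <- function(model, cohort, train_ids, val_ids, B = 50L,
                             pi0 = 0.97, target = 0.05, n_steps = 16L,
                             null_epochs = 8L, null_lr = 2e-3,
                             null_batch = 32L,
                             score_mode = c("magnitude", "signed"),
                             study = "study", null_pools = NULL, seed = 1L) {
  score_mode <- match.arg(score_mode)
  mods <- model$modalities
  source <- if (length(mods) > 1L) "integrated" else mods
  complete <- cohort$sample_ids[Reduce(`&`, lapply(mods, function(nm) cohort$masks[[nm]]))]
  val_use <- intersect(val_ids, complete)
  train_labels <- cohort$labels[match(train_ids, cohort$sample_ids)]
  baselines <- lapply(mods, function(nm) {
    tr <- intersect(train_ids, rownames(cohort$features[[nm]]))
    control_mean_baseline(cohort$features[[nm]][tr, , drop = FALSE],
                          cohort$labels[match(tr, cohort$sample_ids)])
  })
  names(baselines) <- mods
  transform_scores <- function(tb) {
    tb$score <- if (score_mode == "magnitude") abs(tb$phi) else tb$phi
    tb
  }
  attr_obs <- transform_scores(
    attribute_cohort(model, cohort, val_use, baselines, source = source,
                     n_steps = n_steps)
  )
  preds <- predict(model, cohort, source = source)
  preds <- preds[preds$sample_id %in% val_use, , drop = FALSE]
  n_correct <- sum(preds$predicted == preds$label)
  if (is.null(null_pools)) {
    factory <- function(perm_cohort, fseed) {
      nm_model <- train_multiomics(perm_cohort,
                                   modalities = mods,
                                   encoder_cfg = model$encoder_cfg,
                                   integrator_cfg = model$integrator_cfg,
                                   loss_cfg = model$loss_cfg %||% loss_config(),
                                   epochs = null_epochs, batch_size = null_batch,
                                   lr = null_lr, seed = fseed,
                                   train_ids = train_ids)
      tb <- transform_scores(
        attribute_cohort(nm_model, perm_cohort, val_use, baselines,
                         source = source, n_steps = n_steps)
      )
      # keep modality blocks identifiable in the pooled vector
      setNames(tb$score, tb$modality)
    }
    null_pools <- list(all = train_null_models(cohort, factory, B = B, seed = seed))
  }
  pooled <- null_pools$all
  decisions <- list(); informative <- list()
  for (nm in mods) {
    obs_nm <- attr_obs[attr_obs$modality == nm, , drop = FALSE]
    null_nm <- unlist(lapply(pooled$per_b, function(v) v[names(v) == nm]))
    dec <- select_threshold(obs_nm$score, null_nm, B = pooled$B, pi0 = pi0,
                            target = target)
    decisions[[nm]] <- dec
    if (dec$achieved) {
      informative[[nm]] <- call_informative(obs_nm, dec$threshold, preds,
                                            score = "score")
    } else {
      informative[[nm]] <- obs_nm[0, , drop = FALSE]
    }
  }
  calls <- dplyr::bind_rows(informative)
  ranking <- if (nrow(calls) && n_correct > 0) {
    rank_markers(setNames(list(calls), study), setNames(n_correct, study))
  } else {
    tibble(rank = integer(0), feature = character(0),
           mean_fraction = numeric(0), total_samples = numeric(0))
  }
  list(attributions = attr_obs, predictions = preds, decisions = decisions,
       informative = calls, ranking = ranking, null_pools = null_pools,
       n_correct = n_correct, baselines = baselines)
}
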