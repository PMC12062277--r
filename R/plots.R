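#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Tidy a trained model's training log
#'
#' @param x a trained `omics_gnn`.
#' @param ... unused.
#' @return tibble with one row per (epoch, subset, batch) and the loss
#'   components.
#' @export
tidy.omics_gnn <- function(x, ...) {
  if (is.null(x$log)) abort("model has no training log; train it first.")
  as_tibble(x$log)
}

#' One-row model summary
#' @param x a trained `omics_gnn`.
#' @param ... unused.
#' @return tibble: modalities, parameter count, epochs, final mean loss.
#' @export
glance.omics_gnn <- function(x, ...) {
  np <- sum(vapply(x$flat, function(p) length(p$value), numeric(1)))
  lg <- x$log
  tibble(
    modalities = paste(x$modalities, collapse = "+"),
    n_parameters = np,
    embedding_dim = x$encoder_cfg$embedding_dim,
    epochs = if (is.null(lg)) 0L else max(lg$epoch),
    final_loss = if (is.null(lg)) NA_real_ else {
      mean(lg$loss_total[lg$epoch == max(lg$epoch)])
    }
  )
}

#' Tidy an FDR decision's threshold table
#' @param x an `fdr_decision`.
#' @param ... unused.
#' @return tibble of evaluated thresholds with discovery counts and FDR.
#' @export
tidy.fdr_decision <- function(x, ...) x$table

#' One-row FDR decision summary
#' @param x an `fdr_decision`.
#' @param ... unused.
#' @return tibble: threshold, fdr, achieved, target, discoveries.
#' @export
glance.fdr_decision <- function(x, ...) {
  tibble(threshold = x$threshold, fdr = x$fdr, achieved = x$achieved,
         target = x$target, min_fdr = x$min_fdr,
         n_informative = sum(x$informative))
}

#' Training-loss curves
#' @param object a trained `omics_gnn`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.omics_gnn <- function(object, ...) {
  lg <- tidy(object)
  per_epoch <- dplyr::summarise(dplyr::group_by(lg, .data$epoch),
                                loss = mean(.data$loss_total), .groups = "drop")
  ggplot(per_epoch, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "#2c7fb8") +
    labs(x = "epoch", y = "mean total loss", title = "Training loss") +
    theme_minimal()
}

#' Estimated FDR across candidate thresholds
#' @param object an `fdr_decision`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fdr_decision <- function(object, ...) {
  p <- ggplot(object$table, aes(x = .data$d, y = .data$fdr)) +
    geom_line(color = "grey40") + geom_point(size = 0.8) +
    geom_hline(yintercept = object$target, linetype = 2, color = "#d7301f") +
    labs(x = "threshold d", y = "estimated FDR") +
    theme_minimal()
  p
}

#' Bar chart of top-ranked markers
#' @param ranking tibble from [rank_markers()].
#' @param top number of markers to show.
#' @return a ggplot.
#' @export
plot_marker_ranking <- function(ranking, top = 20L) {
  df <- utils::head(ranking, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$feature, y = .data$mean_fraction)) +
    geom_col(fill = "#31a354") +
    coord_flip() +
    labs(x = NULL, y = "mean fraction of informative samples") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
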