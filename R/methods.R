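# Tidiers and plot methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained model's training history
#'
#' @param x A trained `of_model`.
#' @param ... Unused.
#' @return Long tibble with `epoch`, `metric` (`train_loss` / `val_loss`),
#'   and `value`.
#' @export
tidy.of_model <- function(x, ...) {
  if (is.null(x$history)) of_abort("model has no training history.")
  tidyr::pivot_longer(x$history, -epoch, names_to = "metric", values_to = "value")
}

#' One-row model summary
#'
#' @param x A trained `of_model`.
#' @param ... Unused.
#' @return Tibble with one row: architecture, fusion, modality count,
#'   embedding width, parameter count, epochs trained, best validation loss.
#' @export
glance.of_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$spec$architecture,
    fusion = x$spec$fusion,
    n_modalities = length(x$modalities),
    embedding_width = x$embedding_width,
    n_parameters = sum(rapply(x$theta, length, how = "unlist")),
    epochs_trained = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    best_val_loss = x$best_val_loss %||% NA_real_
  )
}

#' Plot training and validation loss curves
#'
#' @param object A trained `of_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.of_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = value, color = metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL,
                  title = sprintf("%s (%s fusion) training history",
                                  object$spec$architecture, object$spec$fusion)) +
    ggplot2::theme_minimal()
}

#' Tidy a paired bootstrap comparison
#'
#' @param x A `bootstrap_comparison`.
#' @param ... Unused.
#' @return The per-replicate scores in long form: `replicate`, `model`,
#'   `score`.
#' @export
tidy.bootstrap_comparison <- function(x, ...) {
  tidyr::pivot_longer(x$replicates, -replicate,
                      names_to = "model", values_to = "score")
}

#' One-row summary of a paired bootstrap comparison
#'
#' @param x A `bootstrap_comparison`.
#' @param ... Unused.
#' @return Tibble with the mean difference, its percentile interval, the
#'   paired t statistic and p value, and the replicate/redraw counts.
#' @export
glance.bootstrap_comparison <- function(x, ...) {
  tibble::tibble(
    mean_a = mean(x$replicates$model_a),
    mean_b = mean(x$replicates$model_b),
    ci_a_low = x$ci_a[1], ci_a_high = x$ci_a[2],
    ci_b_low = x$ci_b[1], ci_b_high = x$ci_b[2],
    mean_diff = x$mean_diff,
    ci_diff_low = x$ci_diff[1], ci_diff_high = x$ci_diff[2],
    t_statistic = x$t_statistic, p_value = x$p_value,
    n_boot = x$n_boot, redraws = x$redraws
  )
}

#' Plot the bootstrap score distributions of two models
#'
#' @param object A `bootstrap_comparison`.
#' @param ... Unused.
#' @return A ggplot (overlaid score histograms with interval bars).
#' @export
autoplot.bootstrap_comparison <- function(object, ...) {
  df <- tidy(object)
  ci <- tibble::tibble(model = c("model_a", "model_b"),
                       lo = c(object$ci_a[1], object$ci_b[1]),
                       hi = c(object$ci_a[2], object$ci_b[2]),
                       mid = c(mean(object$replicates$model_a),
                               mean(object$replicates$model_b)))
  ggplot2::ggplot(df, ggplot2::aes(x = score, fill = model)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 25) +
    ggplot2::geom_vline(data = ci, ggplot2::aes(xintercept = mid, color = model),
                        linetype = 2, show.legend = FALSE) +
    ggplot2::labs(x = "bootstrap metric", y = "replicates", fill = NULL,
                  subtitle = sprintf("diff %.3f [%.3f, %.3f], p = %.3g",
                                     object$mean_diff, object$ci_diff[1],
                                     object$ci_diff[2], object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a clustering's silhouette profile over the candidate settings
#'
#' @param object A `clustering_result` from [cluster_embeddings()].
#' @param ... Unused.
#' @return A ggplot of mean silhouette against the candidate k (or
#'   resolution), with the selected candidate highlighted.
#' @export
autoplot.clustering_result <- function(object, ...) {
  df <- object$candidates
  ggplot2::ggplot(df, ggplot2::aes(x = candidate, y = silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$candidate == object$chosen, , drop = FALSE],
                        color = "red", size = 3) +
    ggplot2::labs(x = if (object$method == "kmeans") "k" else "resolution",
                  y = "mean silhouette",
                  title = sprintf("selected %s = %s (silhouette %.3f)",
                                  if (object$method == "kmeans") "k" else "resolution",
                                  object$chosen, object$silhouette)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of sample embeddings
#'
#' Projects the embedding to two dimensions with PCA when it is wider than
#' two, and colors points by an optional label vector.
#'
#' @param embedding Samples x dimensions numeric matrix.
#' @param labels Optional per-sample labels (factor/character/numeric).
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_embeddings <- function(embedding, labels = NULL, title = "embeddings") {
  assert_matrix_like(embedding, "embedding")
  xy <- if (ncol(embedding) > 2) {
    stats::prcomp(embedding, rank. = 2)$x
  } else {
    embedding
  }
  df <- tibble::tibble(dim1 = xy[, 1], dim2 = xy[, 2])
  axis_lab <- if (ncol(embedding) > 2) c("PC1", "PC2") else c("dim 1", "dim 2")
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = dim1, y = dim2)) +
      ggplot2::geom_point(alpha = 0.8)
  } else {
    df$label <- if (is.numeric(labels)) labels else factor(labels)
    ggplot2::ggplot(df, ggplot2::aes(x = dim1, y = dim2, color = label)) +
      ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(x = axis_lab[1], y = axis_lab[2], title = title) +
    ggplot2::theme_minimal()
}

#' Bar plot of ranked markers
#'
#' @param markers A marker tibble from [rank_markers()] or
#'   [compute_markers()].
#' @param top_n Bars to show (default 15).
#' @return A ggplot of relative importance per feature, faceted by target
#'   (and class) when several are present.
#' @export
plot_markers <- function(markers, top_n = 15) {
  if (!all(c("feature", "relative_importance") %in% names(markers))) {
    of_abort("`markers` must be a marker table.")
  }
  df <- markers
  df$panel <- interaction(df$target, df$class, drop = TRUE)
  df <- dplyr::ungroup(dplyr::slice_max(dplyr::group_by(df, panel),
                                        relative_importance, n = top_n,
                                        with_ties = FALSE))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = relative_importance,
    y = stats::reorder(paste(feature, panel, sep = "\r"), relative_importance),
    fill = modality)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_discrete(labels = function(l) sub("\r.*$", "", l)) +
    ggplot2::labs(x = "relative importance", y = NULL, fill = "modality") +
    ggplot2::theme_minimal()
  if (length(unique(df$panel)) > 1) {
    p <- p + ggplot2::facet_wrap(~panel, scales = "free_y")
  }
  p
}
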