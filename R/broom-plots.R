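#' Tidy a fitted stacked model
#'
#' One row per fitted scalar artifact: decision threshold `tau`, network
#' threshold `theta`, selected meta-SVM hyperparameters, the AC gap, and
#' the per-ontology LCA-cluster (F2 feature) counts.
#'
#' @param x A fitted [ppi_stack()].
#' @param ... Unused.
#' @return Tibble: `component`, `value`.
#' @method tidy ppi_stack
#' @export
tidy.ppi_stack <- function(x, ...) {
  man <- model_manifest(x)
  comps <- c(tau = man$tau, theta = unname(man$theta),
             max_gap = unname(man$max_gap), svm_cost = man$svm_cost,
             svm_gamma = if (identical(man$svm_gamma, "default"))
               NA_real_ else man$svm_gamma,
             n_features = man$n_features)
  f2 <- man$n_f2
  if (length(f2) > 0L) {
    comps <- c(comps, setNames(as.numeric(f2), paste0("n_f2_", names(f2))))
  }
  tibble(component = names(comps), value = unname(comps))
}

#' One-row summary of a fitted stacked model
#'
#' Training-split (out-of-fold) MCC at the fitted threshold and AUC, plus
#' the model dimensions.
#'
#' @inheritParams tidy.ppi_stack
#' @return One-row tibble.
#' @method glance ppi_stack
#' @export
glance.ppi_stack <- function(x, ...) {
  m <- compute_metrics(mutate(x$train_scores, truth = .data$label),
                       truth = "truth", prob = "prob",
                       threshold = x$tau)
  tibble(n_pairs = x$n_pairs, n_features = x$n_features,
         n_base = length(x$base_fits), tau = x$tau,
         theta = x$theta %||% NA_real_,
         train_mcc = m$mcc, train_auc = m$auc)
}

#' Per-run metric reports of a cross-validation result
#' @param x A [ppi_cv()] result.
#' @param ... Unused.
#' @return Tibble with one row per repeat x fold.
#' @method tidy ppi_cv
#' @export
tidy.ppi_cv <- function(x, ...) {
  x$runs
}

#' Pooled cross-validation summary (mean over all runs)
#' @inheritParams tidy.ppi_cv
#' @return One-row tibble of the seven pooled metrics plus the design.
#' @method glance ppi_cv
#' @export
glance.ppi_cv <- function(x, ...) {
  bind_cols(tibble(repeats = x$repeats, folds = x$folds), x$pooled)
}

#' Per-run metric reports of an ablation experiment
#' @param x A [ppi_ablation()] result.
#' @param ... Unused.
#' @return Tibble with one row per subset x run.
#' @method tidy ppi_ablation
#' @export
tidy.ppi_ablation <- function(x, ...) {
  x$runs
}

#' Training-probability plot of a fitted stacked model
#'
#' Out-of-fold pair probabilities by true label with the fitted decision
#' threshold.
#'
#' @param object A fitted [ppi_stack()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_stack
#' @export
autoplot.ppi_stack <- function(object, ...) {
  ggplot2::ggplot(object$train_scores,
                  ggplot2::aes(x = .data$prob, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 30, position = "identity",
                            alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$tau, linetype = 2) +
    ggplot2::labs(x = "out-of-fold meta probability", y = "pairs",
                  fill = NULL,
                  title = sprintf("Training probabilities (tau = %.3f)",
                                  object$tau)) +
    ggplot2::theme_minimal()
}

#' Metric distributions across cross-validation runs
#' @param object A [ppi_cv()] result.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_cv
#' @export
autoplot.ppi_cv <- function(object, metrics = metric_cols, ...) {
  long <- tidyr::pivot_longer(object$runs, dplyr::all_of(metrics),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d x %d-fold CV", object$repeats,
                                  object$folds)) +
    ggplot2::theme_minimal()
}

#' Pooled metric by feature subset
#' @param object A [ppi_ablation()] result.
#' @param metric Pooled metric to display (default `"auc"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_ablation
#' @export
autoplot.ppi_ablation <- function(object, metric = "auc", ...) {
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(x = stats::reorder(.data$subset,
                                                  .data[[metric]]),
                               y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric,
                  title = "Feature-subset ablation") +
    ggplot2::theme_minimal()
}
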