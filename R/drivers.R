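metric_cols <- c("tpr", "fpr", "precision", "accuracy", "f_score",
                 "mcc", "auc")

# One CV evaluation over precomputed fold assignments (one vector per
# repeat). Every training-derived artifact is refitted inside each fold.
cv_engine <- function(dataset, features, control, fold_list, seed) {
  runs <- list()
  preds <- list()
  for (r in seq_along(fold_list)) {
    folds <- fold_list[[r]]
    for (f in sort(unique(folds))) {
      train <- subset_pairs(dataset, folds != f)
      test_pairs <- dataset$pairs[folds == f, ]
      model <- ppi_stack(train, features = features, control = control,
                          seed = seed + 1000L * r + f)
      pr <- predict(model, test_pairs, proteins = dataset$proteins,
                    annotations = dataset$annotations)
      pr$truth <- test_pairs$label
      m <- compute_metrics(pr, truth = "truth", prob = "prob",
                           estimate = "label")
      runs[[length(runs) + 1L]] <- bind_cols(
        tibble(run = r, fold = f, n_test = nrow(test_pairs),
               tau = model$tau), m)
      preds[[length(preds) + 1L]] <- mutate(pr, run = r, fold = f)
    }
  }
  list(runs = bind_rows(runs), predictions = bind_rows(preds))
}

#' Repeated stratified cross-validation of the stacked classifier
#'
#' The evaluation protocol: `repeats` x `folds` stratified CV (folds
#' disjoint, class ratio preserved within one instance), with the whole
#' pipeline -- normalizer, LCA partitions, IC table, network threshold, base
#' and meta learners, decision threshold -- refitted inside every training
#' split. Per-run metrics are pooled by averaging over all runs (the primary
#' summary); metrics of the pooled predictions are kept as a secondary
#' diagnostic.
#'
#' @param dataset A [ppi_dataset()].
#' @param features Feature blocks, see [ppi_stack()].
#' @param repeats,folds CV design (defaults 3 x 10).
#' @param control A [ppi_control()].
#' @param seed Integer seed; repeat `r` assigns folds with `seed + r - 1`.
#' @return A `ppi_cv` object: per-run metric reports, pooled means, pooled
#'   predictions.
#' @export
ppi_cv <- function(dataset, features = c("F1", "F2", "F3"),
                   repeats = 3, folds = 10, control = ppi_control(),
                   seed = 1L) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  fold_list <- lapply(seq_len(repeats), function(r) {
    stratified_folds(dataset$pairs$label, folds, seed = seed + r - 1L)
  })
  res <- cv_engine(dataset, features, control, fold_list, seed)
  structure(list(runs = res$runs, predictions = res$predictions,
                 pooled = summarise(res$runs,
                                    across(dplyr::all_of(metric_cols), mean)),
                 pooled_predictions = compute_metrics(
                   res$predictions, truth = "truth", prob = "prob",
                   estimate = "label"),
                 features = features, repeats = repeats, folds = folds,
                 seed = seed, fold_list = fold_list),
            class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("<ppi_cv: %d x %d-fold CV, features %s>\n", x$repeats,
              x$folds, paste(x$features, collapse = "+")))
  print(x$pooled)
  invisible(x)
}

#' Feature-ablation experiment
#'
#' Runs one CV evaluation per feature subset with identical fold
#' assignments across subsets, so per-fold metrics are paired and
#' subset-to-subset differences can be tested with [paired_metric_test()].
#'
#' @inheritParams ppi_cv
#' @param subsets List of feature-block subsets; defaults to all seven
#'   non-empty subsets of F1/F2/F3.
#' @return A `ppi_ablation` object with one row per subset x run in
#'   `$runs` and per-subset pooled means in `$pooled`.
#' @export
ppi_ablation <- function(dataset,
                         subsets = list("F1", "F2", "F3",
                                        c("F1", "F2"), c("F1", "F3"),
                                        c("F2", "F3"), c("F1", "F2", "F3")),
                         repeats = 1, folds = 10,
                         control = ppi_control(), seed = 1L) {
  stopifnot(length(subsets) >= 1)
  fold_list <- lapply(seq_len(repeats), function(r) {
    stratified_folds(dataset$pairs$label, folds, seed = seed + r - 1L)
  })
  runs <- lapply(subsets, function(fs) {
    res <- cv_engine(dataset, fs, control, fold_list, seed)
    mutate(res$runs, subset = paste(fs, collapse = "&"), .before = 1)
  })
  runs <- bind_rows(runs)
  pooled <- runs |>
    group_by(.data$subset) |>
    summarise(across(dplyr::all_of(metric_cols), mean), .groups = "drop")
  structure(list(runs = runs, pooled = pooled, fold_list = fold_list,
                 repeats = repeats, folds = folds, seed = seed),
            class = "ppi_ablation")
}

#' @export
print.ppi_ablation <- function(x, ...) {
  cat(sprintf("<ppi_ablation: %d subsets, %d x %d-fold CV>\n",
              length(unique(x$runs$subset)), x$repeats, x$folds))
  print(x$pooled)
  invisible(x)
}

#' Train on one dataset, test on another
#'
#' Cross-dataset (e.g. cross-species) protocol: the model is fitted wholly
#' on the training dataset and evaluated once on the test dataset,
#' optionally restricting both to a single subontology. Test proteins
#' absent from the training network simply receive zero topology features.
#'
#' @param train,test [ppi_dataset()] objects sharing a feature
#'   configuration.
#' @param features Feature blocks, see [ppi_stack()].
#' @param ontology Optional single subontology (`"BP"`, `"CC"` or `"MF"`)
#'   to restrict both datasets to.
#' @param control A [ppi_control()].
#' @param seed Integer seed.
#' @return One-row metric tibble (see [compute_metrics()]).
#' @export
ppi_cross_test <- function(train, test, features = c("F1", "F2", "F3"),
                           ontology = NULL, control = ppi_control(),
                           seed = 1L) {
  if (!is.null(ontology)) {
    if (!ontology %in% names(train$ontologies) ||
        !ontology %in% names(test$ontologies)) {
      abort(sprintf("ontology '%s' missing from one of the datasets",
                    ontology))
    }
    train <- restrict_ontology(train, ontology)
    test <- restrict_ontology(test, ontology)
  }
  model <- ppi_stack(train, features = features, control = control,
                      seed = seed)
  pr <- predict(model, test$pairs, proteins = test$proteins,
                annotations = test$annotations)
  pr$truth <- test$pairs$label
  compute_metrics(pr, truth = "truth", prob = "prob", estimate = "label")
}
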