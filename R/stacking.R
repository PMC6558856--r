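#' Control settings for the stacked ensemble
#'
#' Defaults follow the reference architecture: four base learners (random
#' forest, Gaussian naive Bayes, single-hidden-layer neural network,
#' inverse-distance-weighted kNN) and an RBF-kernel SVM meta-classifier
#' whose cost/gamma are grid-searched by internal cross-validated MCC.
#'
#' @param max_gap Maximum auto-covariance gap G; the sequence block has
#'   `14 * G` values per protein (capped at the shortest training sequence
#'   length minus one).
#' @param nonstandard Policy for non-standard residues, see
#'   [sanitize_sequence()].
#' @param rf_ntree Random-forest tree count.
#' @param ann_size,ann_decay,ann_maxit Hidden-layer size, weight decay and
#'   iteration cap of the neural-network base learner.
#' @param knn_k Neighbour count of the kNN base learner.
#' @param svm_cost,svm_gamma Meta-SVM grids; `NA` in `svm_gamma` means the
#'   kernel default `1/n_features`.
#' @param meta_folds Internal stratified folds for out-of-fold meta-data.
#' @param grid_folds Internal folds for the meta-SVM grid search.
#' @param base_learners Subset of `c("rf", "nb", "ann", "knn")`.
#' @return A `ppi_control` list.
#' @export
ppi_control <- function(max_gap = 30, nonstandard = "drop",
                        rf_ntree = 500, ann_size = 16, ann_decay = 0.1,
                        ann_maxit = 200, knn_k = 5,
                        svm_cost = c(0.1, 1, 10, 100),
                        svm_gamma = c(NA, 0.01, 0.001),
                        meta_folds = 5, grid_folds = 3,
                        base_learners = c("rf", "nb", "ann", "knn")) {
  stopifnot(max_gap >= 1, meta_folds >= 2, grid_folds >= 2,
            length(base_learners) >= 1,
            all(base_learners %in% c("rf", "nb", "ann", "knn")))
  structure(list(max_gap = max_gap, nonstandard = nonstandard,
                 rf_ntree = rf_ntree, ann_size = ann_size,
                 ann_decay = ann_decay, ann_maxit = ann_maxit,
                 knn_k = knn_k, svm_cost = svm_cost, svm_gamma = svm_gamma,
                 meta_folds = meta_folds, grid_folds = grid_folds,
                 base_learners = base_learners),
            class = "ppi_control")
}

## ---- base learners -------------------------------------------------------

fit_base <- function(name, x, y, control, seed) {
  # a degenerate block (e.g. every pair isolated in a very sparse network)
  # carries no information; fall back to the class prior rather than hand
  # the learners an all-constant matrix
  if (all(x == rep(x[1, ], each = nrow(x)))) {
    return(structure(list(p = mean(y)), class = "ppistack_prior"))
  }
  yf <- factor(ifelse(y, "interacting", "non-interacting"),
               levels = label_levels)
  switch(name,
    rf = {
      set.seed(seed)
      randomForest::randomForest(x, yf, ntree = control$rf_ntree)
    },
    nb = e1071::naiveBayes(x, yf),
    ann = {
      set.seed(seed)
      nnet::nnet(x, as.numeric(y), size = control$ann_size,
                 decay = control$ann_decay, maxit = control$ann_maxit,
                 entropy = TRUE, trace = FALSE,
                 MaxNWts = (ncol(x) + 2) * control$ann_size + 1000)
    },
    knn = structure(list(x = x, y = y, k = control$knn_k),
                    class = "ppistack_knn"),
    abort(sprintf("unknown base learner '%s'", name))
  )
}

predict_base <- function(name, fit, x) {
  if (inherits(fit, "ppistack_prior")) return(rep(fit$p, nrow(x)))
  # deserialized models may predate this session: make sure the learner
  # namespaces (and their S3 predict methods) are loaded
  for (ns in c("randomForest", "e1071", "nnet")) loadNamespace(ns)
  p <- switch(name,
    rf = predict(fit, x, type = "prob")[, "interacting"],
    nb = predict(fit, as.data.frame(x), type = "raw")[, "interacting"],
    ann = as.numeric(predict(fit, x)),
    knn = predict_knn(fit, x)
  )
  p[!is.finite(p)] <- 0.5
  pmin(pmax(unname(p), 0), 1)
}

# Inverse-distance-weighted k-nearest-neighbour probability.
predict_knn <- function(fit, x) {
  k <- min(fit$k, nrow(fit$x))
  d2 <- outer(rowSums(x^2), rowSums(fit$x^2), "+") - 2 * x %*% t(fit$x)
  d2[d2 < 0] <- 0
  vapply(seq_len(nrow(x)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    w <- 1 / (sqrt(d2[i, nn]) + 1e-8)
    sum(w[fit$y[nn]]) / sum(w)
  }, numeric(1))
}

## ---- meta level ----------------------------------------------------------

#' Out-of-fold meta-data for stacked generalization
#'
#' Each training instance's meta-features (one interacting-class probability
#' per base learner) come from base models fitted on internal stratified
#' folds that exclude it, the held-out scheme stacked generalization
#' requires. Both concatenation orders of a pair share a fold so sibling
#' rows cannot leak into each other's meta-features.
#'
#' @param x Numeric feature matrix (training instances in rows).
#' @param y Logical vector: is the instance interacting.
#' @param pair_id Grouping vector (one value per row) tying the two orders
#'   of a pair together; defaults to one group per row.
#' @param control A [ppi_control()].
#' @param seed Integer seed.
#' @return List: `meta` (matrix, one column per base learner), `folds`
#'   (integer row fold ids).
#' @export
build_meta_data <- function(x, y, pair_id = NULL,
                            control = ppi_control(), seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2L) abort("training data contain a single class")
  pair_id <- pair_id %||% seq_len(nrow(x))
  groups <- !duplicated(pair_id)
  gid <- pair_id[groups]
  gy <- y[groups]
  gfold <- stratified_folds(gy, control$meta_folds, seed = seed)
  folds <- gfold[match(pair_id, gid)]
  meta <- matrix(NA_real_, nrow(x), length(control$base_learners),
                 dimnames = list(NULL, paste0("m_", control$base_learners)))
  for (f in sort(unique(folds))) {
    in_tr <- folds != f
    if (length(unique(y[in_tr])) < 2L) {
      abort("an internal fold lost a class; stratification failure")
    }
    for (j in seq_along(control$base_learners)) {
      b <- control$base_learners[j]
      fit <- fit_base(b, x[in_tr, , drop = FALSE], y[in_tr], control,
                      seed = seed + 31L * j + f)
      meta[!in_tr, j] <- predict_base(b, fit, x[!in_tr, , drop = FALSE])
    }
  }
  list(meta = meta, folds = folds)
}

fit_meta_svm <- function(meta, y, pair_id, control, seed) {
  yf <- factor(ifelse(y, "interacting", "non-interacting"),
               levels = label_levels)
  grid <- expand.grid(cost = control$svm_cost, gamma = control$svm_gamma)
  if (nrow(grid) > 1L) {
    groups <- !duplicated(pair_id)
    gfold <- stratified_folds(y[groups], control$grid_folds, seed = seed)
    folds <- gfold[match(pair_id, pair_id[groups])]
    score <- vapply(seq_len(nrow(grid)), function(g) {
      preds <- rep(NA, length(y))
      for (f in sort(unique(folds))) {
        in_tr <- folds != f
        set.seed(seed + g)
        fit <- do_svm(meta[in_tr, , drop = FALSE], yf[in_tr],
                      grid$cost[g], grid$gamma[g], probability = FALSE)
        preds[!in_tr] <- predict(fit, meta[!in_tr, , drop = FALSE]) ==
          "interacting"
      }
      cm <- table(factor(y, c(TRUE, FALSE)), factor(preds, c(TRUE, FALSE)))
      mcc_counts(cm[1, 1], cm[2, 2], cm[2, 1], cm[1, 2])
    }, numeric(1))
    best <- which.max(score)
  } else best <- 1L
  set.seed(seed)
  fit <- do_svm(meta, yf, grid$cost[best], grid$gamma[best],
                probability = TRUE)
  list(fit = fit, cost = grid$cost[best], gamma = grid$gamma[best])
}

do_svm <- function(x, yf, cost, gamma, probability) {
  args <- list(x = x, y = yf, kernel = "radial", cost = cost,
               scale = FALSE, probability = probability)
  if (!is.na(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

predict_meta_svm <- function(ms, meta) {
  p <- attr(predict(ms$fit, meta, probability = TRUE),
            "probabilities")[, "interacting"]
  p[!is.finite(p)] <- 0.5
  unname(p)
}

# MCC-maximizing threshold over the sorted unique training probabilities;
# MCC ties resolve to the smaller threshold (higher sensitivity).
select_tau <- function(prob, y) {
  cand <- sort(unique(prob))
  mccs <- vapply(cand, function(t) {
    yh <- prob >= t
    mcc_counts(sum(y & yh), sum(!y & !yh), sum(!y & yh), sum(y & !yh))
  }, numeric(1))
  cand[which.max(mccs)]
}

## ---- feature assembly ----------------------------------------------------

# Order-symmetric (F2 + F3) feature block for a pair table.
symmetric_block <- function(pairs, model) {
  blocks <- list()
  if ("F2" %in% model$features) {
    for (ont in names(model$partitions)) {
      enc <- encode_go_pairs(pairs, model$partitions[[ont]],
                             model$ontologies[[ont]], model$annotations)
      blocks <- c(blocks, list(enc[, -(1:2), drop = FALSE]))
    }
  }
  if ("F3" %in% model$features) {
    tf <- suppressWarnings(topology_features(pairs, model$network))
    blocks <- c(blocks, list(tf[, -(1:2), drop = FALSE]))
  }
  if (length(blocks) == 0L) return(NULL)
  as.matrix(bind_cols(blocks))
}

# Per-protein AC vectors for the requested proteins; proteins without a
# usable sequence encode to zeros (degraded-feature policy) with a warning.
ac_block <- function(ids, proteins, model) {
  nm <- ac_feature_names(model$max_gap)
  out <- matrix(0, length(ids), length(nm),
                dimnames = list(ids, nm))
  known <- if (is.null(proteins)) character(0) else
    intersect(ids, proteins$protein_id)
  if (length(known) < length(ids)) {
    warn(sprintf("%d protein(s) without sequences encode to zero AC vectors",
                 length(ids) - length(known)))
  }
  if (length(known) > 0L) {
    ptab <- proteins[match(known, proteins$protein_id), ]
    enc <- encode_proteins(ptab, max_gap = model$max_gap,
                           scales = model$scales,
                           nonstandard = model$control$nonstandard)
    out[known, ] <- as.matrix(enc[, -1])
  }
  out
}

# Instance matrix: one row per concatenation order (two when F1 is on,
# one otherwise since the orders would be identical), plus bookkeeping.
instance_matrix <- function(pairs, model, proteins) {
  sym <- symmetric_block(pairs, model)
  n <- nrow(pairs)
  use_f1 <- "F1" %in% model$features
  orders <- if (use_f1) c("12", "21") else "12"
  if (use_f1) {
    ids <- unique(c(pairs$protein_1, pairs$protein_2))
    ac <- ac_block(ids, proteins, model)
    m <- ncol(ac)
    f1 <- matrix(0, n * length(orders), 2L * m)
    colnames(f1) <- c(paste0(colnames(ac), "_a"), paste0(colnames(ac), "_b"))
    f1[1:n, ] <- cbind(ac[pairs$protein_1, , drop = FALSE],
                       ac[pairs$protein_2, , drop = FALSE])
    if (length(orders) == 2L) {
      f1[(n + 1):(2 * n), ] <- cbind(ac[pairs$protein_2, , drop = FALSE],
                                     ac[pairs$protein_1, , drop = FALSE])
    }
    x <- if (is.null(sym)) f1 else
      cbind(f1, sym[rep(seq_len(n), length(orders)), , drop = FALSE])
  } else {
    if (is.null(sym)) abort("no feature block produced any features")
    x <- sym
  }
  rownames(x) <- NULL
  list(x = x, pair_index = rep(seq_len(n), length(orders)),
       order = rep(orders, each = n))
}

## ---- fit / predict -------------------------------------------------------

#' Fit the stacked protein-pair interaction classifier
#'
#' Fits the whole pipeline on a training dataset, strictly inside it: AC
#' encoding and the two-stage normalizer, the per-ontology LCA partitions,
#' the IC table / similarity-thresholded network, the out-of-fold base
#' learner meta-data, the RBF-SVM meta-classifier, and finally the
#' MCC-maximizing decision threshold on pair-level (order-averaged)
#' training probabilities.
#'
#' @param dataset A [ppi_dataset()] (its `pairs` are the training split).
#' @param features Feature blocks to use: subset of
#'   `c("F1", "F2", "F3")` (sequence auto-covariance, LCA-indexed GO
#'   clusters, network topology).
#' @param control A [ppi_control()].
#' @param seed Integer seed threaded to every stochastic component.
#' @return A fitted `ppi_stack` model.
#' @export
ppi_stack <- function(dataset, features = c("F1", "F2", "F3"),
                       control = ppi_control(), seed = 1L) {
  stopifnot(inherits(dataset, "ppi_dataset"),
            all(features %in% c("F1", "F2", "F3")), length(features) >= 1)
  pairs <- dataset$pairs
  y <- as_interacting(pairs$label)
  if (length(unique(y)) < 2L) abort("training pairs contain a single class")
  if ("F1" %in% features && is.null(dataset$proteins)) {
    abort("F1 requested but the dataset has no protein sequences")
  }
  if (any(c("F2", "F3") %in% features) &&
      (is.null(dataset$ontologies) || is.null(dataset$annotations))) {
    abort("F2/F3 requested but ontologies or annotations are missing")
  }
  train_prots <- unique(c(pairs$protein_1, pairs$protein_2))

  model <- list(features = features, control = control, seed = seed,
                ontologies = dataset$ontologies,
                annotations = dataset$annotations,
                scales = physchem_scales())

  if ("F1" %in% features) {
    lens <- nchar(vapply(dataset$proteins$sequence[
      dataset$proteins$protein_id %in% train_prots],
      function(s) suppressWarnings(sanitize_sequence(s, "drop")),
      character(1)))
    model$max_gap <- min(control$max_gap, min(lens) - 1L)
    if (model$max_gap < control$max_gap) {
      warn(sprintf("max_gap capped at %d by the shortest training sequence",
                   model$max_gap))
    }
  }
  if ("F2" %in% features) {
    model$partitions <- list()
    for (ont in names(dataset$ontologies)) {
      part <- tryCatch(
        partition_dag(pairs, dataset$ontologies[[ont]], dataset$annotations),
        error = function(e) NULL)
      if (is.null(part)) {
        inform(sprintf("ontology %s yields no LCA partition; skipped", ont))
      } else model$partitions[[ont]] <- part
    }
    if (length(model$partitions) == 0L) abort("no ontology could be partitioned")
  }
  if ("F3" %in% features) {
    model$ics <- lapply(dataset$ontologies, ic_table,
                        annotations = dataset$annotations,
                        corpus = train_prots)
    sims <- protein_similarities(train_prots, dataset$ontologies,
                                 dataset$annotations, model$ics)
    n_s <- build_reference_network(pairs, nodes = train_prots)
    model$theta <- select_threshold(sims, n_s)
    model$network <- build_ppi_network(sims, model$theta, train_prots)
    model$reference <- n_s
  }

  inst <- instance_matrix(pairs, model, dataset$proteins)
  model$normalizer <- fit_normalizer(inst$x)
  xn <- apply_normalizer(model$normalizer, inst$x)
  yy <- y[inst$pair_index]

  md <- build_meta_data(xn, yy, pair_id = inst$pair_index,
                        control = control, seed = seed)
  model$base_fits <- lapply(seq_along(control$base_learners), function(j) {
    fit_base(control$base_learners[j], xn, yy, control,
             seed = seed + 977L * j)
  })
  names(model$base_fits) <- control$base_learners
  model$meta <- fit_meta_svm(md$meta, yy, inst$pair_index, control,
                             seed = seed + 5000L)
  oof_prob <- predict_meta_svm(model$meta, md$meta)
  pair_prob <- vapply(split(oof_prob, inst$pair_index), mean, numeric(1))
  pair_prob <- pair_prob[order(as.integer(names(pair_prob)))]
  model$tau <- select_tau(pair_prob, y)
  model$train_scores <- tibble(protein_1 = pairs$protein_1,
                               protein_2 = pairs$protein_2,
                               label = pairs$label, prob = unname(pair_prob))
  model$n_pairs <- nrow(pairs)
  model$n_features <- ncol(xn)
  structure(model, class = "ppi_stack")
}

#' @export
print.ppi_stack <- function(x, ...) {
  cat(sprintf(paste0("<ppi_stack: %d training pairs, %d features (%s), ",
                     "%d base learners, tau = %.3f>\n"),
              x$n_pairs, x$n_features, paste(x$features, collapse = "+"),
              length(x$base_fits), x$tau))
  invisible(x)
}

#' Predict interaction probabilities for protein pairs
#'
#' The meta-probability is computed for both concatenation orders of each
#' pair and averaged, so `predict(m, A, B)` and `predict(m, B, A)` are
#' identical by construction. Pairs are labeled interacting when the
#' averaged probability reaches the fitted threshold `tau`.
#'
#' @param object A fitted [ppi_stack()] model.
#' @param pairs Data frame with `protein_1`, `protein_2` (a `ppi_dataset`
#'   is also accepted).
#' @param proteins Sequence table for proteins unseen at training (only
#'   needed when F1 is enabled).
#' @param annotations Annotation table covering the new proteins (F2/F3).
#' @param ... Unused.
#' @return Tibble: `protein_1`, `protein_2`, `prob`, `label`.
#' @export
predict.ppi_stack <- function(object, pairs, proteins = NULL,
                               annotations = NULL, ...) {
  if (inherits(pairs, "ppi_dataset")) {
    proteins <- proteins %||% pairs$proteins
    annotations <- annotations %||% pairs$annotations
    pairs <- pairs$pairs
  }
  model <- object
  if (!is.null(annotations)) model$annotations <- annotations
  # canonical pair orientation: predict(A, B) and predict(B, A) then build
  # bit-identical instance matrices, making symmetry exact
  canon <- tibble(protein_1 = pmin(pairs$protein_1, pairs$protein_2),
                  protein_2 = pmax(pairs$protein_1, pairs$protein_2))
  inst <- instance_matrix(canon, model, proteins)
  xn <- apply_normalizer(model$normalizer, inst$x)
  meta <- vapply(seq_along(model$base_fits), function(j) {
    predict_base(names(model$base_fits)[j], model$base_fits[[j]], xn)
  }, numeric(nrow(xn)))
  meta <- matrix(meta, nrow = nrow(xn),
                 dimnames = list(NULL, paste0("m_", names(model$base_fits))))
  prob <- predict_meta_svm(model$meta, meta)
  pair_prob <- vapply(split(prob, inst$pair_index), mean, numeric(1))
  pair_prob <- unname(pair_prob[order(as.integer(names(pair_prob)))])
  tibble(protein_1 = pairs$protein_1, protein_2 = pairs$protein_2,
         prob = pair_prob,
         label = ifelse(pair_prob >= model$tau,
                        "interacting", "non-interacting"))
}
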