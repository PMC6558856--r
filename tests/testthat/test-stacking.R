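small_ds <- function(seed = 7, n_pairs = 60, ...) {
  generate_dataset(synthetic_config(seed = seed, n_proteins = 40,
                                    n_pairs = n_pairs, n_terms = 30,
                                    ontologies = c("BP", "CC"), ...))
}

fit_quiet <- function(ds, ...) {
  suppressMessages(suppressWarnings(ppi_stack(ds, ...)))
}

test_that("out-of-fold meta-data has one probability column per base", {
  set.seed(1)
  x <- matrix(rnorm(200), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] + rnorm(50, sd = 0.3) > 0
  ctl <- fast_control()
  md <- build_meta_data(x, y, control = ctl, seed = 2)
  expect_equal(dim(md$meta), c(50, 4))
  expect_true(all(md$meta >= 0 & md$meta <= 1))
  expect_false(anyNA(md$meta))
  # determinism under a fixed seed
  md2 <- build_meta_data(x, y, control = ctl, seed = 2)
  expect_identical(md$meta, md2$meta)
  expect_error(build_meta_data(x, rep(TRUE, 50), control = ctl),
               "single class")
})

test_that("meta-features separate cleanly on near-separable data", {
  set.seed(3)
  x <- matrix(rnorm(400), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(TRUE, FALSE), each = 50)
  x[y, 1] <- x[y, 1] + 4 # wide margin on one feature
  md <- build_meta_data(x, y, control = fast_control(), seed = 5)
  expect_gt(mean(md$meta[y, ]), 0.75)
  expect_lt(mean(md$meta[!y, ]), 0.25)
})

test_that("the fitted pipeline is reproducible and threshold-optimal", {
  ds <- small_ds()
  ctl <- fast_control()
  m1 <- fit_quiet(ds, control = ctl, seed = 11)
  m2 <- fit_quiet(ds, control = ctl, seed = 11)
  expect_identical(m1$tau, m2$tau)
  expect_identical(m1$train_scores$prob, m2$train_scores$prob)
  # tau maximizes training MCC, so it is at least as good as a 0.5 cut
  sc <- m1$train_scores
  mcc_at <- function(t) {
    compute_metrics(dplyr::mutate(sc, truth = label), truth = "truth",
                    prob = "prob", threshold = t)$mcc
  }
  expect_gte(mcc_at(m1$tau), mcc_at(0.5))
  man <- model_manifest(m1)
  expect_equal(man$base_learners, c("rf", "nb", "ann", "knn"))
  expect_true(man$tau >= 0 && man$tau <= 1)
})

test_that("feature-block ablation configurations all fit", {
  ds <- small_ds(n_pairs = 40)
  ctl <- fast_control()
  for (fs in list("F1", "F2", c("F1", "F2", "F3"))) {
    m <- fit_quiet(ds, features = fs, control = ctl, seed = 3)
    expect_s3_class(m, "ppi_stack")
    pr <- suppressWarnings(predict(m, ds$pairs[1:4, ],
                                   proteins = ds$proteins,
                                   annotations = ds$annotations))
    expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  }
})

test_that("prediction is exactly symmetric in the pair arguments", {
  ds <- small_ds()
  m <- fit_quiet(ds, control = fast_control(), seed = 1)
  p <- ds$pairs[1:10, ]
  fwd <- suppressWarnings(predict(m, p, proteins = ds$proteins,
                                  annotations = ds$annotations))
  rev <- suppressWarnings(predict(
    m, dplyr::tibble(protein_1 = p$protein_2, protein_2 = p$protein_1),
    proteins = ds$proteins, annotations = ds$annotations))
  expect_identical(fwd$prob, rev$prob)
  expect_identical(fwd$label, rev$label)
})

test_that("fitting ignores anything outside the training split", {
  ds <- small_ds(n_pairs = 50)
  train_idx <- 1:36
  train_prots <- unique(c(ds$pairs$protein_1[train_idx],
                          ds$pairs$protein_2[train_idx]))
  full <- ppi_dataset(ds$pairs[train_idx, ], proteins = ds$proteins,
                      ontologies = ds$ontologies,
                      annotations = ds$annotations)
  trimmed <- ppi_dataset(
    ds$pairs[train_idx, ],
    proteins = dplyr::filter(ds$proteins, protein_id %in% train_prots),
    ontologies = ds$ontologies,
    annotations = dplyr::filter(ds$annotations,
                                protein_id %in% train_prots))
  ctl <- fast_control()
  m_full <- fit_quiet(full, control = ctl, seed = 9)
  m_trim <- fit_quiet(trimmed, control = ctl, seed = 9)
  expect_identical(m_full$tau, m_trim$tau)
  expect_identical(m_full$theta, m_trim$theta)
  expect_identical(m_full$normalizer, m_trim$normalizer)
  expect_identical(m_full$train_scores$prob, m_trim$train_scores$prob)
  expect_identical(lapply(m_full$partitions, `[[`, "clusters"),
                   lapply(m_trim$partitions, `[[`, "clusters"))
})

test_that("a single-base configuration degenerates gracefully", {
  ds <- small_ds(n_pairs = 40)
  ctl <- fast_control(base_learners = "rf")
  m <- fit_quiet(ds, control = ctl, seed = 2)
  expect_equal(length(m$base_fits), 1L)
  pr <- suppressWarnings(predict(m, ds$pairs[1:3, ],
                                 proteins = ds$proteins,
                                 annotations = ds$annotations))
  expect_true(all(is.finite(pr$prob)))
})

test_that("held-out accuracy is high on fully separable data", {
  ds <- generate_dataset(synthetic_config(seed = 21, n_proteins = 60,
                                          n_pairs = 150, go_signal = 1,
                                          motif_rate = 1))
  tr <- ppi_dataset(ds$pairs[1:100, ], proteins = ds$proteins,
                    ontologies = ds$ontologies,
                    annotations = ds$annotations)
  m <- fit_quiet(tr, control = fast_control(), seed = 4)
  held <- ds$pairs[101:150, ]
  pr <- suppressWarnings(predict(m, held, proteins = ds$proteins,
                                 annotations = ds$annotations))
  acc <- mean(pr$label == held$label)
  expect_gt(acc, 0.95)
  # stacking at least keeps up with its best base out-of-fold (soft check)
  inst <- suppressWarnings(
    ppistack:::instance_matrix(tr$pairs, m, ds$proteins))
  xn <- apply_normalizer(m$normalizer, inst$x)
  yy <- (tr$pairs$label == "interacting")[inst$pair_index]
  md <- build_meta_data(xn, yy, pair_id = inst$pair_index,
                        control = fast_control(), seed = 4)
  base_mcc <- apply(md$meta, 2, function(p) {
    compute_metrics(tibble::tibble(truth = yy, prob = p))$mcc
  })
  meta_mcc <- compute_metrics(
    dplyr::mutate(m$train_scores, truth = label), truth = "truth",
    prob = "prob", threshold = m$tau)$mcc
  expect_gte(meta_mcc, max(base_mcc) - 0.1)
})

test_that("missing inputs for an enabled block are rejected", {
  ds <- small_ds(n_pairs = 40)
  no_seq <- ppi_dataset(ds$pairs, proteins = NULL,
                        ontologies = ds$ontologies,
                        annotations = ds$annotations)
  expect_error(ppi_stack(no_seq, features = "F1"), "no protein sequences")
  no_go <- ppi_dataset(ds$pairs, proteins = ds$proteins)
  expect_error(ppi_stack(no_go, features = c("F2", "F3")), "missing")
  one_class <- ppi_dataset(
    dplyr::mutate(ds$pairs, label = "interacting"),
    proteins = ds$proteins, ontologies = ds$ontologies,
    annotations = ds$annotations)
  expect_error(ppi_stack(one_class), "single class")
})
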