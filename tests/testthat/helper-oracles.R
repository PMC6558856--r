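# Independent brute-force oracles used to cross-check the implementation.
# They are written directly from the defining formulas, term by term, and
# deliberately share no code with the package internals.

# Lagged auto-covariance, literal sum.
oracle_ac <- function(x, g) {
  L <- length(x)
  if (g >= L) return(0)
  mu <- sum(x) / L
  s <- 0
  for (j in 1:(L - g)) s <- s + (x[j] - mu) * (x[j + g] - mu)
  s / (L - g)
}

# Full AC encoding via the double loop (scale-major then gap).
oracle_encode <- function(sequence, scales, max_gap) {
  chars <- strsplit(sequence, "")[[1]]
  out <- c()
  for (s in setdiff(names(scales), "aa")) {
    x <- scales[[s]][match(chars, scales$aa)]
    for (g in seq_len(max_gap)) out <- c(out, oracle_ac(x, g))
  }
  out
}

# Two-stage normalization, column by column.
oracle_normalize <- function(train, new) {
  apply_col <- function(j) {
    a <- train[, j]
    mu <- mean(a); sdv <- sd(a)
    if (sdv == 0) sdv <- 1
    s_train <- (a - mu) / sdv
    s_new <- (new[, j] - mu) / sdv
    rng <- max(s_train) - min(s_train)
    if (rng == 0) return(rep(0, length(s_new)))
    v <- (s_new - min(s_train)) / rng
    pmin(pmax(v, 0), 1)
  }
  sapply(seq_len(ncol(train)), apply_col)
}

# Small random rooted DAG (node 1 is the root); independent of the
# package's generator.
random_test_dag <- function(n, ontology = "BP") {
  ids <- sprintf("T%02d", seq_len(n))
  child <- parent <- character(0)
  for (i in 2:n) {
    k <- sample(1:min(2, i - 1), 1)
    ps <- sample(seq_len(i - 1), k)
    child <- c(child, rep(ids[i], k))
    parent <- c(parent, ids[ps])
  }
  list(edges = tibble::tibble(child = child, parent = parent),
       dag = go_dag(tibble::tibble(child = child, parent = parent),
                    ontology = ontology),
       ids = ids)
}

# Ancestors (inclusive) from the raw edge table by repeated expansion.
oracle_ancestors <- function(edges, term) {
  anc <- term
  repeat {
    more <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(more, anc)
    if (length(new) == 0) break
    anc <- c(anc, new)
  }
  anc
}

# Number of distinct cluster terms on any ascending path (restricted to
# the cluster) from the pair's terms up to the cluster LCA, by explicit
# path enumeration.
oracle_cluster_count <- function(edges, cluster, lca, terms) {
  nodes <- character(0)
  walk <- function(t, path) {
    if (!(t %in% cluster)) return(invisible())
    path <- c(path, t)
    if (t == lca) {
      nodes <<- union(nodes, path)
      return(invisible())
    }
    for (p in edges$parent[edges$child == t]) walk(p, path)
    invisible()
  }
  for (t in intersect(terms, cluster)) walk(t, character(0))
  length(nodes)
}

# Term-level Resnik by scanning common ancestors; protein-level by the
# literal double loop over the annotation cross product.
oracle_resnik_term <- function(edges, ic_tbl, t1, t2) {
  common <- intersect(oracle_ancestors(edges, t1),
                      oracle_ancestors(edges, t2))
  vals <- ic_tbl$ic[match(common, ic_tbl$term)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) 0 else max(vals)
}

oracle_resnik_protein <- function(edges, ic_tbl, terms_i, terms_j) {
  if (length(terms_i) == 0 || length(terms_j) == 0) return(0)
  best <- 0
  for (a in terms_i) for (b in terms_j) {
    best <- max(best, oracle_resnik_term(edges, ic_tbl, a, b))
  }
  best
}

# Topology features from the raw undirected edge table.
oracle_topology <- function(edge_tbl, p1, p2) {
  nb <- function(p) {
    unique(c(edge_tbl$b[edge_tbl$a == p], edge_tbl$a[edge_tbl$b == p]))
  }
  ni <- nb(p1); nj <- nb(p2)
  cn <- intersect(ni, nj)
  degs <- sapply(cn, function(p) length(nb(p)))
  aa <- if (length(cn) == 0) 0 else sum(ifelse(degs > 1, 1 / log(degs), 0))
  un <- union(ni, nj)
  c(cn = length(cn),
    jaccard = if (length(un) == 0) 0 else length(cn) / length(un),
    aa = aa,
    pa = length(ni) * length(nj),
    oo = if (length(ni) == 0 || length(nj) == 0) 0 else
      length(cn) / sqrt(length(ni) * length(nj)))
}

# Metrics from counts, straight from the defining ratios.
oracle_metrics <- function(tp, tn, fp, fn) {
  div <- function(a, b) if (b == 0) 0 else a / b
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  tpr <- div(tp, tp + fn); prec <- div(tp, tp + fp)
  c(tpr = tpr, fpr = div(fp, fp + tn), precision = prec,
    accuracy = div(tp + tn, tp + tn + fp + fn),
    f_score = div(2 * tpr * prec, tpr + prec),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

# Closed-form paired t statistic and two-sided p.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  c(statistic = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# Counts -> expanded truth/prediction vectors (for metric checks).
counts_to_data <- function(tp, tn, fp, fn) {
  tibble::tibble(
    truth = c(rep(TRUE, tp + fn), rep(FALSE, tn + fp)),
    pred = c(rep(TRUE, tp), rep(FALSE, fn), rep(FALSE, tn), rep(TRUE, fp)),
    prob = c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
  )
}

# A light control used throughout the tests: same architecture, desk-scale
# capacity.
fast_control <- function(...) {
  defaults <- list(max_gap = 3, rf_ntree = 100, ann_size = 6,
                   ann_maxit = 100, svm_cost = c(1, 10), svm_gamma = NA,
                   meta_folds = 3, grid_folds = 2)
  do.call(ppi_control, utils::modifyList(defaults, list(...)))
}
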