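# Annotation tables are tidy: one row per (protein_id, ontology, term).
# Helper: the term sets of given proteins restricted to one DAG's ontology.
protein_terms <- function(annotations, dag, proteins) {
  ann <- annotations
  if ("ontology" %in% names(ann)) {
    ann <- filter(ann, .data$ontology == dag$ontology)
  }
  ann <- filter(ann, .data$term %in% dag$terms,
                .data$protein_id %in% proteins)
  sets <- split(ann$term, factor(ann$protein_id, levels = proteins))
  lapply(sets, unique)
}

#' Lowest common ancestor of a protein pair's GO terms
#'
#' Traverses the hierarchy upward from the union of the two proteins' term
#' sets to their lowest (deepest) common ancestor. Every term counts as an
#' ancestor of itself. When a DAG admits several lowest common ancestors the
#' deepest-level candidate wins, remaining ties broken by lexicographic term
#' id, so the result is a single designated term.
#'
#' @param dag A [go_dag()].
#' @param terms_i,terms_j Character vectors of term ids annotating the two
#'   proteins (restricted to this ontology).
#' @return A term id, or `NA_character_` when either set is empty.
#' @export
pair_lca <- function(dag, terms_i, terms_j) {
  stopifnot(inherits(dag, "go_dag"))
  if (length(terms_i) == 0L || length(terms_j) == 0L) return(NA_character_)
  all_terms <- unique(c(terms_i, terms_j))
  missing <- setdiff(all_terms, dag$terms)
  if (length(missing) > 0L) {
    abort(sprintf("term(s) not in %s ontology: %s", dag$ontology,
                  paste(head(missing, 5), collapse = ", ")))
  }
  common <- Reduce(intersect, dag$ancestors[all_terms])
  # guaranteed non-empty: the root is a universal ancestor
  if (length(common) == 0L) {
    abort("terms share no common ancestor; not a single rooted DAG")
  }
  lev <- dag$level[common]
  cand <- common[lev == max(lev)]
  sort(cand)[1]
}

#' Partition a GO DAG by the LCAs of training protein pairs
#'
#' Computes one LCA per training pair (over the union of both proteins'
#' annotations), collapses duplicates, orders the LCAs deepest level first
#' (ties by term id) and then greedily assigns each LCA's descendants -- minus
#' terms already claimed by a deeper LCA -- to its cluster. The result is a
#' set of mutually exclusive LCA-rooted subgraphs; terms outside every
#' cluster simply contribute nothing to the encoding.
#'
#' @param pairs Data frame with columns `protein_1`, `protein_2`.
#' @param dag A [go_dag()].
#' @param annotations Data frame with columns `protein_id`, `term` and
#'   optionally `ontology`.
#' @return An `lca_partition` object with the ordered LCA list, cluster
#'   memberships, and precomputed within-cluster ascending-path node sets.
#' @export
partition_dag <- function(pairs, dag, annotations) {
  stopifnot(inherits(dag, "go_dag"),
            all(c("protein_1", "protein_2") %in% names(pairs)))
  if (nrow(pairs) == 0L) abort("empty training pair set")
  prots <- unique(c(pairs$protein_1, pairs$protein_2))
  tsets <- protein_terms(annotations, dag, prots)
  lcas <- vapply(seq_len(nrow(pairs)), function(i) {
    pair_lca(dag, tsets[[pairs$protein_1[i]]] %||% character(0),
             tsets[[pairs$protein_2[i]]] %||% character(0))
  }, character(1))
  n_missing <- sum(is.na(lcas))
  if (n_missing > 0L) {
    inform(sprintf("%d pair(s) without %s annotations contribute no LCA",
                   n_missing, dag$ontology))
  }
  lcas <- unique(lcas[!is.na(lcas)])
  if (length(lcas) == 0L) {
    abort(sprintf("no pair yields an LCA in ontology %s", dag$ontology))
  }
  lev <- dag$level[lcas]
  ord <- order(-lev, lcas)
  lcas <- lcas[ord]
  assigned <- character(0)
  clusters <- vector("list", length(lcas))
  names(clusters) <- lcas
  for (l in lcas) {
    clusters[[l]] <- setdiff(term_descendants(dag, l), assigned)
    assigned <- c(assigned, clusters[[l]])
  }
  paths <- lapply(lcas, function(l) cluster_paths(dag, clusters[[l]], l))
  names(paths) <- lcas
  cluster_of <- setNames(rep(lcas, lengths(clusters)),
                         unlist(clusters, use.names = FALSE))
  structure(
    list(ontology = dag$ontology, lcas = lcas, level = dag$level[lcas],
         clusters = clusters, cluster_of = cluster_of, paths = paths),
    class = "lca_partition"
  )
}

#' @export
print.lca_partition <- function(x, ...) {
  cat(sprintf("<lca_partition %s: %d clusters (sizes %s)>\n", x$ontology,
              length(x$lcas), paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

# For every term of a cluster, the set of distinct cluster terms lying on
# some ascending path (restricted to the cluster) from that term up to the
# cluster's LCA root, endpoints included. A term whose every upward route
# leaves the cluster before reaching the LCA yields the empty set.
cluster_paths <- function(dag, cluster, lca) {
  memo <- list()
  upR <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- intersect(dag$parents[[t]], cluster)
    res <- unique(c(t, unlist(lapply(ps, upR), use.names = FALSE)))
    memo[[t]] <<- res
    res
  }
  for (t in cluster) upR(t)
  lapply(setNames(cluster, cluster), function(t) {
    u <- memo[[t]]
    u[vapply(u, function(x) lca %in% memo[[x]], logical(1))]
  })
}

#' Encode protein pairs as LCA-indexed GO-term cluster features
#'
#' For each cluster of the partition, the feature value is the number of
#' distinct cluster terms encountered on the ascending paths (restricted to
#' the cluster) from the pair's annotated terms up to the cluster's LCA root,
#' endpoints included. Clusters containing none of the pair's terms score 0;
#' unannotated pairs yield the all-zero vector. The encoding uses the union
#' of both proteins' term sets, so it is symmetric in the pair.
#'
#' @param pairs Data frame with columns `protein_1`, `protein_2`.
#' @param partition An [partition_dag()] result.
#' @param dag The same [go_dag()] the partition was built on.
#' @param annotations Annotation table (`protein_id`, `term`, optional
#'   `ontology`).
#' @return Tibble: `protein_1`, `protein_2` plus one non-negative integer
#'   column per LCA, named `f2_<ontology>_<index>` in sorted-LCA order
#'   (deepest first).
#' @export
encode_go_pairs <- function(pairs, partition, dag, annotations) {
  stopifnot(inherits(partition, "lca_partition"), inherits(dag, "go_dag"),
            identical(partition$ontology, dag$ontology))
  prots <- unique(c(pairs$protein_1, pairs$protein_2))
  tsets <- protein_terms(annotations, dag, prots)
  feat <- matrix(0L, nrow = nrow(pairs), ncol = length(partition$lcas))
  for (i in seq_len(nrow(pairs))) {
    terms <- unique(c(tsets[[pairs$protein_1[i]]],
                      tsets[[pairs$protein_2[i]]]))
    if (length(terms) == 0L) next
    for (k in seq_along(partition$lcas)) {
      l <- partition$lcas[k]
      hit <- intersect(terms, partition$clusters[[l]])
      if (length(hit) == 0L) next
      nodes <- unique(unlist(partition$paths[[l]][hit], use.names = FALSE))
      feat[i, k] <- length(nodes)
    }
  }
  colnames(feat) <- paste0("f2_", partition$ontology,
                           "_", seq_along(partition$lcas))
  bind_cols(as_tibble(pairs[, c("protein_1", "protein_2")]),
            as_tibble(feat))
}
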