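#' Information content of ontology terms from an annotation corpus
#'
#' Counts, for every term, the number of corpus proteins annotated to it
#' directly or through a descendant (ancestor propagation), and sets
#' `IC(t) = -log p(t)` with `p(t)` the fraction of annotated corpus proteins
#' covering `t` (natural log). The root covers every annotated protein, so
#' `IC(root) = 0`; IC is non-decreasing from root to leaves.
#'
#' @param dag A [go_dag()].
#' @param annotations Annotation table (`protein_id`, `term`, optional
#'   `ontology`).
#' @param corpus Character vector of protein ids forming the corpus
#'   (typically the training-split proteins). Defaults to every annotated
#'   protein in the table.
#' @return An `ic_table`: tibble with columns `term`, `count`, `p`, `ic`
#'   (one row per term with a positive count), carrying the ontology and
#'   corpus size as attributes.
#' @export
ic_table <- function(dag, annotations, corpus = NULL) {
  stopifnot(inherits(dag, "go_dag"))
  corpus <- corpus %||% unique(annotations$protein_id)
  tsets <- protein_terms(annotations, dag, corpus)
  tsets <- tsets[lengths(tsets) > 0L]
  n <- length(tsets)
  counts <- setNames(integer(length(dag$terms)), dag$terms)
  for (ts in tsets) {
    closure <- term_ancestors(dag, ts)
    counts[closure] <- counts[closure] + 1L
  }
  tbl <- tibble(term = names(counts), count = unname(counts)) |>
    filter(.data$count > 0L) |>
    mutate(p = .data$count / n, ic = -log(.data$p))
  structure(tbl, ontology = dag$ontology, n_proteins = n,
            class = c("ic_table", class(tbl)))
}

ic_lookup <- function(ic) {
  setNames(ic$ic, ic$term)
}

#' Resnik semantic similarity between two terms
#'
#' The information content of the most informative common ancestor (each
#' term counts as its own ancestor). Terms whose only informative common
#' ancestor is the root score 0.
#'
#' @param ic An [ic_table()].
#' @param dag The matching [go_dag()].
#' @param t_i,t_j Term ids.
#' @return Non-negative similarity value.
#' @export
resnik_term_sim <- function(ic, dag, t_i, t_j) {
  common <- intersect(term_ancestors(dag, t_i), term_ancestors(dag, t_j))
  vals <- ic_lookup(ic)[common]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) return(0)
  max(vals)
}

#' Resnik similarity between two proteins
#'
#' The maximum term-level Resnik similarity over the cross product of the
#' two annotation sets; equivalently, the maximum IC over the intersection
#' of the two sets' inclusive ancestor closures. Either side empty scores 0.
#'
#' @inheritParams resnik_term_sim
#' @param terms_i,terms_j Character vectors of annotated terms.
#' @return Non-negative similarity value.
#' @export
resnik_protein_sim <- function(ic, dag, terms_i, terms_j) {
  if (length(terms_i) == 0L || length(terms_j) == 0L) return(0)
  common <- intersect(term_ancestors(dag, terms_i),
                      term_ancestors(dag, terms_j))
  vals <- ic_lookup(ic)[common]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) return(0)
  max(vals)
}

#' All-pairs protein similarities over one or more subontologies
#'
#' For network construction the protein-level similarity is the maximum of
#' the per-subontology Resnik values, giving a single threshold scale.
#'
#' @param proteins Character vector of protein ids.
#' @param dags Named list of [go_dag()] objects.
#' @param annotations Annotation table.
#' @param ics Named list of [ic_table()]s parallel to `dags`.
#' @return Tibble of all unordered pairs: `protein_1`, `protein_2`,
#'   `similarity`.
#' @export
protein_similarities <- function(proteins, dags, annotations, ics) {
  stopifnot(length(dags) == length(ics))
  n <- length(proteins)
  if (n < 2L) return(tibble(protein_1 = character(0),
                            protein_2 = character(0),
                            similarity = numeric(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sim <- numeric(nrow(idx))
  for (k in seq_along(dags)) {
    dag <- dags[[k]]
    icv <- ic_lookup(ics[[k]])
    tsets <- protein_terms(annotations, dag, proteins)
    closures <- lapply(tsets, function(ts) {
      if (length(ts) == 0L) character(0) else term_ancestors(dag, ts)
    })
    s_k <- vapply(seq_len(nrow(idx)), function(r) {
      common <- intersect(closures[[idx[r, 1]]], closures[[idx[r, 2]]])
      v <- icv[common]
      v <- v[is.finite(v)]
      if (length(v) == 0L) 0 else max(v)
    }, numeric(1))
    sim <- pmax(sim, s_k)
  }
  tibble(protein_1 = proteins[idx[, 1]], protein_2 = proteins[idx[, 2]],
         similarity = sim)
}

new_ppi_network <- function(edges, nodes, provenance, theta = NA_real_) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  structure(list(graph = g, nodes = nodes, provenance = provenance,
                 theta = theta),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network %s: %d nodes, %d edges, mean degree %.3f%s>\n",
              x$provenance, length(x$nodes),
              igraph::ecount(x$graph), average_degree(x),
              if (is.na(x$theta)) "" else sprintf(", theta = %.4g", x$theta)))
  invisible(x)
}

#' Average degree of a network
#' @param net A `ppi_network`.
#' @return Numeric scalar `2 * |E| / |V|`.
#' @export
average_degree <- function(net) {
  2 * igraph::ecount(net$graph) / length(net$nodes)
}

#' Reference interaction network from positive training labels
#'
#' Two proteins are connected only when their pair is labeled interacting in
#' the training set; every training protein is a node.
#'
#' @param pairs Data frame with `protein_1`, `protein_2`, `label`
#'   (`"interacting"` / `"non-interacting"`).
#' @param nodes Node set; defaults to all proteins in `pairs`.
#' @return A `ppi_network` with provenance `"reference"`.
#' @export
build_reference_network <- function(pairs, nodes = NULL) {
  stopifnot(all(c("protein_1", "protein_2", "label") %in% names(pairs)))
  nodes <- nodes %||% unique(c(pairs$protein_1, pairs$protein_2))
  pos <- filter(pairs, .data$label == "interacting",
                .data$protein_1 != .data$protein_2)
  new_ppi_network(pos[, c("protein_1", "protein_2")], nodes, "reference")
}

#' Select the similarity threshold by average-degree matching
#'
#' Candidate thresholds are the observed similarity values (plus `+Inf` for
#' the empty network); edges with `similarity >= theta` are kept. The chosen
#' threshold makes the thresholded network's average degree closest to the
#' reference network's; ties resolve to the larger threshold (sparser
#' network).
#'
#' @param similarities Tibble from [protein_similarities()].
#' @param n_s Reference `ppi_network` from [build_reference_network()].
#' @return Numeric threshold `theta`.
#' @export
select_threshold <- function(similarities, n_s) {
  stopifnot(inherits(n_s, "ppi_network"))
  sims <- similarities$similarity
  if (length(sims) == 0L) abort("no similarities to threshold")
  if (length(unique(sims)) == 1L) {
    warn("all similarities are equal; threshold selection is degenerate")
  }
  target <- average_degree(n_s)
  n_nodes <- length(n_s$nodes)
  cand <- sort(unique(c(sims, Inf)))
  avg <- vapply(cand, function(th) 2 * sum(sims >= th) / n_nodes, numeric(1))
  err <- abs(avg - target)
  best <- which(err == min(err))
  cand[max(best)]
}

#' Build the similarity-thresholded interaction network
#'
#' @inheritParams select_threshold
#' @param theta Similarity threshold (from [select_threshold()]).
#' @param nodes Node set (training proteins).
#' @return A `ppi_network` with provenance `"thresholded"`.
#' @export
build_ppi_network <- function(similarities, theta, nodes) {
  keep <- filter(similarities, .data$similarity >= theta,
                 .data$protein_1 != .data$protein_2)
  new_ppi_network(keep[, c("protein_1", "protein_2")], nodes,
                  "thresholded", theta = theta)
}

#' Link-prediction topology features for protein pairs
#'
#' Five symmetric features of the neighbour sets `N(P)` in the network:
#' common-neighbour count, Jaccard index, Adamic-Adar index (natural log;
#' degree-1 common neighbours contribute 0), preferential attachment
#' `|N(P_i)| * |N(P_j)|`, and the Otsuka-Ochiai (cosine) coefficient.
#' Proteins absent from the network are treated as isolated; `0/0` ratios
#' resolve to 0.
#'
#' @param pairs Data frame with `protein_1`, `protein_2`.
#' @param net A `ppi_network`.
#' @return Tibble: the pair columns plus `f3_cn`, `f3_jaccard`, `f3_aa`,
#'   `f3_pa`, `f3_oo`.
#' @export
topology_features <- function(pairs, net) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- igraph::as_adj_list(net$graph)
  nbrs <- lapply(adj, function(v) names(v))
  names(nbrs) <- names(igraph::V(net$graph))
  get_n <- function(p) nbrs[[p]] %||% character(0)
  skipped <- 0L
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    ni <- get_n(pairs$protein_1[i])
    nj <- get_n(pairs$protein_2[i])
    cn <- intersect(ni, nj)
    un <- union(ni, nj)
    degs <- lengths(nbrs[cn])
    low <- degs <= 1L
    skipped <<- skipped + sum(low)
    aa <- if (length(cn) == 0L) 0 else sum(1 / log(degs[!low]))
    pa <- length(ni) * length(nj)
    c(f3_cn = length(cn),
      f3_jaccard = if (length(un) == 0L) 0 else length(cn) / length(un),
      f3_aa = aa,
      f3_pa = pa,
      f3_oo = if (pa == 0L) 0 else length(cn) / sqrt(pa))
  })
  if (skipped > 0L) {
    warn(sprintf(
      "%d degree-1 common neighbour contribution(s) skipped in Adamic-Adar",
      skipped))
  }
  bind_cols(as_tibble(pairs[, c("protein_1", "protein_2")]),
            as_tibble(do.call(rbind, out)))
}
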