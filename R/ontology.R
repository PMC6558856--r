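#' Build a rooted GO-style DAG from a child-parent edge table
#'
#' Each subontology (BP, CC, MF) is a rooted directed acyclic graph of terms
#' with child-to-parent edges (`is_a` / `part_of`). The constructor validates
#' acyclicity and the unique root, and precomputes for every term its
#' inclusive ancestor closure and hierarchical level (length of the longest
#' path from the root, the standard GO depth convention on DAGs).
#'
#' @param edges Data frame with columns `child` and `parent` (term ids);
#'   an optional `relation` column is kept for provenance.
#' @param ontology Subontology label, e.g. `"BP"`, `"CC"`, `"MF"`.
#' @return A `go_dag` object.
#' @export
go_dag <- function(edges, ontology = "BP") {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  edges <- as_tibble(edges)
  edges <- distinct(edges, .data$child, .data$parent,
                    .keep_all = TRUE)
  if (any(edges$child == edges$parent)) abort("self-loop edge in ontology")
  terms <- sort(unique(c(edges$child, edges$parent)))
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms)
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    abort(sprintf("ontology graph contains a cycle (involving '%s')",
                  cyc[1]))
  }
  has_parent <- terms %in% edges$child
  roots <- terms[!has_parent]
  if (length(roots) != 1L) {
    abort(sprintf("expected exactly one root term, found %d (%s)",
                  length(roots), paste(head(roots, 5), collapse = ", ")))
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  # topological order child -> parent; reverse gives root-first
  topo <- names(igraph::topo_sort(g, mode = "out"))
  root_first <- rev(topo)
  anc <- vector("list", length(terms))
  names(anc) <- terms
  lev <- setNames(integer(length(terms)), terms)
  for (t in root_first) {
    ps <- parents[[t]]
    if (length(ps) == 0L) {
      anc[[t]] <- t
      lev[[t]] <- 0L
    } else {
      anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
      lev[[t]] <- max(lev[ps]) + 1L
    }
  }
  structure(
    list(ontology = ontology, terms = terms, edges = edges,
         root = roots, parents = parents, children = children,
         ancestors = anc, level = lev),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag %s: %d terms, %d edges, root %s, max level %d>\n",
              x$ontology, length(x$terms), nrow(x$edges), x$root,
              max(x$level)))
  invisible(x)
}

#' Inclusive ancestor set of one or more terms
#'
#' @param dag A [go_dag()].
#' @param terms Character vector of term ids.
#' @return Character vector: the union of the terms and all their ancestors.
#' @export
term_ancestors <- function(dag, terms) {
  stopifnot(inherits(dag, "go_dag"))
  missing <- setdiff(terms, dag$terms)
  if (length(missing) > 0L) {
    abort(sprintf("term(s) not in %s ontology: %s", dag$ontology,
                  paste(head(missing, 5), collapse = ", ")))
  }
  unique(unlist(dag$ancestors[terms], use.names = FALSE))
}

#' Inclusive descendant set of a term
#' @inheritParams term_ancestors
#' @param term A single term id.
#' @return Character vector of the term and all its descendants.
#' @export
term_descendants <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"), term %in% dag$terms)
  dag$terms[vapply(dag$ancestors, function(a) term %in% a, logical(1))]
}

#' Hierarchical level of terms (longest path from the root)
#' @inheritParams term_ancestors
#' @return Integer vector named by term.
#' @export
term_level <- function(dag, terms = dag$terms) {
  stopifnot(inherits(dag, "go_dag"))
  dag$level[terms]
}

#' Read a two-column child/parent ontology edge list
#'
#' The fixture dialect: a TSV with two columns, child term then parent term,
#' no header; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param ontology Subontology label for the resulting DAG.
#' @return A [go_dag()].
#' @export
read_edge_list <- function(path, ontology = "BP") {
  tbl <- readr::read_tsv(path, col_names = c("child", "parent"),
                         comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tbl) != 2L || nrow(tbl) == 0L) {
    abort(sprintf("'%s' is not a two-column edge list", path))
  }
  go_dag(tbl, ontology = ontology)
}

#' Write the two-column edge-list dialect
#' @param dag A [go_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(dag, path) {
  readr::write_tsv(dag$edges[, c("child", "parent")], path,
                   col_names = FALSE)
  invisible(path)
}

obo_namespace_map <- c(biological_process = "BP",
                       cellular_component = "CC",
                       molecular_function = "MF")

#' Read an OBO 1.2 ontology file
#'
#' Minimal reader for the term stanzas: `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete`. Obsolete terms are dropped.
#' One rooted DAG is built per namespace present.
#'
#' @param path OBO file path.
#' @param relations Edge relations to traverse (default `is_a` and
#'   `part_of`, the two relations the encoding uses).
#' @return Named list of [go_dag()] objects keyed by subontology
#'   (`BP`/`CC`/`MF`).
#' @export
read_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) abort(sprintf("no [Term] stanzas in '%s'", path))
  bounds <- c(starts, length(lines) + 1L)
  rows <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "",
               grep(paste0("^", key, ": "), block, value = TRUE))
      if (length(v) == 0L) NA_character_ else v[1]
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) next
    ns <- get1("namespace")
    isa <- sub(" !.*$", "",
               sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE)))
    po <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub(" !.*$", "", sub("^relationship: *part_of *", "", po))
    parents <- character(0)
    rel <- character(0)
    if ("is_a" %in% relations && length(isa) > 0L) {
      parents <- c(parents, isa); rel <- c(rel, rep("is_a", length(isa)))
    }
    if ("part_of" %in% relations && length(po) > 0L) {
      parents <- c(parents, po); rel <- c(rel, rep("part_of", length(po)))
    }
    rows[[length(rows) + 1L]] <- tibble(
      child = if (length(parents)) id else character(0),
      parent = parents, relation = rel,
      namespace = if (length(parents)) ns else character(0)
    )
  }
  edges <- bind_rows(rows)
  if (nrow(edges) == 0L) abort("OBO file yields no usable edges")
  edges$ontology <- unname(obo_namespace_map[edges$namespace])
  edges$ontology[is.na(edges$ontology)] <- edges$namespace[is.na(edges$ontology)]
  split(edges, edges$ontology) |>
    lapply(function(e) go_dag(e[, c("child", "parent", "relation")],
                              ontology = e$ontology[1]))
}
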