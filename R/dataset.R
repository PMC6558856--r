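#' Assemble a labeled protein-pair dataset
#'
#' Bundles the four ingredients of a prediction problem: protein sequences,
#' one rooted DAG per subontology, protein-term annotations, and labeled
#' protein pairs. Pairs are unordered at the dataset level: duplicates with
#' agreeing labels collapse with a warning, conflicting labels are an error.
#'
#' @param pairs Data frame: `protein_1`, `protein_2`, `label`
#'   (`"interacting"` / `"non-interacting"`).
#' @param proteins Data frame `protein_id`, `sequence`, or `NULL` when
#'   sequence features are not used.
#' @param ontologies Named list of [go_dag()] objects (a single `go_dag` is
#'   wrapped), or `NULL`.
#' @param annotations Data frame `protein_id`, `ontology`, `term`, or
#'   `NULL`.
#' @return A `ppi_dataset` object (a list with the four components).
#' @export
ppi_dataset <- function(pairs, proteins = NULL, ontologies = NULL,
                        annotations = NULL) {
  stopifnot(all(c("protein_1", "protein_2", "label") %in% names(pairs)))
  pairs <- as_tibble(pairs)
  as_interacting(pairs$label) # validates labels
  if (any(pairs$protein_1 == pairs$protein_2)) {
    abort("self-pairs (protein paired with itself) are not allowed")
  }
  key <- pair_key(pairs$protein_1, pairs$protein_2)
  if (anyDuplicated(key)) {
    agree <- tapply(pairs$label, key, function(l) length(unique(l)) == 1L)
    if (!all(agree)) {
      abort(sprintf("conflicting labels for unordered pair %s",
                    names(agree)[!agree][1]))
    }
    warn(sprintf("collapsed %d duplicate unordered pair(s)",
                 sum(duplicated(key))))
    pairs <- pairs[!duplicated(key), ]
  }
  if (inherits(ontologies, "go_dag")) {
    ontologies <- setNames(list(ontologies), ontologies$ontology)
  }
  if (!is.null(ontologies)) {
    stopifnot(all(vapply(ontologies, inherits, logical(1), "go_dag")))
    names(ontologies) <- vapply(ontologies, function(d) d$ontology,
                                character(1))
  }
  if (!is.null(proteins)) {
    proteins <- as_tibble(proteins)
    stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
    unknown <- setdiff(c(pairs$protein_1, pairs$protein_2),
                       proteins$protein_id)
    if (length(unknown) > 0L) {
      abort(sprintf("%d pair protein(s) missing from the protein table (e.g. %s)",
                    length(unknown), unknown[1]))
    }
  }
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    stopifnot(all(c("protein_id", "term") %in% names(annotations)))
    if (!"ontology" %in% names(annotations) && length(ontologies) == 1L) {
      annotations$ontology <- names(ontologies)
    }
  }
  structure(list(pairs = pairs, proteins = proteins,
                 ontologies = ontologies, annotations = annotations),
            class = "ppi_dataset")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.ppi_dataset <- function(x, ...) {
  n_pos <- sum(as_interacting(x$pairs$label))
  cat(sprintf("<ppi_dataset: %d pairs (%d interacting), %d proteins, %s>\n",
              nrow(x$pairs), n_pos,
              if (is.null(x$proteins)) 0L else nrow(x$proteins),
              if (is.null(x$ontologies)) "no ontologies"
              else paste0("ontologies ",
                          paste(names(x$ontologies), collapse = "/"))))
  invisible(x)
}

# Restrict a dataset to one subontology (cross-species protocol).
restrict_ontology <- function(dataset, ontology) {
  if (is.null(ontology)) return(dataset)
  stopifnot(ontology %in% names(dataset$ontologies))
  dataset$ontologies <- dataset$ontologies[ontology]
  if (!is.null(dataset$annotations)) {
    dataset$annotations <- filter(dataset$annotations,
                                  .data$ontology == !!ontology)
  }
  dataset
}

subset_pairs <- function(dataset, idx) {
  dataset$pairs <- dataset$pairs[idx, ]
  dataset
}
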