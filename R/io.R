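#' Read protein sequences from a FASTA file
#'
#' Identifiers are the header up to the first whitespace, case preserved.
#'
#' @param path FASTA file path.
#' @return Tibble: `protein_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) abort(sprintf("no FASTA records in '%s'", path))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[starts])
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    if (starts[i] + 1L > ends[i]) return("")
    paste(gsub("[[:space:]]", "", lines[(starts[i] + 1L):ends[i]]),
          collapse = "")
  }, character(1))
  if (any(seqs == "")) {
    abort(sprintf("empty FASTA record '%s' (line %d)",
                  ids[seqs == ""][1], starts[seqs == ""][1]))
  }
  tibble(protein_id = ids, sequence = seqs)
}

#' Write a protein table as FASTA
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i]), con)
    s <- proteins$sequence[i]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1L,
                              nchar(s))), con)
  }
  invisible(path)
}

gaf_aspect_map <- c(P = "BP", C = "CC", F = "MF")

#' Read protein-term annotations
#'
#' Accepts GAF 2.x (comment lines starting `!`; DB object id, GO id,
#' aspect and evidence code are used) or a TSV with columns `protein_id`,
#' `term` and optionally `ontology` (headerless two-column files are read
#' as protein/term).
#'
#' @param path File path.
#' @param format `"auto"` sniffs GAF by its `!` comment leader.
#' @param evidence Optional character vector of GAF evidence codes to keep
#'   (default: keep all).
#' @return Tibble: `protein_id`, `ontology` (may be `NA` for two-column
#'   input), `term`.
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gaf"),
                             evidence = NULL) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (format == "auto") {
    format <- if (startsWith(first, "!")) "gaf" else "tsv"
  }
  if (format == "gaf") {
    tbl <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
    if (ncol(tbl) < 9L) abort(sprintf("'%s' is not a GAF file", path))
    out <- tibble(protein_id = trimws(as.character(tbl[[2]])),
                  ontology = unname(gaf_aspect_map[as.character(tbl[[9]])]),
                  term = trimws(as.character(tbl[[5]])),
                  evidence = as.character(tbl[[7]]))
    if (!is.null(evidence)) out <- filter(out, .data$evidence %in% !!evidence)
    return(distinct(select(out, -"evidence")))
  }
  has_header <- grepl("protein", first, ignore.case = TRUE)
  tbl <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  if (!has_header) {
    if (ncol(tbl) == 2L) names(tbl) <- c("protein_id", "term")
    else if (ncol(tbl) == 3L) names(tbl) <- c("protein_id", "ontology", "term")
    else abort(sprintf("'%s': expected 2 or 3 annotation columns", path))
  }
  stopifnot(all(c("protein_id", "term") %in% names(tbl)))
  if (!"ontology" %in% names(tbl)) tbl$ontology <- NA_character_
  distinct(mutate(tbl[, c("protein_id", "ontology", "term")],
                  protein_id = trimws(.data$protein_id),
                  term = trimws(.data$term)))
}

#' Read labeled protein pairs
#'
#' TSV with columns `protein_1`/`protein_id_1`, `protein_2`/`protein_id_2`
#' and `label` (headerless three-column files are accepted). Pairs are
#' unordered: `(A,B)` and `(B,A)` collapse to one pair with a warning;
#' conflicting labels are an error.
#'
#' @param path File path.
#' @return Tibble: `protein_1`, `protein_2`, `label`.
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("protein", first, ignore.case = TRUE)
  tbl <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  if (!has_header) {
    if (ncol(tbl) != 3L) {
      abort(sprintf("'%s': expected 3 pair columns", path))
    }
    names(tbl) <- c("protein_1", "protein_2", "label")
  }
  names(tbl) <- sub("^protein_id_", "protein_", names(tbl))
  stopifnot(all(c("protein_1", "protein_2", "label") %in% names(tbl)))
  tbl <- mutate(tbl, protein_1 = trimws(.data$protein_1),
                protein_2 = trimws(.data$protein_2),
                label = trimws(.data$label))
  as_interacting(tbl$label)
  key <- pair_key(tbl$protein_1, tbl$protein_2)
  if (anyDuplicated(key)) {
    agree <- tapply(tbl$label, key, function(l) length(unique(l)) == 1L)
    if (!all(agree)) {
      abort(sprintf("conflicting labels for unordered pair %s",
                    gsub("\r", "/", names(agree)[!agree][1])))
    }
    warn(sprintf("collapsed %d duplicate unordered pair(s)",
                 sum(duplicated(key))))
    tbl <- tbl[!duplicated(key), ]
  }
  tbl[, c("protein_1", "protein_2", "label")]
}

#' Model manifest: the fitted quantities a run report records
#'
#' @param model A fitted [ppi_stack()].
#' @return Named list: seed, feature blocks, AC gap, theta, tau, selected
#'   meta-SVM hyperparameters, F2 feature counts per ontology, base
#'   learners.
#' @export
model_manifest <- function(model) {
  stopifnot(inherits(model, "ppi_stack"))
  list(
    seed = model$seed,
    features = model$features,
    max_gap = model$max_gap %||% NA_integer_,
    theta = model$theta %||% NA_real_,
    tau = model$tau,
    svm_cost = model$meta$cost,
    svm_gamma = if (is.na(model$meta$gamma)) "default" else model$meta$gamma,
    base_learners = names(model$base_fits),
    n_f2 = if (is.null(model$partitions)) integer(0) else
      vapply(model$partitions, function(p) length(p$lcas), integer(1)),
    n_features = model$n_features,
    n_pairs = model$n_pairs
  )
}

#' Serialize a fitted model (manifest + components) to one archive
#' @param model A fitted [ppi_stack()].
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(list(manifest = model_manifest(model), model = model), path)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#' @param path Archive path.
#' @return The fitted `ppi_stack` model (manifest in attribute
#'   `manifest`).
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$model, "ppi_stack"))
  attr(obj$model, "manifest") <- obj$manifest
  obj$model
}
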