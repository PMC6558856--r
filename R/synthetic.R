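#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the predictor assumes:
#' proteins belong to latent functional modules; interacting pairs tend to
#' fall within a module, so they share a GO subgraph (elevated semantic
#' similarity and shared LCA clusters) and a sequence motif, while
#' non-interacting pairs tend to span modules. `go_signal` controls how
#' strongly pair labels follow module structure (0 = labels independent of
#' every feature, the null case), `motif_rate` how often a protein carries
#' its module's motif.
#'
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param n_proteins Number of proteins.
#' @param ontologies Subontology labels to generate.
#' @param n_terms Terms per subontology DAG.
#' @param max_parents Maximum parents per term (DAG branching).
#' @param n_modules Number of latent functional modules.
#' @param annotations_per_protein Module-drawn annotations per protein per
#'   ontology.
#' @param noise_terms Additional uniformly random annotations per protein
#'   per ontology (annotation noise; 0 keeps annotations module-confined).
#' @param seq_len_range Min/max sequence length.
#' @param motif_length Length of the module motifs.
#' @param motif_rate Probability a protein carries its module motif.
#' @param n_pairs Number of labeled pairs.
#' @param pos_frac Fraction of interacting pairs (balance holds within one
#'   pair).
#' @param go_signal Probability a pair's protein choice follows module
#'   structure.
#' @param noise_rate Probability a pair's label is flipped after
#'   generation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_proteins = 60,
                             ontologies = c("BP", "CC", "MF"),
                             n_terms = 40, max_parents = 2, n_modules = 4,
                             annotations_per_protein = 3, noise_terms = 0,
                             seq_len_range = c(50, 120), motif_length = 10,
                             motif_rate = 0.9, n_pairs = 100,
                             pos_frac = 0.5, go_signal = 0.9,
                             noise_rate = 0) {
  probs <- c(motif_rate, pos_frac, go_signal, noise_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_terms >= 2 * n_modules + 1,
            n_proteins >= 2 * n_modules, n_pairs >= 2,
            annotations_per_protein + noise_terms <= n_terms,
            seq_len_range[1] >= motif_length + 2)
  structure(as.list(environment())[c(
    "seed", "n_proteins", "ontologies", "n_terms", "max_parents",
    "n_modules", "annotations_per_protein", "noise_terms",
    "seq_len_range", "motif_length", "motif_rate", "n_pairs",
    "pos_frac", "go_signal", "noise_rate")],
    class = "synthetic_config")
}

# Branch-structured random DAG: below the root, one subgraph per latent
# module; within a branch every new term attaches to 1..max_parents earlier
# branch terms. Module subgraphs are therefore disjoint by construction,
# which is what gives within-module annotations a deep shared ancestor.
random_dag <- function(ontology, n_terms, max_parents, n_modules) {
  ids <- sprintf("%s:%03d", ontology, seq_len(n_terms))
  stopifnot(n_terms >= 2 * n_modules + 1)
  root <- ids[1]
  anchors <- ids[1 + seq_len(n_modules)]
  child <- anchors
  parent <- rep(root, n_modules)
  branch <- lapply(seq_len(n_modules), function(m) anchors[m])
  rest <- ids[-(1:(n_modules + 1L))]
  owner <- rep_len(seq_len(n_modules), length(rest))
  for (i in seq_along(rest)) {
    b <- branch[[owner[i]]]
    k <- sample.int(min(max_parents, length(b)), 1L)
    ps <- if (length(b) == 1L) b else sample(b, k)
    child <- c(child, rep(rest[i], length(ps)))
    parent <- c(parent, ps)
    branch[[owner[i]]] <- c(b, rest[i])
  }
  dag <- go_dag(tibble(child = child, parent = parent), ontology = ontology)
  attr(dag, "anchors") <- anchors
  dag
}

random_sequence <- function(len, aa) {
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

insert_motif <- function(seq, motif) {
  pos <- sample.int(nchar(seq) - nchar(motif) + 1L, 1L)
  paste0(substr(seq, 1, pos - 1L), motif,
         substr(seq, pos + nchar(motif), nchar(seq)))
}

#' Generate a synthetic labeled PPI dataset
#'
#' Deterministic under the config seed: same config, bit-identical output.
#' With `go_signal` high, interacting pairs share module subgraphs (and
#' motifs), so they have elevated Resnik similarity and shared-cluster
#' annotations by construction; with `go_signal = 0` labels are independent
#' of all features.
#'
#' @param config A [synthetic_config()].
#' @return A [ppi_dataset()] carrying the config as attribute `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  aa <- physchem_scales()$aa
  n <- config$n_proteins
  prot_ids <- sprintf("PROT%03d", seq_len(n))
  module <- sample(rep_len(seq_len(config$n_modules), n))

  # one DAG per subontology; each module's term pool is the disjoint
  # subgraph rooted at its branch anchor
  dags <- lapply(config$ontologies, random_dag,
                 n_terms = config$n_terms, max_parents = config$max_parents,
                 n_modules = config$n_modules)
  names(dags) <- config$ontologies
  pools <- lapply(dags, function(dag) {
    lapply(attr(dag, "anchors"), function(a) term_descendants(dag, a))
  })

  ann <- list()
  for (ont in config$ontologies) {
    dag <- dags[[ont]]
    for (i in seq_len(n)) {
      pool <- pools[[ont]][[module[i]]]
      terms <- sample(pool, min(config$annotations_per_protein,
                                length(pool)))
      if (config$noise_terms > 0) {
        terms <- unique(c(terms, sample(dag$terms, config$noise_terms)))
      }
      ann[[length(ann) + 1L]] <- tibble(protein_id = prot_ids[i],
                                        ontology = ont, term = terms)
    }
  }
  annotations <- bind_rows(ann)

  motifs <- vapply(seq_len(config$n_modules), function(m) {
    random_sequence(config$motif_length, aa)
  }, character(1))
  sequences <- vapply(seq_len(n), function(i) {
    len <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]), 1L)
    s <- random_sequence(len, aa)
    if (runif(1) < config$motif_rate) s <- insert_motif(s, motifs[module[i]])
    s
  }, character(1))
  proteins <- tibble(protein_id = prot_ids, sequence = sequences)

  n_pos <- round(config$n_pairs * config$pos_frac)
  n_neg <- config$n_pairs - n_pos
  draw_pair <- function(positive) {
    if (runif(1) < config$go_signal) {
      if (positive) {
        m <- sample.int(config$n_modules, 1L)
        sample(prot_ids[module == m], 2L)
      } else {
        ms <- sample.int(config$n_modules, 2L)
        c(sample(prot_ids[module == ms[1]], 1L),
          sample(prot_ids[module == ms[2]], 1L))
      }
    } else sample(prot_ids, 2L)
  }
  seen <- character(0)
  rows <- vector("list", config$n_pairs)
  lab <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  for (i in seq_len(config$n_pairs)) {
    for (try in 1:1000) {
      p <- draw_pair(lab[i])
      k <- pair_key(p[1], p[2])
      if (!k %in% seen) break
    }
    seen <- c(seen, k)
    rows[[i]] <- tibble(protein_1 = p[1], protein_2 = p[2])
  }
  flip <- runif(config$n_pairs) < config$noise_rate
  pairs <- bind_rows(rows) |>
    mutate(label = ifelse(xor(lab, flip), "interacting", "non-interacting"))

  ds <- ppi_dataset(pairs, proteins = proteins, ontologies = dags,
                    annotations = annotations)
  attr(ds, "config") <- config
  ds
}

#' Write a dataset to its standard on-disk formats
#'
#' FASTA sequences, one two-column edge list per subontology, a TSV
#' annotation table and a TSV pair table.
#'
#' @param dataset A [ppi_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(dataset$proteins)) {
    write_fasta(dataset$proteins, file.path(dir, "proteins.fasta"))
  }
  for (ont in names(dataset$ontologies)) {
    write_edge_list(dataset$ontologies[[ont]],
                    file.path(dir, paste0("ontology_", ont, ".tsv")))
  }
  if (!is.null(dataset$annotations)) {
    readr::write_tsv(dataset$annotations, file.path(dir, "annotations.tsv"))
  }
  readr::write_tsv(dataset$pairs, file.path(dir, "pairs.tsv"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory containing the standard files.
#' @return A [ppi_dataset()].
#' @export
read_dataset <- function(dir) {
  fasta <- file.path(dir, "proteins.fasta")
  proteins <- if (file.exists(fasta)) read_fasta(fasta) else NULL
  onts <- list.files(dir, pattern = "^ontology_.*\\.tsv$")
  dags <- lapply(onts, function(f) {
    read_edge_list(file.path(dir, f),
                   ontology = sub("^ontology_(.*)\\.tsv$", "\\1", f))
  })
  names(dags) <- vapply(dags, function(d) d$ontology, character(1))
  ann_path <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) {
    read_annotations(ann_path)
  } else NULL
  pairs <- read_pairs(file.path(dir, "pairs.tsv"))
  ppi_dataset(pairs, proteins = proteins,
              ontologies = if (length(dags)) dags else NULL,
              annotations = annotations)
}
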