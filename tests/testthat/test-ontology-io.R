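test_that("DAG construction validates rootedness and acyclicity", {
  dag <- go_dag(tibble::tibble(child = c("b", "c", "d"),
                               parent = c("a", "a", "b")))
  expect_equal(dag$root, "a")
  expect_equal(unname(term_level(dag, c("a", "b", "d"))), c(0, 1, 2))
  expect_setequal(term_ancestors(dag, "d"), c("d", "b", "a"))
  expect_setequal(term_descendants(dag, "b"), c("b", "d"))
  # level is the longest root path on multi-parent terms
  dia <- go_dag(tibble::tibble(child = c("b", "c", "d", "d"),
                               parent = c("a", "b", "a", "c")))
  expect_equal(unname(term_level(dia, "d")), 3)
  expect_error(go_dag(tibble::tibble(child = c("b", "a"),
                                     parent = c("a", "b"))), "cycle")
  expect_error(go_dag(tibble::tibble(child = "b", parent = "b")),
               "self-loop")
  expect_error(go_dag(tibble::tibble(child = c("b", "d"),
                                     parent = c("a", "c"))),
               "exactly one root")
})

test_that("edge-list files round-trip and cycles are rejected at read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ont.tsv")
  dag <- go_dag(tibble::tibble(child = c("b", "c"), parent = c("a", "a")),
                ontology = "MF")
  write_edge_list(dag, path)
  back <- read_edge_list(path, ontology = "MF")
  expect_equal(back$terms, dag$terms)
  expect_equal(back$root, "a")
  writeLines(c("x\ty", "y\tx"), path)
  expect_error(read_edge_list(path), "cycle")
})

test_that("the OBO reader handles is_a, part_of and obsolete terms", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0002", "name: mid",
    "namespace: biological_process", "is_a: GO:0001 ! root", "",
    "[Term]", "id: GO:0003", "name: leaf",
    "namespace: biological_process",
    "relationship: part_of GO:0002 ! mid", "",
    "[Term]", "id: GO:0004", "name: gone",
    "namespace: biological_process", "is_obsolete: true",
    "is_a: GO:0001", "",
    "[Typedef]", "id: part_of")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mini.obo")
  writeLines(obo, path)
  dags <- read_obo(path)
  expect_named(dags, "BP")
  expect_setequal(dags$BP$terms, c("GO:0001", "GO:0002", "GO:0003"))
  expect_equal(dags$BP$root, "GO:0001")
  expect_setequal(term_ancestors(dags$BP, "GO:0003"),
                  c("GO:0003", "GO:0002", "GO:0001"))
  # is_a-only traversal drops the part_of leaf
  isa_only <- read_obo(path, relations = "is_a")
  expect_false("GO:0003" %in% isa_only$BP$terms)
})

test_that("FASTA files round-trip with ids cut at whitespace", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "p.fasta")
  prots <- tibble::tibble(protein_id = c("P1", "P2"),
                          sequence = c(strrep("ACDEF", 20), "WYVK"))
  write_fasta(prots, path)
  back <- read_fasta(path)
  expect_equal(back, prots)
  writeLines(c(">A desc here", "MKV", "LLT", ">B", "GG"), path)
  two <- read_fasta(path)
  expect_equal(two$protein_id, c("A", "B"))
  expect_equal(two$sequence, c("MKVLLT", "GG"))
  writeLines(c(">A", "", ">B", "GG"), path)
  expect_error(read_fasta(path), "empty FASTA record")
})

test_that("annotation readers accept TSV and GAF dialects", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "ann.tsv")
  writeLines(c("P1\tGO:1", "P1\tGO:2", "P2\tGO:1"), tsv)
  a <- read_annotations(tsv)
  expect_equal(nrow(a), 3)
  expect_true(all(is.na(a$ontology)))
  gaf <- file.path(dir, "ann.gaf")
  row <- function(p, go, aspect, ev = "IDA") {
    paste(c("DB", p, p, "", go, "REF", ev, "", aspect,
            rep("", 8)), collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.1",
               row("P1", "GO:1", "P"), row("P1", "GO:2", "C", "IEA"),
               row("P2", "GO:3", "F")), gaf)
  g <- read_annotations(gaf)
  expect_equal(sort(g$ontology), c("BP", "CC", "MF"))
  filtered <- read_annotations(gaf, evidence = "IDA")
  expect_equal(nrow(filtered), 2)
})

test_that("pair files collapse unordered duplicates and catch conflicts", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pairs.tsv")
  writeLines(c("protein_id_1\tprotein_id_2\tlabel",
               "A\tB\tinteracting",
               "B\tA\tinteracting",
               "C\tD\tnon-interacting"), path)
  expect_warning(p <- read_pairs(path), "duplicate")
  expect_equal(nrow(p), 2)
  writeLines(c("A\tB\tinteracting", "B\tA\tnon-interacting"), path)
  expect_error(read_pairs(path), "conflicting")
  writeLines(c("A\tB\tmaybe"), path)
  expect_error(read_pairs(path), "label")
})

test_that("dataset assembly validates pairs against the protein table", {
  pairs <- tibble::tibble(protein_1 = "A", protein_2 = "B",
                          label = "interacting")
  expect_error(
    ppi_dataset(pairs, proteins = tibble::tibble(protein_id = "A",
                                                 sequence = "MK")),
    "missing from the protein table")
  expect_error(
    ppi_dataset(tibble::tibble(protein_1 = "A", protein_2 = "A",
                               label = "interacting")),
    "self-pairs")
})

test_that("model archives round-trip through save and load", {
  ds <- generate_dataset(synthetic_config(seed = 2, n_proteins = 30,
                                          n_pairs = 30, ontologies = "BP"))
  m <- suppressMessages(suppressWarnings(
    ppi_stack(ds, features = "F2", control = fast_control(), seed = 1)))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.rds")
  save_model(m, path)
  back <- load_model(path)
  pr1 <- predict(m, ds$pairs[1:5, ], annotations = ds$annotations)
  pr2 <- predict(back, ds$pairs[1:5, ], annotations = ds$annotations)
  expect_identical(pr1, pr2)
  expect_equal(attr(back, "manifest")$tau, m$tau)
})
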