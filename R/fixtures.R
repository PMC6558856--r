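# Worked-example fixtures: a 45-term toy subontology whose partition into
# four LCA-rooted clusters, and the two encoded demonstration pairs, are
# known exactly. The DAG is listed edge by edge so every expectation about
# it can be audited against the cluster memberships and ascending-path
# traversals it must reproduce.

toy_dag_edges <- function() {
  e <- c(
    "G2", "G1", "G3", "G1", "G4", "G1",
    # cluster rooted at G1 (with G2/G3 side branches)
    "G5", "G3", "G6", "G3", "G9", "G2", "G10", "G2",
    "G13", "G9", "G14", "G9", "G19", "G13",
    # children of G4: two leaves, the G11 subgraph, the G12 chain
    "G7", "G4", "G8", "G4", "G11", "G4", "G12", "G4",
    "G18", "G12", "G24", "G18", "G25", "G18",
    "G32", "G24", "G40", "G32", "G41", "G32",
    # subgraph rooted at G11 (11 terms)
    "G16", "G11", "G17", "G11", "G22", "G16", "G23", "G17",
    "G29", "G22", "G30", "G22", "G31", "G23",
    "G37", "G29", "G38", "G29", "G39", "G31",
    # subgraph rooted at G15 (14 terms), hanging off G10
    "G15", "G10", "G20", "G15", "G21", "G15",
    "G26", "G20", "G27", "G20", "G28", "G21",
    "G33", "G26", "G34", "G26", "G35", "G27", "G36", "G28",
    "G42", "G33", "G43", "G33", "G44", "G35", "G45", "G36"
  )
  m <- matrix(e, ncol = 2, byrow = TRUE)
  tibble(child = m[, 1], parent = m[, 2])
}

#' Toy DAG-partitioning fixture
#'
#' A 45-term rooted DAG with five training pairs whose LCAs are G15, G11
#' (shared by two pairs), G4 and G1. Partitioning by those LCAs (deepest
#' first) splits the DAG into four mutually exclusive clusters of sizes
#' 14, 11, 10 and 10 that together cover all 45 terms.
#'
#' @return List with `dag` (a [go_dag()], ontology `"BP"`), `pairs`,
#'   `annotations`, and `expected_clusters` (named list of term sets in
#'   partition order G15, G11, G4, G1).
#' @export
toy_dag_fixture <- function() {
  dag <- go_dag(toy_dag_edges(), ontology = "BP")
  pairs <- tibble(
    protein_1 = c("P1", "P3", "P5", "P7", "P9"),
    protein_2 = c("P2", "P4", "P6", "P8", "P10")
  )
  annotations <- tibble(
    protein_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
                   "P9", "P10"),
    ontology = "BP",
    term = c("G16", "G17", "G7", "G8", "G22", "G23", "G20", "G21",
             "G2", "G3")
  )
  expected <- list(
    G15 = c("G15", "G20", "G21", "G26", "G27", "G28", "G33", "G34",
            "G35", "G36", "G42", "G43", "G44", "G45"),
    G11 = c("G11", "G16", "G17", "G22", "G23", "G29", "G30", "G31",
            "G37", "G38", "G39"),
    G4 = c("G4", "G7", "G8", "G12", "G18", "G24", "G25", "G32",
           "G40", "G41"),
    G1 = c("G1", "G2", "G3", "G5", "G6", "G9", "G10", "G13", "G14",
           "G19")
  )
  list(dag = dag, pairs = pairs, annotations = annotations,
       expected_clusters = expected)
}

#' Encoded demonstration pairs for the toy partition
#'
#' Two annotated pairs whose LCA-indexed feature vectors over the
#' [toy_dag_fixture()] partition are known: `<P11,P12>` encodes to
#' `(2, 0, 3, 4)` and `<P13,P14>` to `(0, 3, 3, 0)`, components ordered by
#' the sorted LCA list (G15, G11, G4, G1).
#'
#' @return List with `pairs`, `annotations` and `expected` (matrix of the
#'   two feature vectors).
#' @export
toy_encoded_pairs <- function() {
  pairs <- tibble(protein_1 = c("P11", "P13"),
                  protein_2 = c("P12", "P14"))
  annotations <- tibble(
    protein_id = c("P11", "P11", "P11", "P12", "P12", "P13", "P13", "P14"),
    ontology = "BP",
    term = c("G5", "G7", "G20", "G6", "G8", "G16", "G18", "G17")
  )
  expected <- rbind(c(2, 0, 3, 4), c(0, 3, 3, 0))
  rownames(expected) <- c("P11~P12", "P13~P14")
  colnames(expected) <- c("G15", "G11", "G4", "G1")
  list(pairs = pairs, annotations = annotations, expected = expected)
}
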