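make_ic_fixture <- function() {
  # linear chain r -> a -> b plus sibling c under r; 10 annotated proteins
  dag <- go_dag(tibble::tibble(child = c("a", "b", "c"),
                               parent = c("r", "a", "r")), ontology = "BP")
  ann <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:10),
    ontology = "BP",
    term = c("b", rep("c", 5), rep("a", 2), rep("r", 2))
  )
  list(dag = dag, ann = ann)
}

test_that("information content propagates counts to ancestors", {
  fx <- make_ic_fixture()
  ic <- ic_table(fx$dag, fx$ann)
  icv <- setNames(ic$ic, ic$term)
  expect_equal(unname(icv["r"]), 0) # root covers everyone
  expect_equal(unname(icv["b"]), -log(0.1)) # 1 of 10 proteins
  expect_equal(unname(icv["a"]), -log(0.3)) # b's protein + 2 direct
  expect_equal(unname(icv["c"]), -log(0.5))
  # monotone non-decreasing root -> leaf
  expect_true(icv["r"] <= icv["a"] && icv["a"] <= icv["b"])
})

test_that("IC matches a brute-force ancestor closure on random corpora", {
  set.seed(5)
  for (rep in 1:8) {
    td <- random_test_dag(sample(10:30, 1))
    ann <- tibble::tibble(
      protein_id = rep(sprintf("p%d", 1:12), each = 2),
      ontology = "BP",
      term = sample(td$ids, 24, replace = TRUE)
    )
    ic <- ic_table(td$dag, ann)
    for (t in sample(td$ids, 5)) {
      covered <- sum(vapply(split(ann$term, ann$protein_id), function(ts) {
        any(t %in% unlist(lapply(ts, oracle_ancestors, edges = td$edges)))
      }, logical(1)))
      got <- ic$count[ic$term == t]
      expect_equal(if (length(got) == 0) 0L else got, covered)
    }
  }
})

test_that("Resnik similarity is the IC of the best common ancestor", {
  fx <- make_ic_fixture()
  ic <- ic_table(fx$dag, fx$ann)
  expect_equal(resnik_term_sim(ic, fx$dag, "b", "b"), -log(0.1))
  # only common ancestor is the root -> 0
  expect_equal(resnik_term_sim(ic, fx$dag, "b", "c"), 0)
  expect_equal(resnik_protein_sim(ic, fx$dag, "b", "b"), -log(0.1))
  expect_equal(resnik_protein_sim(ic, fx$dag, character(0), "b"), 0)
  # cross-product equivalence on random sets
  set.seed(23)
  for (rep in 1:15) {
    td <- random_test_dag(sample(10:25, 1))
    ann <- tibble::tibble(protein_id = rep(sprintf("p%d", 1:8), each = 2),
                          ontology = "BP",
                          term = sample(td$ids, 16, replace = TRUE))
    ic <- ic_table(td$dag, ann)
    gi <- sample(td$ids, sample(1:4, 1))
    gj <- sample(td$ids, sample(1:4, 1))
    expect_equal(resnik_protein_sim(ic, td$dag, gi, gj),
                 oracle_resnik_protein(td$edges, ic, gi, gj),
                 tolerance = 1e-12)
  }
})

sim_tbl <- function(p, s) {
  idx <- which(upper.tri(matrix(0, length(p), length(p))), arr.ind = TRUE)
  tibble::tibble(protein_1 = p[idx[, 1]], protein_2 = p[idx[, 2]],
                 similarity = s)
}

test_that("threshold selection matches average degrees", {
  prots <- c("A", "B", "C", "D")
  sims <- sim_tbl(prots, c(0.9, 0.8, 0.2, 0.1, 0.1, 0.05))
  # reference with two interacting pairs: average degree 1.0
  ns <- build_reference_network(
    tibble::tibble(protein_1 = c("A", "C"), protein_2 = c("B", "D"),
                   label = "interacting"), nodes = prots)
  expect_equal(average_degree(ns), 1.0)
  th <- select_threshold(sims, ns)
  np <- build_ppi_network(sims, th, prots)
  expect_equal(igraph::ecount(np$graph), 2) # the two strongest edges
  expect_equal(average_degree(np), 1.0)
  # empty reference -> empty thresholded network
  ns0 <- build_reference_network(
    tibble::tibble(protein_1 = "A", protein_2 = "B",
                   label = "non-interacting"), nodes = prots)
  th0 <- select_threshold(sims, ns0)
  expect_gt(th0, max(sims$similarity))
  expect_equal(igraph::ecount(build_ppi_network(sims, th0, prots)$graph), 0)
  # reference as dense as the complete similarity graph -> keep every edge
  full <- tidyr::crossing(i = prots, j = prots) |>
    dplyr::filter(i < j) |>
    dplyr::transmute(protein_1 = i, protein_2 = j, label = "interacting")
  thf <- select_threshold(sims, build_reference_network(full, nodes = prots))
  expect_equal(thf, min(sims$similarity))
  # all-equal similarities are degenerate but handled
  expect_warning(select_threshold(sim_tbl(prots, rep(0.4, 6)), ns),
                 "degenerate")
})

test_that("thresholding is monotone: larger theta, sparser network", {
  set.seed(9)
  prots <- sprintf("p%d", 1:8)
  sims <- sim_tbl(prots, runif(28))
  ths <- sort(sample(sims$similarity, 5))
  nets <- lapply(ths, function(t) build_ppi_network(sims, t, prots))
  for (i in 2:5) {
    e_hi <- igraph::as_edgelist(nets[[i]]$graph)
    e_lo <- igraph::as_edgelist(nets[[i - 1]]$graph)
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(key(e_hi) %in% key(e_lo)))
    expect_lte(average_degree(nets[[i]]), average_degree(nets[[i - 1]]))
  }
})

edge_net <- function(a, b, nodes) {
  build_reference_network(tibble::tibble(protein_1 = a, protein_2 = b,
                                         label = "interacting"),
                          nodes = nodes)
}

test_that("topology features follow the five neighbour-set formulas", {
  # i-a, i-b, j-a, j-b, a-x
  net <- edge_net(c("i", "i", "j", "j", "a"), c("a", "b", "a", "b", "x"),
                  nodes = c("i", "j", "a", "b", "x"))
  f <- topology_features(tibble::tibble(protein_1 = "i", protein_2 = "j"),
                         net)
  expect_equal(f$f3_cn, 2)
  expect_equal(f$f3_jaccard, 1.0)
  expect_equal(f$f3_aa, 1 / log(3) + 1 / log(2))
  expect_equal(f$f3_pa, 4)
  expect_equal(f$f3_oo, 1.0)
  # disjoint neighbourhoods
  net2 <- edge_net(c("i", "j"), c("a", "b"), nodes = c("i", "j", "a", "b"))
  f2 <- suppressWarnings(
    topology_features(tibble::tibble(protein_1 = "i", protein_2 = "j"),
                      net2))
  expect_equal(unname(unlist(f2[, -(1:2)])), c(0, 0, 0, 1, 0))
  # unknown proteins are isolated: all zeros
  f3 <- topology_features(tibble::tibble(protein_1 = "zz", protein_2 = "yy"),
                          net)
  expect_equal(unname(unlist(f3[, -(1:2)])), c(0, 0, 0, 0, 0))
})

test_that("topology features are symmetric and match the oracle", {
  set.seed(31)
  for (rep in 1:10) {
    nodes <- sprintf("n%d", 1:10)
    m <- matrix(sample(nodes, 24, replace = TRUE), ncol = 2)
    m <- m[m[, 1] != m[, 2], , drop = FALSE]
    edge_tbl <- tibble::tibble(a = pmin(m[, 1], m[, 2]),
                               b = pmax(m[, 1], m[, 2])) |> dplyr::distinct()
    net <- edge_net(edge_tbl$a, edge_tbl$b, nodes)
    pq <- sample(nodes, 2)
    f_ij <- suppressWarnings(topology_features(
      tibble::tibble(protein_1 = pq[1], protein_2 = pq[2]), net))
    f_ji <- suppressWarnings(topology_features(
      tibble::tibble(protein_1 = pq[2], protein_2 = pq[1]), net))
    expect_equal(f_ij[, -(1:2)], f_ji[, -(1:2)], ignore_attr = TRUE)
    exp <- oracle_topology(edge_tbl, pq[1], pq[2])
    expect_equal(unname(unlist(f_ij[, -(1:2)])), unname(exp),
                 tolerance = 1e-12)
    # Jaccard <= Otsuka-Ochiai <= 1
    expect_lte(f_ij$f3_jaccard, f_ij$f3_oo + 1e-12)
    expect_lte(f_ij$f3_oo, 1)
  }
})
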