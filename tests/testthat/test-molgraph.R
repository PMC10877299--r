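test_that("SMILES parsing yields the hydrogen-suppressed simple graph", {
  g <- graph_from_smiles(acet_smiles, name = "acetaminophen")
  expect_s3_class(g, "mol_graph")
  expect_equal(igraph::vcount(g$graph), 11)
  expect_equal(igraph::ecount(g$graph), 11)

  # single heavy atom: no edges
  g1 <- graph_from_smiles("C")
  expect_equal(igraph::vcount(g1$graph), 1)
  expect_equal(igraph::ecount(g1$graph), 0)

  # triangle: bond-order collapse keeps it simple
  g3 <- graph_from_smiles("C1CC1")
  expect_equal(igraph::vcount(g3$graph), 3)
  expect_equal(igraph::ecount(g3$graph), 3)
  expect_true(all(degree_sequence(g3) == 2))

  # double bonds contribute one edge each
  g2 <- graph_from_smiles("C=C")
  expect_equal(igraph::ecount(g2$graph), 1)
})

test_that("SMILES failures are informative", {
  expect_error(graph_from_smiles("xyz123"), "failed to parse SMILES 'xyz123'")
  expect_error(graph_from_smiles("CC.O"), "disconnected|strip")
  expect_error(graph_from_smiles(""), "empty")
})

test_that("edge-list parsing validates structure line by line", {
  g <- graph_from_edgelist(lines = c("1 2", "2 3"))
  expect_equal(igraph::vcount(g$graph), 3)
  expect_equal(sort(unname(degree_sequence(g))), c(1, 1, 2))

  expect_error(graph_from_edgelist(lines = c("1 2", "1 2")),
               "line 2: duplicate edge")
  expect_error(graph_from_edgelist(lines = c("2 1", "1 2")),
               "line 2: duplicate edge")
  expect_error(graph_from_edgelist(lines = c("1 1")), "self-loop")
  expect_error(graph_from_edgelist(lines = c("1 2", "3 4")), "disconnected")
  expect_error(graph_from_edgelist(lines = c("1 2 3")), "expected 'u v'")

  named <- graph_from_edgelist(lines = c("name my molecule", "a b"))
  expect_equal(named$name, "my molecule")
})

test_that("the acetaminophen edge-list fixture matches the SMILES graph", {
  path <- system.file("extdata", "edgelists", "acetaminophen.el",
                      package = "topoqspr")
  g_el <- graph_from_edgelist(path)
  expect_equal(g_el$name, "Acetaminophen")
  expect_equal(igraph::vcount(g_el$graph), 11)
  expect_equal(igraph::ecount(g_el$graph), 11)
  g_smi <- graph_from_smiles(acet_smiles)
  expect_equal(
    as.data.frame(edge_partition(g_el)),
    as.data.frame(edge_partition(g_smi))
  )
})

test_that("degree sequences satisfy the handshake lemma", {
  expect_equal(unname(degree_sequence(graph_from_smiles("C1CC1"))), rep(2, 3))
  star <- graph_from_edgelist(lines = c("c 1", "c 2", "c 3", "c 4"))
  expect_equal(sort(unname(degree_sequence(star))), c(1, 1, 1, 1, 4))

  acet <- degree_sequence(graph_from_smiles(acet_smiles))
  expect_equal(as.integer(table(acet)), c(3L, 5L, 3L))  # degrees 1, 2, 3
  expect_equal(sum(acet), 2 * 11)

  for (s in 1:25) {
    g <- generate_graph(sample(5:40, 1), seed = s)
    expect_equal(sum(degree_sequence(g)), 2 * igraph::ecount(g$graph))
  }
})

test_that("edge partitions count every edge exactly once", {
  p <- edge_partition(graph_from_smiles(acet_smiles))
  expect_equal(
    as.data.frame(p),
    data.frame(lo = c(1, 2, 2), hi = c(3, 2, 3), count = c(3L, 2L, 6L)),
    ignore_attr = TRUE
  )
  expect_equal(n_edges(p), 11)

  p6 <- edge_partition(graph_from_smiles("C1CCCCC1"))
  expect_equal(as.data.frame(p6), data.frame(lo = 2, hi = 2, count = 6L),
               ignore_attr = TRUE)

  star <- graph_from_edgelist(lines = paste("c", 1:4))
  expect_equal(as.data.frame(edge_partition(star)),
               data.frame(lo = 1, hi = 4, count = 4L), ignore_attr = TRUE)

  for (s in 1:25) {
    g <- generate_graph(sample(5:40, 1), seed = s + 100)
    p <- edge_partition(g)
    expect_equal(sum(p$count), igraph::ecount(g$graph))
    expect_true(all(p$lo >= 1 & p$lo <= p$hi & p$hi <= 4))
  }
})

test_that("as_edge_partition rejects malformed partitions", {
  expect_error(as_edge_partition(data.frame(lo = 2, hi = 1, count = 1)),
               "lo <= hi")
  expect_error(as_edge_partition(data.frame(lo = 0, hi = 1, count = 1)),
               "lo <= hi")
  expect_error(as_edge_partition(data.frame(lo = 1, hi = 2, count = -1)),
               "non-negative")
  expect_error(as_edge_partition(data.frame(lo = 1, hi = 2, count = 1.5)),
               "integer")
})

test_that("chemical validation warns on hypervalent and trivial graphs", {
  expect_length(validate_chemistry(graph_from_smiles(acet_smiles)), 0)
  k5_lines <- apply(utils::combn(5, 2), 2, paste, collapse = " ")
  expect_length(validate_chemistry(graph_from_edgelist(lines = k5_lines)), 0)
  star5 <- graph_from_edgelist(lines = paste("c", 1:5))
  expect_match(validate_chemistry(star5), "degree 5", all = FALSE)
  expect_match(validate_chemistry(graph_from_smiles("C")), "single vertex")
})

test_that("edge-list round trip preserves the partition of every fixture drug", {
  drugs <- hep_drugs()
  tmp <- withr::local_tempfile(fileext = ".el")
  for (i in seq_len(nrow(drugs))) {
    write_edgelist(drugs$graph[[i]], tmp)
    back <- graph_from_edgelist(tmp)
    expect_equal(back$name, drugs$drug[[i]])
    expect_equal(
      as.data.frame(edge_partition(back)),
      as.data.frame(edge_partition(drugs$graph[[i]]))
    )
  }
})
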