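# Expected values below are frozen from independent hand computation of
# count * f(lo, hi) sums (and closed forms for regular graphs), not from
# the implementation.

test_that("each index reproduces hand-computed sums on known partitions", {
  acet <- acet_partition()
  cases <- list(
    # index, partition, expected, tolerance
    list("Z1", acet, 50, 0),
    list("Z2", acet, 9 + 36 + 8, 0),
    list("Z3", acet, 3 * 2 + 6 * 1 + 0, 0),
    list("ReZG3", acet, 36 + 180 + 32, 0),
    list("RZ2", acet, 0 + 2 + 12, 0),
    list("HZ", acet, 3 * 16 + 2 * 16 + 6 * 25, 0),
    list("ABC", acet, 3 * sqrt(2 / 3) + 8 * sqrt(1 / 2), 1e-12),
    list("RI", acet, 3 / sqrt(3) + 6 / sqrt(6) + 1, 1e-12),
    list("F", acet, 3 * 10 + 2 * 8 + 6 * 13, 0),
    list("GA", acet, 3 * sqrt(3) / 2 + 12 * sqrt(6) / 5 + 2, 1e-12),
    list("SCI", acet, 3 / 2 + 6 / sqrt(5) + 1, 1e-12),
    list("IS", acet, 2.25 + 7.2 + 2, 1e-12),
    list("SDD", acet, 10 + 13 + 4, 1e-12),
    # six-cycle: all degrees 2
    list("Z1", data.frame(lo = 2, hi = 2, count = 6), 24, 0),
    list("Z2", data.frame(lo = 2, hi = 2, count = 6), 24, 0),
    list("ReZG3", data.frame(lo = 2, hi = 2, count = 6), 96, 0),
    list("HZ", data.frame(lo = 2, hi = 2, count = 1), 16, 0),
    list("ABC", data.frame(lo = 2, hi = 2, count = 1), sqrt(1 / 2), 1e-12),
    list("F", data.frame(lo = 2, hi = 2, count = 1), 8, 0),
    list("IS", data.frame(lo = 2, hi = 2, count = 1), 1, 0),
    list("SCI", data.frame(lo = 2, hi = 2, count = 4), 2, 1e-12),
    # star K1,4
    list("Z3", data.frame(lo = 1, hi = 4, count = 4), 12, 0),
    list("RZ2", data.frame(lo = 1, hi = 4, count = 4), 0, 0),
    list("RZ2", data.frame(lo = 2, hi = 3, count = 6), 12, 0)
  )
  for (case in cases) {
    expect_equal(
      topo_index(case[[2]], case[[1]]), case[[3]],
      tolerance = if (case[[4]] == 0) NULL else case[[4]],
      info = case[[1]]
    )
  }
})

test_that("the harmonic index honors both conventions, differing exactly 2x", {
  acet <- acet_partition()
  expect_equal(topo_index(acet, "H"), 2 * (3 / 4 + 2 / 4 + 6 / 5))
  expect_equal(topo_index(acet, "H", "paper_table"), 3 / 4 + 2 / 4 + 6 / 5)
  for (s in 1:20) {
    p <- random_partition(s)
    expect_identical(topo_index(p, "H", "standard"),
                     2 * topo_index(p, "H", "paper_table"))
  }
})

test_that("regular graphs satisfy the closed forms", {
  c6 <- edge_partition(graph_from_smiles("C1CCCCC1"))  # 2-regular, m = 6
  k5 <- edge_partition(graph_from_edgelist(
    lines = apply(utils::combn(5, 2), 2, paste, collapse = " ")
  ))  # 4-regular, m = 10
  for (case in list(list(c6, 2, 6), list(k5, 4, 10))) {
    p <- case[[1]]; d <- case[[2]]; m <- case[[3]]
    expect_equal(topo_index(p, "Z3"), 0)
    expect_equal(topo_index(p, "GA"), m)
    expect_equal(topo_index(p, "RI"), m / d)
    expect_equal(topo_index(p, "H"), m / d)
    expect_equal(topo_index(p, "SCI"), m / sqrt(2 * d))
    expect_equal(topo_index(p, "SDD"), 2 * m)
  }
})

test_that("edge-grouped sums equal the per-edge and per-vertex oracles", {
  for (s in 1:30) {
    g <- generate_graph(sample(5:45, 1), seed = s + 300)
    p <- edge_partition(g)
    deg <- degree_sequence(g)
    # vertex forms of the first Zagreb and forgotten indices
    expect_equal(topo_index(p, "Z1"), sum(deg^2))
    expect_equal(topo_index(p, "F"), sum(deg^3))
    # per-edge oracle for the non-polynomial indices
    expect_equal(topo_index(p, "ABC"),
                 oracle_edge_sum(g, function(a, b) sqrt((a + b - 2) / (a * b))))
    expect_equal(topo_index(p, "GA"),
                 oracle_edge_sum(g, function(a, b) 2 * sqrt(a * b) / (a + b)))
    expect_equal(topo_index(p, "RI"),
                 oracle_edge_sum(g, function(a, b) 1 / sqrt(a * b)))
  }
})

test_that("the hyper-Zagreb identity HZ = F + 2 Z2 is exact", {
  for (s in 1:40) {
    p <- random_partition(s + 50)
    expect_identical(topo_index(p, "HZ"),
                     topo_index(p, "F") + 2 * topo_index(p, "Z2"))
  }
})

test_that("adding an occupied degree class increases every index but Z3", {
  p <- acet_partition()
  grown <- as_edge_partition(
    rbind(as.data.frame(p), data.frame(lo = 3, hi = 4, count = 2))
  )
  for (ix in setdiff(index_names(), "Z3")) {
    expect_gt(topo_index(grown, ix), topo_index(p, ix))
  }
  expect_gte(topo_index(grown, "Z3"), topo_index(p, "Z3"))
})

test_that("compute_indices returns the full named row, zeros when edgeless", {
  row <- compute_indices(graph_from_smiles(acet_smiles, "acetaminophen"))
  expect_named(row, c("molecule", index_names()))
  expect_equal(row$molecule, "acetaminophen")

  empty <- compute_indices(graph_from_smiles("C"))
  expect_true(all(empty[index_names()] == 0))
})

test_that("index_table stacks molecules and format_index_table rounds", {
  graphs <- list(a = graph_from_smiles("C1CC1"), b = graph_from_smiles("CCO"))
  tbl <- index_table(graphs)
  expect_equal(tbl$molecule, c("a", "b"))
  rounded <- format_index_table(tbl)
  expect_equal(rounded$ABC, round(tbl$ABC, 2))
  expect_identical(rounded$Z1, tbl$Z1)  # integer-valued columns untouched
})
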