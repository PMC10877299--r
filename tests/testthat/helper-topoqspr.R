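# Shared fixtures and independent oracles for the test suite.

# acetaminophen's degree-pair edge partition, enumerated by hand from the
# heavy-atom skeleton (3 pendant atoms on degree-3 carbons, 2 CH-CH ring
# bonds, 6 bonds between degree-2 and degree-3 atoms)
acet_partition <- function() {
  as_edge_partition(data.frame(
    lo = c(1, 2, 2), hi = c(3, 2, 3), count = c(3, 2, 6)
  ))
}

acet_smiles <- "CC(=O)Nc1ccc(O)cc1"

# the published acetaminophen index row
acet_paper <- c(
  Z1 = 50, Z2 = 53, Z3 = 12, ReZG3 = 248, RZ2 = 14, HZ = 230, ABC = 8.10,
  RI = 5.18, H = 2.45, F = 124, GA = 10.47, SCI = 5.18, IS = 11.45, SDD = 27
)

# independent per-edge oracle: walks the raw edge list of the graph and
# sums f(du, dv) edge by edge, bypassing the partition-grouping code path
oracle_edge_sum <- function(g, f) {
  deg <- degree_sequence(g)
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  if (nrow(el) == 0) return(0)
  sum(mapply(function(u, v) f(deg[[u]], deg[[v]]), el[, 1], el[, 2]))
}

# independent Pearson r from raw sums (textbook computational formula)
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# independent OLS slope/intercept from raw moments
oracle_ols <- function(x, y) {
  b <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

random_partition <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(1:6, 1)
    lo <- sample(1:4, k, replace = TRUE)
    hi <- pmin(lo + sample(0:3, k, replace = TRUE), 4)
    as_edge_partition(
      dplyr::distinct(
        data.frame(lo = pmin(lo, hi), hi = pmax(lo, hi)), lo, hi,
        .keep_all = TRUE
      ) |> dplyr::mutate(count = sample(1:20, dplyr::n(), replace = TRUE))
    )
  })
}
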