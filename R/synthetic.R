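# Seeded generators for chemical-like graphs and linear-plus-noise
# property tables, so that every pipeline stage is testable with known
# ground truth and no external data.
#
# Randomness: base R's default Mersenne-Twister generator, seeded
# explicitly through every entry point via withr::with_seed, so identical
# seeds give byte-identical outputs across runs and platforms.

#' Generate a random connected chemical-like graph
#'
#' Grows a random tree vertex by vertex (each new vertex attaches to a
#' uniformly chosen existing vertex with spare degree budget), then makes
#' `n_vertices` ring-closure attempts: each picks two random vertices and
#' joins them with probability `ring_probability` when they are distinct,
#' non-adjacent and both below `max_degree`.  This guarantees
#' connectivity by construction and mimics the acyclic-plus-rings shape
#' of drug skeletons; `max_degree = 4` matches the carbon-valence bound
#' of hydrogen-suppressed drug graphs.
#'
#' @param n_vertices Number of vertices (>= 2).
#' @param max_degree Degree cap (default 4).
#' @param ring_probability Acceptance probability of each ring-closure
#'   attempt, in `[0, 1)` (default 0.2, giving roughly 0.1-0.15 rings per
#'   vertex, comparable to the study drugs).
#' @param seed Integer seed; required, so every graph is reproducible.
#' @param name Molecule label (default derived from the seed).
#' @return A `mol_graph`.
#' @examples
#' g <- generate_graph(30, seed = 7)
#' max(degree_sequence(g))  # <= 4
#' @export
generate_graph <- function(n_vertices, max_degree = 4L, ring_probability = 0.2,
                           seed, name = NULL) {
  stopifnot(n_vertices >= 2L, max_degree >= 1L,
            ring_probability >= 0, ring_probability < 1)
  if (n_vertices > 2L && max_degree < 2L) {
    abort("max_degree = 1 admits no connected graph beyond a single edge")
  }
  name <- name %||% sprintf("synthetic-%d", seed)
  withr::with_seed(seed, {
    deg <- integer(n_vertices)
    from <- integer(0)
    to <- integer(0)
    for (v in seq(2L, n_vertices)) {
      eligible <- which(deg[seq_len(v - 1L)] < max_degree)
      if (length(eligible) == 0L) {
        abort("degree budget exhausted while growing the tree")
      }
      u <- eligible[[sample.int(length(eligible), 1L)]]
      from <- c(from, u)
      to <- c(to, v)
      deg[u] <- deg[u] + 1L
      deg[v] <- deg[v] + 1L
    }
    adj <- paste(pmin(from, to), pmax(from, to))
    for (i in seq_len(n_vertices)) {
      uv <- sample.int(n_vertices, 2L)
      u <- min(uv)
      v <- max(uv)
      key <- paste(u, v)
      if (deg[u] < max_degree && deg[v] < max_degree &&
          !(key %in% adj) && runif(1) < ring_probability) {
        from <- c(from, u)
        to <- c(to, v)
        adj <- c(adj, key)
        deg[u] <- deg[u] + 1L
        deg[v] <- deg[v] + 1L
      }
    }
    gr <- igraph::graph_from_edgelist(
      cbind(as.character(from), as.character(to)), directed = FALSE
    )
    validate_mol_graph(new_mol_graph(gr, name))
  })
}

#' Generate a batch of random graphs
#'
#' @param n_graphs Number of graphs.
#' @param n_vertices Either a single size or a `c(min, max)` range from
#'   which each graph's size is drawn uniformly.  The default range 11-65
#'   spans the heavy-atom counts of the study drugs.
#' @param seed Integer master seed; per-graph seeds are derived from it.
#' @inheritParams generate_graph
#' @return A tibble with columns `name` and list-column `graph`.
#' @export
generate_graphs <- function(n_graphs, n_vertices = c(11L, 65L),
                            max_degree = 4L, ring_probability = 0.2, seed) {
  stopifnot(n_graphs >= 1L)
  sizes <- withr::with_seed(seed, {
    if (length(n_vertices) == 2L) {
      sample(seq(n_vertices[[1]], n_vertices[[2]]), n_graphs, replace = TRUE)
    } else {
      rep_len(n_vertices, n_graphs)
    }
  })
  # keep derived seeds well inside 32-bit integer range
  seeds <- (as.double(seed) * 1009 + 7919 * seq_len(n_graphs)) %% .Machine$integer.max
  tibble(
    name = sprintf("synthetic-%03d", seq_len(n_graphs)),
    graph = purrr::map2(
      sizes, seeds,
      ~ generate_graph(.x, max_degree, ring_probability, seed = as.integer(.y))
    )
  )
}

#' Generate a synthetic property with known linear ground truth
#'
#' Emulates the study's model in reverse: the property is
#' `intercept + slope * TI + N(0, noise_sd^2)`, computed from the
#' recomputed index of each graph, with cells knocked out at rate
#' `missing_fraction` to exercise listwise deletion.
#'
#' @param graphs A list of `mol_graph`s or a tibble with a `graph`
#'   list-column (as from [generate_graphs()]).
#' @param index Which index drives the property (default `"Z1"`).
#' @param intercept,slope,noise_sd Ground-truth model parameters.
#' @param missing_fraction Probability a cell is dropped, in `[0, 1)`.
#' @param seed Integer seed for noise and missingness.
#' @param harmonic Harmonic convention used when `index = "H"`.
#' @return A tibble with columns `drug`, `ti`, `value` (`NA` when
#'   missing); attribute `truth` records the generating parameters.  In
#'   long `property_table`-compatible form the `property` column is the
#'   index name prefixed with `"syn_"`.
#' @export
generate_property_table <- function(graphs, index = "Z1", intercept = 0,
                                    slope = 1, noise_sd = 0,
                                    missing_fraction = 0, seed,
                                    harmonic = "standard") {
  stopifnot(noise_sd >= 0, missing_fraction >= 0, missing_fraction < 1)
  index <- match.arg(index, index_names())
  if (is.data.frame(graphs)) {
    nms <- graphs[[intersect(c("drug", "name"), names(graphs))[1]]]
    graphs <- setNames(graphs$graph, nms)
  }
  if (is.null(names(graphs))) {
    names(graphs) <- purrr::map_chr(graphs, "name")
  }
  ti <- purrr::map_dbl(graphs, ~ topo_index(.x, index, harmonic))
  out <- withr::with_seed(seed, {
    value <- intercept + slope * ti + rnorm(length(ti), sd = noise_sd)
    drop <- runif(length(ti)) < missing_fraction
    value[drop] <- NA_real_
    tibble(
      drug = names(graphs), property = paste0("syn_", index),
      ti = unname(ti), value = value
    )
  })
  if (sum(!is.na(out$value)) < 3L) {
    abort("fewer than 3 rows survive missingness; lower missing_fraction")
  }
  structure(out,
    truth = list(index = index, intercept = intercept, slope = slope,
                 noise_sd = noise_sd, missing_fraction = missing_fraction),
    class = c("synthetic_property", class(out))
  )
}
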