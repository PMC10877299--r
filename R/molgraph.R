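# Hydrogen-suppressed molecular graphs and their degree-pair edge partitions.
#
# A `mol_graph` is a thin S3 wrapper around an igraph object: an undirected,
# simple, connected graph whose vertices are heavy atoms and whose edges are
# bonds collapsed to single edges (bond order, aromaticity, charge and
# stereochemistry are deliberately discarded -- every index computed here
# depends only on the degree sequence over edges).

new_mol_graph <- function(graph, name = "molecule") {
  stopifnot(igraph::is_igraph(graph))
  structure(list(graph = graph, name = name), class = "mol_graph")
}

validate_mol_graph <- function(g, context = g$name) {
  gr <- g$graph
  if (any(igraph::which_loop(gr))) {
    abort(sprintf("molecular graph '%s' contains a self-loop", context))
  }
  if (any(igraph::which_multiple(gr))) {
    abort(sprintf("molecular graph '%s' contains a duplicate edge", context))
  }
  if (igraph::vcount(gr) > 0 && igraph::count_components(gr) > 1) {
    abort(sprintf(
      "molecular graph '%s' is disconnected (%d components)",
      context, igraph::count_components(gr)
    ))
  }
  # graphs are immutable once validated, so the degree-pair partition is
  # computed here once and served from cache ever after
  g$partition <- compute_partition(gr)
  g
}

compute_partition <- function(gr) {
  deg <- igraph::degree(gr)
  el <- igraph::as_edgelist(gr, names = FALSE)
  if (nrow(el) == 0L) {
    return(as_edge_partition(tibble(
      lo = integer(0), hi = integer(0), count = integer(0)
    )))
  }
  d1 <- deg[el[, 1]]
  d2 <- deg[el[, 2]]
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  key <- paste(lo, hi)
  counts <- table(key)
  first <- !duplicated(key)
  ord <- order(lo[first], hi[first])
  as_edge_partition(tibble(
    lo = as.integer(lo[first][ord]),
    hi = as.integer(hi[first][ord]),
    count = as.integer(counts[key[first][ord]])
  ))
}

#' Build a molecular graph from a SMILES string
#'
#' Parses a SMILES string into its hydrogen-suppressed molecular graph:
#' hydrogens are excluded, and double, triple and aromatic bonds each
#' contribute exactly one edge, so the result is a simple connected graph
#' over the heavy atoms.  Element symbols are retained as the vertex
#' attribute `element` (metadata only; no index uses them).
#'
#' @param smiles A single SMILES string.
#' @param name Label for the molecule (defaults to the SMILES itself).
#' @return A `mol_graph` object.
#' @examples
#' g <- graph_from_smiles("CC(=O)Nc1ccc(O)cc1", name = "acetaminophen")
#' g
#' edge_partition(g)
#' @export
graph_from_smiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) abort("empty SMILES string")
  if (grepl("^\\[?[A-Za-z][a-z]?([H][0-9]?)?([+-][0-9]?)?\\]?$", smiles)) {
    # single heavy atom (e.g. "C", "[Na+]"): no bond block to parse
    element <- sub("^\\[?([A-Za-z][a-z]?).*$", "\\1", smiles)
    gr <- igraph::make_empty_graph(1, directed = FALSE)
    igraph::V(gr)$name <- "1"
    igraph::V(gr)$element <- element
    return(validate_mol_graph(new_mol_graph(gr, name)))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      abort(sprintf(
        "failed to parse SMILES '%s' (%s)", smiles, conditionMessage(e)
      ))
    }
  )
  atoms <- ChemmineR::atomblock(sdf[[1]])
  bonds <- ChemmineR::bondblock(sdf[[1]])
  labels <- rownames(atoms)
  elements <- sub("_.*$", "", labels)
  keep <- elements != "H"
  idx <- which(keep)
  if (length(idx) == 0L) abort(sprintf("SMILES '%s' has no heavy atoms", smiles))
  remap <- match(seq_along(labels), idx)
  el <- matrix(0L, nrow = 0L, ncol = 2L)
  if (nrow(bonds) > 0L) {
    u <- remap[as.integer(bonds[, 1])]
    v <- remap[as.integer(bonds[, 2])]
    ok <- !is.na(u) & !is.na(v)
    el <- cbind(u[ok], v[ok])
  }
  gr <- igraph::graph_from_edgelist(
    matrix(as.character(el), ncol = 2L), directed = FALSE
  )
  gr <- igraph::add_vertices(
    gr, length(idx) - igraph::vcount(gr)
  )
  # vertices created from the edge list are named by atom position; ensure
  # isolated heavy atoms (possible only in disconnected inputs) are counted
  gr <- igraph::simplify(gr, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(gr)$element <- elements[idx][
    match(igraph::V(gr)$name, as.character(seq_along(idx)))
  ]
  if (igraph::count_components(gr) > 1) {
    abort(sprintf(
      paste0(
        "SMILES '%s' yields a disconnected graph (%d components); ",
        "strip salt/solvent components (the '.' separator) and retry"
      ),
      smiles, igraph::count_components(gr)
    ))
  }
  validate_mol_graph(new_mol_graph(gr, name))
}

#' Read molecules from a SMILES (.smi) file
#'
#' One molecule per line: a SMILES string optionally followed by a
#' tab-separated name.  Blank lines and `#` comments are skipped.
#'
#' @param path Path to a `.smi` file.
#' @return A tibble with columns `name`, `smiles` and a list-column `graph`
#'   of [graph_from_smiles()] results.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort(sprintf("no molecules in '%s'", path))
  parts <- stringr::str_split_fixed(lines, "\t", 2L)
  smiles <- trimws(parts[, 1])
  nm <- trimws(parts[, 2])
  nm[!nzchar(nm)] <- smiles[!nzchar(nm)]
  tibble(
    name = nm,
    smiles = smiles,
    graph = purrr::map2(smiles, nm, graph_from_smiles)
  )
}

#' Build a molecular graph from an edge-list text file
#'
#' The format is one `"u v"` pair per line with opaque vertex labels,
#' an optional `name <label>` header line, and `#` comments.  Duplicate
#' edge lines and self-loops are errors (not silently repaired), so that
#' transcription mistakes in hand-written fixtures surface immediately.
#'
#' @param path Path to an edge-list file, or `NULL` when `lines` is given.
#' @param lines Character vector of lines (alternative to `path`).
#' @param name Fallback molecule label when the file has no `name` header.
#' @return A `mol_graph` object.
#' @examples
#' g <- graph_from_edgelist(lines = c("name triangle", "1 2", "2 3", "3 1"))
#' degree_sequence(g)
#' @export
graph_from_edgelist <- function(path = NULL, lines = NULL, name = NULL) {
  if (is.null(lines)) {
    if (is.null(path)) abort("supply either `path` or `lines`")
    lines <- readLines(path, encoding = "UTF-8")
    name <- name %||% basename(path)
  }
  name <- name %||% "molecule"
  raw <- sub("#.*$", "", lines)
  raw <- trimws(raw)
  edges <- character(0)
  seen <- character(0)
  from <- character(0)
  to <- character(0)
  for (i in seq_along(raw)) {
    line <- raw[[i]]
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (tok[[1]] == "name") {
      name <- paste(tok[-1], collapse = " ")
      next
    }
    if (length(tok) != 2L) {
      abort(sprintf("line %d: expected 'u v', got '%s'", i, line))
    }
    if (tok[[1]] == tok[[2]]) {
      abort(sprintf("line %d: self-loop on vertex '%s'", i, tok[[1]]))
    }
    key <- paste(sort(tok), collapse = "\r")
    if (key %in% seen) {
      abort(sprintf("line %d: duplicate edge '%s %s'", i, tok[[1]], tok[[2]]))
    }
    seen <- c(seen, key)
    from <- c(from, tok[[1]])
    to <- c(to, tok[[2]])
  }
  if (length(from) == 0L) abort("edge list contains no edges")
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::count_components(gr) > 1) {
    abort(sprintf(
      "edge list '%s' describes a disconnected graph (%d components)",
      name, igraph::count_components(gr)
    ))
  }
  validate_mol_graph(new_mol_graph(gr, name))
}

#' Write a molecular graph as an edge-list text file
#'
#' Inverse of [graph_from_edgelist()]; round-trips exactly.
#'
#' @param g A `mol_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "mol_graph"))
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  writeLines(
    c(paste("name", g$name), paste(el[, 1], el[, 2])),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' Degree sequence of a molecular graph
#'
#' @param g A `mol_graph`.
#' @return Named integer vector of vertex degrees; its sum is twice the
#'   number of edges.
#' @export
degree_sequence <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  igraph::degree(g$graph)
}

#' Degree-pair edge partition of a molecular graph
#'
#' Groups the edges of a graph by the unordered pair of endpoint degrees
#' `(lo, hi)` with `lo <= hi`.  This partition is the sole input to every
#' degree-based topological index.
#'
#' @param g A `mol_graph`.
#' @return A tibble of class `edge_partition` with columns `lo`, `hi`
#'   and `count`, one row per occupied degree class, sorted by `(lo, hi)`;
#'   the attribute `n_edges` carries the edge total.
#' @examples
#' edge_partition(graph_from_smiles("C1CC1"))  # one class: (2,2) x 3
#' @export
edge_partition <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  g$partition %||% compute_partition(g$graph)
}

#' Coerce a data frame of degree-class counts to an edge partition
#'
#' @param x A data frame with columns `lo`, `hi`, `count`; `lo <= hi`
#'   and counts must be non-negative integers.
#' @return A validated `edge_partition` tibble.
#' @examples
#' # acetaminophen's partition, entered by hand
#' as_edge_partition(data.frame(
#'   lo = c(1, 2, 2), hi = c(3, 2, 3), count = c(3, 2, 6)
#' ))
#' @export
as_edge_partition <- function(x) {
  stopifnot(is.data.frame(x), all(c("lo", "hi", "count") %in% names(x)))
  x <- as_tibble(x)[c("lo", "hi", "count")]
  if (any(x$lo < 1) || any(x$hi < x$lo)) {
    abort("degree pairs must satisfy 1 <= lo <= hi")
  }
  if (any(x$count < 0) || any(x$count != round(x$count))) {
    abort("degree-class counts must be non-negative integers")
  }
  x <- dplyr::arrange(x, .data$lo, .data$hi)
  structure(x,
    n_edges = sum(x$count),
    class = c("edge_partition", class(x))
  )
}

#' Number of edges recorded in an edge partition
#'
#' @param p An `edge_partition`.
#' @return Integer edge count.
#' @export
n_edges <- function(p) {
  stopifnot(inherits(p, "edge_partition"))
  attr(p, "n_edges")
}

#' Chemical-plausibility warnings for a molecular graph
#'
#' Drug-like hydrogen-suppressed graphs have maximum degree four (carbon
#' valence); a vertex of higher degree usually indicates a transcription
#' error.  Returns warnings as a character vector rather than failing,
#' since hypervalent atoms (S, P) are legitimately possible.
#'
#' @param g A `mol_graph`.
#' @param max_degree Degree above which a vertex is flagged (default 4).
#' @return Character vector of warnings (length zero when none).
#' @export
validate_chemistry <- function(g, max_degree = 4L) {
  stopifnot(inherits(g, "mol_graph"))
  deg <- degree_sequence(g)
  out <- character(0)
  high <- deg[deg > max_degree]
  if (length(high) > 0) {
    out <- c(out, sprintf(
      "vertex '%s' has degree %d (> %d)",
      names(high), high, max_degree
    ))
  }
  if (length(deg) == 1L) {
    out <- c(out, "graph has a single vertex (no edges, all indices zero)")
  }
  out
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph> %s: %d vertices, %d edges, max degree %s\n",
    x$name, igraph::vcount(x$graph), igraph::ecount(x$graph),
    if (igraph::vcount(x$graph)) max(igraph::degree(x$graph)) else 0
  ))
  invisible(x)
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("<edge_partition> %d edges in %d degree classes\n",
              attr(x, "n_edges"), nrow(x)))
  NextMethod()
}
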