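# Degree-based topological indices, all computed from a degree-pair edge
# partition by one shared summation engine: index(G) = sum over degree
# classes of count * f(lo, hi).  Adding an index is a one-line registration
# in `.index_funs`.

.index_funs <- list(
  Z1    = function(lo, hi) lo + hi,
  Z2    = function(lo, hi) lo * hi,
  Z3    = function(lo, hi) abs(hi - lo),
  ReZG3 = function(lo, hi) (lo * hi) * (lo + hi),
  RZ2   = function(lo, hi) (lo - 1) * (hi - 1),
  HZ    = function(lo, hi) (lo + hi)^2,
  ABC   = function(lo, hi) sqrt((lo + hi - 2) / (lo * hi)),
  RI    = function(lo, hi) 1 / sqrt(lo * hi),
  H     = function(lo, hi) 2 / (lo + hi),
  F     = function(lo, hi) lo^2 + hi^2,
  GA    = function(lo, hi) 2 * sqrt(lo * hi) / (lo + hi),
  SCI   = function(lo, hi) 1 / sqrt(lo + hi),
  IS    = function(lo, hi) lo * hi / (lo + hi),
  SDD   = function(lo, hi) lo / hi + hi / lo
)

# indices whose values are generally irrational (reported to 2 dp); the
# remainder are integer-valued on integer degree partitions except IS/SDD,
# which are rational
.irrational_indices <- c("ABC", "RI", "H", "GA", "SCI", "IS", "SDD")

#' Names of the supported topological indices
#'
#' The closed set of fourteen degree-based indices, in the conventional
#' reporting order: first/second/third Zagreb (`Z1`, `Z2`, `Z3`), redefined
#' third Zagreb (`ReZG3`), reduced second Zagreb (`RZ2`), hyper-Zagreb
#' (`HZ`), atom-bond connectivity (`ABC`), Randic (`RI`), harmonic (`H`),
#' forgotten (`F`), geometric-arithmetic (`GA`), sum-connectivity (`SCI`),
#' inverse-sum (`IS`) and symmetric division degree (`SDD`).
#'
#' @return Character vector of length 14.
#' @export
index_names <- function() names(.index_funs)

as_partition <- function(x) {
  if (inherits(x, "edge_partition")) return(x)
  if (inherits(x, "mol_graph")) return(edge_partition(x))
  if (is.data.frame(x)) return(as_edge_partition(x))
  abort("expected a mol_graph, edge_partition, or lo/hi/count data frame")
}

#' Compute one degree-based topological index
#'
#' Evaluates `sum(count * f(lo, hi))` over the degree classes of an edge
#' partition.  An empty partition (edgeless graph) yields 0 for every
#' index, keeping the computation total.
#'
#' The harmonic index is the one case with two live conventions: the
#' defining formula sums `2/(dx+dy)` (`harmonic = "standard"`), but the
#' published anti-hepatitis index tables tabulate the halved variant
#' `1/(dx+dy)` (`harmonic = "paper_table"`).  Both are exposed; the
#' standard form is the default, and the two differ by an exact factor
#' of 2 for every graph.
#'
#' @param x A `mol_graph`, `edge_partition`, or data frame with columns
#'   `lo`, `hi`, `count`.
#' @param index One of [index_names()].
#' @param harmonic Harmonic-index convention, `"standard"` or
#'   `"paper_table"`; ignored for the other thirteen indices.
#' @return A single non-negative number.
#' @examples
#' acet <- as_edge_partition(data.frame(
#'   lo = c(1, 2, 2), hi = c(3, 2, 3), count = c(3, 2, 6)
#' ))
#' topo_index(acet, "Z1")             # 50
#' topo_index(acet, "H")              # 4.90...
#' topo_index(acet, "H", "paper_table")  # 2.45...
#' @export
topo_index <- function(x, index, harmonic = c("standard", "paper_table")) {
  index <- match.arg(index, index_names())
  harmonic <- match.arg(harmonic)
  p <- as_partition(x)
  if (nrow(p) == 0L) return(0)
  f <- .index_funs[[index]]
  val <- sum(p$count * f(p$lo, p$hi))
  if (index == "H" && harmonic == "paper_table") val <- val / 2
  val
}

#' Compute all fourteen topological indices of one molecule
#'
#' @inheritParams topo_index
#' @param name Molecule label; taken from the `mol_graph` when omitted.
#' @return A one-row tibble: `molecule`, then one numeric column per index
#'   in [index_names()] order.
#' @examples
#' compute_indices(graph_from_smiles("CC(=O)Nc1ccc(O)cc1", "acetaminophen"),
#'                 harmonic = "paper_table")
#' @export
compute_indices <- function(x, harmonic = c("standard", "paper_table"),
                            name = NULL) {
  harmonic <- match.arg(harmonic)
  if (is.null(name)) {
    name <- if (inherits(x, "mol_graph")) x$name else "molecule"
  }
  p <- as_partition(x)
  vals <- purrr::map_dbl(index_names(), ~ topo_index(p, .x, harmonic))
  dplyr::bind_cols(
    tibble(molecule = name),
    as_tibble(as.list(setNames(vals, index_names())))
  )
}

#' Compute the index table for a set of molecules
#'
#' @param graphs A list of `mol_graph` objects, or a data frame holding a
#'   `graph` list-column (as returned by [read_smiles_file()] or
#'   [hep_drugs()]) and a name column (`name` or `drug`).
#' @inheritParams topo_index
#' @return A tibble with one row per molecule and the 14 index columns.
#' @export
index_table <- function(graphs, harmonic = c("standard", "paper_table")) {
  harmonic <- match.arg(harmonic)
  if (is.data.frame(graphs)) {
    nm_col <- intersect(c("drug", "name", "molecule"), names(graphs))[1]
    if (is.na(nm_col) || !"graph" %in% names(graphs)) {
      abort("data frame input needs a `graph` list-column and a name column")
    }
    gl <- setNames(graphs$graph, graphs[[nm_col]])
  } else {
    gl <- graphs
    if (is.null(names(gl))) {
      names(gl) <- purrr::map_chr(gl, ~ .x$name %||% "molecule")
    }
  }
  purrr::imap(gl, ~ compute_indices(.x, harmonic = harmonic, name = .y)) |>
    purrr::list_rbind()
}

#' Round an index table for reporting
#'
#' Irrational-valued indices (`ABC`, `RI`, `H`, `GA`, `SCI`, `IS`, `SDD`)
#' are rounded to `digits` decimals with R's round-half-even rule; the
#' integer-valued ones are left exact.  Internal computation always keeps
#' full precision -- use this only at the output boundary.
#'
#' @param tbl An index table from [index_table()].
#' @param digits Decimal places for irrational-valued indices (default 2,
#'   matching the published tables).
#' @return The rounded tibble.
#' @export
format_index_table <- function(tbl, digits = 2) {
  dplyr::mutate(tbl, dplyr::across(
    dplyr::any_of(.irrational_indices), ~ round(.x, digits)
  ))
}
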