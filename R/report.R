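# Report-level drivers: the index-table, QSPR-table and reproduce-study
# workflows used by the command-line wrapper (inst/cli/topoqspr.R) and by
# scripts.  Each driver returns its results invisibly and optionally
# writes a CSV/JSON bundle.

#' Compute the index table for a SMILES file
#'
#' @param input Path to a `.smi` file (SMILES, optional tab-separated
#'   name, `#` comments).
#' @param output Optional CSV path for the table.
#' @param harmonic Harmonic convention (the published drug tables use
#'   `"paper_table"`).
#' @param digits Reporting precision for irrational-valued indices;
#'   `NULL` writes full precision.
#' @return The index tibble, invisibly.  Molecules that fail to parse
#'   are skipped with a warning; the call errors only if all fail.
#' @export
cmd_indices <- function(input, output = NULL, harmonic = "paper_table",
                        digits = 2) {
  lines <- readLines(input, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort(sprintf("no molecules in '%s'", input))
  parts <- stringr::str_split_fixed(lines, "\t", 2L)
  nm <- trimws(parts[, 2])
  nm[!nzchar(nm)] <- trimws(parts[!nzchar(nm), 1])
  graphs <- purrr::map2(trimws(parts[, 1]), nm, function(s, n) {
    tryCatch(graph_from_smiles(s, n), error = function(e) {
      warn(sprintf("skipping '%s': %s", n, conditionMessage(e)))
      NULL
    })
  })
  keep <- !purrr::map_lgl(graphs, is.null)
  if (!any(keep)) abort("no molecule in the input could be parsed")
  tbl <- index_table(setNames(graphs[keep], nm[keep]), harmonic = harmonic)
  if (!is.null(digits)) tbl <- format_index_table(tbl, digits)
  if (!is.null(output)) readr::write_csv(tbl, output)
  invisible(tbl)
}

#' Fit the full QSPR table set
#'
#' Runs [qspr_fit_all()] and derives the per-index parameter tables, the
#' correlation comparison matrix and the best-descriptor report.
#'
#' @param indices An index table (tibble, or CSV path with a `drug` or
#'   `molecule` column plus index columns).
#' @param properties A long property table, or a CSV path in the
#'   wide "value±uncertainty" cell format of [hep_properties()].
#' @param out_dir Optional output directory: writes `table_<index>.csv`
#'   per index, `comparison_matrix.csv`, and `best_indices.json`.
#' @return Invisibly, a list with `fits` (`qspr_results`), `comparison`,
#'   and `best`.
#' @export
cmd_qspr <- function(indices, properties, out_dir = NULL) {
  if (is.character(indices)) {
    indices <- readr::read_csv(indices, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(properties)) properties <- hep_properties(properties)
  fits <- qspr_fit_all(properties, indices)
  comparison <- comparison_matrix(fits)
  best <- best_index_report(fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_parameter_tables(fits, out_dir)
    readr::write_csv(comparison, file.path(out_dir, "comparison_matrix.csv"))
    jsonlite::write_json(
      best, file.path(out_dir, "best_indices.json"),
      dataframe = "rows", digits = NA
    )
  }
  invisible(list(fits = fits, comparison = comparison, best = best))
}

#' Write per-index regression parameter tables
#'
#' One CSV per index in the shape of the published parameter tables:
#' `property`, `N`, `x` (intercept), `y` (slope), `r`, `r2`, `p`.
#'
#' @param results A `qspr_results` object.
#' @param out_dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_parameter_tables <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(unique(results$index), function(ix) {
    tbl <- as_tibble(results) |>
      dplyr::filter(.data$index == ix) |>
      dplyr::transmute(
        property = .data$property, N = .data$n,
        x = round(.data$intercept, 4), y = round(.data$slope, 4),
        r = round(.data$r, 4), r2 = round(.data$r2, 4),
        p = round(.data$p_value, 4)
      )
    path <- file.path(out_dir, sprintf("table_%s.csv", ix))
    readr::write_csv(tbl, path)
    path
  })
  invisible(paths)
}

#' Reproduce the full anti-hepatitis study workflow
#'
#' End to end from the packaged fixtures: recomputes the drug index
#' table, audits it against the published rows (including the
#' hyper-Zagreb identity check on the printed values), fits all
#' property-on-index regressions, and builds the comparison matrix and
#' best-descriptor report.
#'
#' @param out_dir Optional output directory for the CSV/JSON bundle.
#' @param harmonic Harmonic convention (default `"paper_table"`, the one
#'   the published tables use).
#' @param index_source `"paper_printed"` fits the regressions on the
#'   published index values (isolating regression verification from any
#'   structure-transcription differences; the default), `"recomputed"`
#'   uses the indices recomputed from the structure fixtures.
#' @param plots If `TRUE` and `out_dir` is given, also writes scatter
#'   plots for every fit with `r2 >= 0.8`.
#' @return Invisibly, a list: `indices_recomputed`, `indices_paper`,
#'   `audit`, `identity_audit`, `fits`, `comparison`, `best`,
#'   `manifest`.
#' @export
cmd_reproduce_paper <- function(out_dir = NULL, harmonic = "paper_table",
                                index_source = c("paper_printed", "recomputed"),
                                plots = FALSE) {
  index_source <- match.arg(index_source)
  drugs <- hep_drugs()
  properties <- hep_properties()
  recomputed <- index_table(drugs, harmonic = harmonic) |>
    dplyr::rename(drug = "molecule")
  paper <- hep_paper_indices()
  idx <- if (index_source == "paper_printed") paper else recomputed
  fits <- qspr_fit_all(properties, idx)
  comparison <- comparison_matrix(fits)
  best <- best_index_report(fits)
  audit <- audit_recomputed(drugs, harmonic = harmonic)
  identity_audit <- audit_identity(paper)
  manifest <- list(
    package = "topoqspr",
    version = as.character(utils::packageVersion("topoqspr")),
    harmonic = harmonic, index_source = index_source,
    n_drugs = nrow(drugs),
    properties = attr(properties, "properties")
  )
  out <- list(
    indices_recomputed = recomputed, indices_paper = paper,
    audit = audit, identity_audit = identity_audit,
    fits = fits, comparison = comparison, best = best, manifest = manifest
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(format_index_table(recomputed),
                     file.path(out_dir, "indices_recomputed.csv"))
    readr::write_csv(paper, file.path(out_dir, "indices_published.csv"))
    readr::write_csv(audit, file.path(out_dir, "audit_recomputed.csv"))
    readr::write_csv(identity_audit, file.path(out_dir, "audit_identity.csv"))
    write_parameter_tables(fits, out_dir)
    readr::write_csv(comparison, file.path(out_dir, "comparison_matrix.csv"))
    jsonlite::write_json(best, file.path(out_dir, "best_indices.json"),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    if (plots) {
      good <- as_tibble(fits) |>
        dplyr::filter(.data$available, .data$r2 >= 0.8)
      for (i in seq_len(nrow(good))) {
        f <- get_fit(fits, good$property[[i]], good$index[[i]])
        ggplot2::ggsave(
          file.path(out_dir, sprintf("fit_%s_%s.png",
                                     good$property[[i]], good$index[[i]])),
          autoplot(f), width = 5, height = 4, dpi = 150
        )
      }
    }
  }
  invisible(out)
}
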