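# Univariate QSPR modelling: for each (property, index) pair, ordinary
# least squares of the property on the index, P = x + y * TI, with Pearson
# correlation and a two-sided t-test on the slope.  Missing property cells
# are handled by listwise deletion per pair, which is what produces the
# varying sample sizes (9-16) of the published parameter tables.

#' Fit one property-on-index linear model
#'
#' Ordinary least squares of `p` on `ti` (model `P = x + y * TI`), with
#' the Pearson correlation `r`, its square, and the two-sided p-value of
#' the slope (`t = r * sqrt((n-2)/(1-r^2))` on `n - 2` df).  A fit is
#' flagged `significant` when `p <= 0.05`.
#'
#' @param ti Numeric vector of index (descriptor) values.
#' @param p Numeric vector of property values, same length.
#' @param index,property Optional labels carried into the result.
#' @return An object of class `qspr_fit`: a list with `property`,
#'   `index`, `n`, `intercept`, `slope`, their standard errors, `r`,
#'   `r2`, `p_value`, `significant`, and the data used.
#' @examples
#' f <- fit_linear(1:10, 2 * (1:10) + 1 + rnorm(10, sd = 0.1))
#' tidy(f)
#' @export
fit_linear <- function(ti, p, index = NA_character_, property = NA_character_) {
  keep <- !is.na(ti) & !is.na(p)
  ti <- ti[keep]
  p <- p[keep]
  n <- length(ti)
  if (n < 3L) abort("need at least 3 complete (ti, p) pairs")
  if (var(ti) == 0) abort("degenerate fit: index values are all equal")
  if (var(p) == 0) abort("degenerate fit: property values are all equal")
  fit <- lm(p ~ ti)
  # noiseless synthetic data legitimately yields perfect fits; summary.lm's
  # "essentially perfect fit" warning is noise in that case
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  r <- cor(ti, p)
  structure(
    list(
      property = property, index = index, n = n,
      intercept = unname(coef(fit)[1]), slope = slope,
      se_intercept = sm$coefficients[1, 2],
      se_slope = sm$coefficients[2, 2],
      r = r, r2 = r^2,
      p_value = sm$coefficients[2, 4],
      significant = sm$coefficients[2, 4] <= 0.05,
      data = tibble(ti = ti, p = p)
    ),
    class = "qspr_fit"
  )
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf(
    "<qspr_fit> %s ~ %s  (n = %d)\n  P = %.4g + %.4g * TI,  r = %.4f, r2 = %.4f, p = %.3g%s\n",
    x$property %|na|% "P", x$index %|na|% "TI", x$n,
    x$intercept, x$slope, x$r, x$r2, x$p_value,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' @exportS3Method generics::tidy
tidy.qspr_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' @exportS3Method generics::glance
glance.qspr_fit <- function(x, ...) {
  tibble(
    property = x$property, index = x$index, n = x$n,
    intercept = x$intercept, slope = x$slope,
    r = x$r, r2 = x$r2, p_value = x$p_value, significant = x$significant
  )
}

#' Fit every property-on-index regression
#'
#' Crosses all properties of a property table with all index columns of
#' an index table and fits [fit_linear()] to each pair after listwise
#' deletion of absent cells.  Pairs with fewer than 3 complete rows or a
#' degenerate index column are kept as unavailable rows (`available =
#' FALSE`) rather than failing the run.
#'
#' @param properties A long `property_table` (see [hep_properties()]),
#'   or any tibble with columns `drug`, `property`, `value`.
#' @param indices An index table: a `drug` (or `molecule`) column plus
#'   one numeric column per index.
#' @return A tibble of class `qspr_results`: one row per (property,
#'   index) with `n`, `intercept`, `slope`, `r`, `r2`, `p_value`,
#'   `significant`, `available`.  The fitted `qspr_fit` objects are kept
#'   in the `fits` attribute, keyed `"property.index"`.
#' @export
qspr_fit_all <- function(properties, indices) {
  nm <- intersect(c("drug", "molecule"), names(indices))[1]
  if (is.na(nm)) abort("index table needs a `drug` or `molecule` column")
  idx_names <- setdiff(names(indices), nm)
  drugs_p <- unique(properties$drug)
  missing_drugs <- setdiff(drugs_p, indices[[nm]])
  extra_drugs <- setdiff(indices[[nm]], drugs_p)
  if (length(missing_drugs) || length(extra_drugs)) {
    abort(paste0(
      "drug keys do not align between property and index tables\n",
      "  only in property table: ",
      paste(missing_drugs, collapse = ", ") %|empty|% "(none)", "\n",
      "  only in index table: ",
      paste(extra_drugs, collapse = ", ") %|empty|% "(none)"
    ))
  }
  props <- unique(properties$property)
  fits <- list()
  rows <- list()
  for (pr in props) {
    pv <- properties |> dplyr::filter(.data$property == pr)
    pvec <- setNames(pv$value, pv$drug)[indices[[nm]]]
    for (ix in idx_names) {
      key <- paste(pr, ix, sep = ".")
      fit <- tryCatch(
        fit_linear(indices[[ix]], unname(pvec), index = ix, property = pr),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        rows[[key]] <- tibble(
          property = pr, index = ix, n = sum(!is.na(pvec) & !is.na(indices[[ix]])),
          intercept = NA_real_, slope = NA_real_, r = NA_real_,
          r2 = NA_real_, p_value = NA_real_, significant = NA,
          available = FALSE
        )
      } else {
        fits[[key]] <- fit
        rows[[key]] <- dplyr::mutate(glance(fit), available = TRUE)
      }
    }
  }
  out <- purrr::list_rbind(rows)
  structure(out,
    fits = fits, index_order = idx_names,
    class = c("qspr_results", class(out))
  )
}

#' @exportS3Method generics::tidy
tidy.qspr_results <- function(x, ...) as_tibble(x)

#' Extract one stored fit from a result set
#'
#' @param results A `qspr_results` object.
#' @param property,index The pair to extract.
#' @return The `qspr_fit`, or `NULL` when that pair was unavailable.
#' @export
get_fit <- function(results, property, index) {
  attr(results, "fits")[[paste(property, index, sep = ".")]]
}

#' Correlation comparison matrix (indices x properties)
#'
#' @param results A `qspr_results` object.
#' @param digits Rounding for display (default 4, matching the published
#'   comparison table); use `NULL` for full precision.
#' @return A tibble with one row per index and one column per property,
#'   holding the Pearson `r` of each fit.
#' @export
comparison_matrix <- function(results, digits = 4) {
  wide <- as_tibble(results) |>
    dplyr::select("property", "index", "r") |>
    tidyr::pivot_wider(names_from = "property", values_from = "r")
  ord <- attr(results, "index_order") %||% unique(results$index)
  wide <- wide[match(ord, wide$index), ]
  if (!is.null(digits)) {
    wide <- dplyr::mutate(wide, dplyr::across(-"index", ~ round(.x, digits)))
  }
  wide
}

#' Best descriptor per property
#'
#' For each property, the index maximizing |r|; ties broken by index
#' declaration order (the [index_names()] order).
#'
#' @param results A `qspr_results` object.
#' @return A tibble: `property`, `index`, `r`, `r2`.
#' @export
best_index_report <- function(results) {
  ord <- attr(results, "index_order") %||% unique(results$index)
  as_tibble(results) |>
    dplyr::filter(.data$available) |>
    dplyr::mutate(.ord = match(.data$index, ord)) |>
    dplyr::group_by(.data$property) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("property", "index", "r", "r2")
}

`%|empty|%` <- function(a, b) if (nzchar(a)) a else b
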