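#' Inverse-hyperbolic-sine transform of raw marker counts
#'
#' Variance-stabilizing transform conventionally applied to cytometry counts:
#' `asinh(raw / cofactor)`. Strictly increasing, maps 0 to 0, behaves like
#' `raw / cofactor` near zero and like `log(2 * raw / cofactor)` for large
#' counts.
#'
#' @param raw numeric vector or matrix of non-negative raw counts.
#' @param cofactor single positive scaling cofactor (default 1).
#' @return transformed values, same shape as `raw`.
#' @export
#' @examples
#' asinh_transform(c(0, 1, 10), cofactor = 1)
asinh_transform <- function(raw, cofactor = 1) {
  if (length(cofactor) != 1 || !is.finite(cofactor) || cofactor <= 0) {
    stop("cofactor must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("raw counts must be finite and non-negative", call. = FALSE)
  }
  asinh(raw / cofactor)
}

#' Add transformed marker columns to a cell table
#'
#' Applies [asinh_transform()] to every raw marker column and stores the
#' result in columns named `<marker>_t`.
#'
#' @param cells cell table with one raw-count column per panel marker.
#' @param markers character vector of marker column names.
#' @param cofactor arcsinh cofactor.
#' @return `cells` with added `<marker>_t` columns.
#' @export
transform_markers <- function(cells, markers = sgc_panel()$marker, cofactor = 1) {
  missing <- setdiff(markers, names(cells))
  if (length(missing) > 0) {
    stop("missing marker column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (m in markers) {
    cells[[paste0(m, "_t")]] <- asinh_transform(cells[[m]], cofactor)
  }
  cells
}
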