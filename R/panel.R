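#' The 13-marker imaging-mass-cytometry panel
#'
#' Marker panel used throughout the pipeline: 12 protein markers plus a
#' nuclear (DNA intercalator) channel. Role tags drive which markers each
#' phenotyping stage clusters on.
#'
#' @return a tibble with columns `marker` and `role`
#'   (epithelial / vascular / immune / CAF / proliferation / nuclear).
#' @export
#' @examples
#' sgc_panel()
sgc_panel <- function() {
  tibble::tibble(
    marker = c("CKAE13", "CD31", "Vimentin", "aSMA", "Collagen1", "Ki67",
               "CD34", "CD74", "CD45", "CD4", "CD8a", "CD138", "DNA"),
    role = c("epithelial", "vascular", "CAF", "CAF", "CAF", "proliferation",
             "vascular", "immune", "immune", "immune", "immune", "immune",
             "nuclear")
  )
}

#' Cell-type label vocabulary
#'
#' Final phenotype labels of the hierarchy and their level-1 compartment.
#' Level-1 compartments are tumor, endothelia, immune and CAF; immune and
#' CAF compartments are subdivided by explicit marker rules.
#'
#' @return a tibble with columns `label` (final label) and `level1`.
#' @export
#' @examples
#' sgc_cell_types()
sgc_cell_types <- function() {
  tibble::tibble(
    label = c("tumor", "endothelia",
              "plasma cell", "CD8 T", "CD4 T", "proliferating CD4 T",
              "CD4+CD74+ T", "other CD4+", "other immune",
              "mCAF", "Collagen CAF", "SMA CAF", "dCAF", "apCAF",
              "other CAF (Vimentin+)"),
    level1 = c("tumor", "endothelia",
               rep("immune", 7),
               rep("CAF", 6))
  )
}

#' @rdname sgc_cell_types
#' @export
sgc_labels <- function() sgc_cell_types()$label
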