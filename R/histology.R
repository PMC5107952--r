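#' Histology label vocabulary
#'
#' The fixed set of tissue-class labels used throughout the package:
#' adjacent unaffected liver, viable tumor, the two necrosis subtypes
#' (usual necrosis, a feature of tumor progression, and infarct-like
#' necrosis, a feature of treatment response), an unspecified necrosis
#' label for annotations that do not subtype, fibrosis, inflammation,
#' and a combined mucin / off-tissue MALDI-matrix class.
#'
#' @return Character vector of the eight canonical labels.
#' @export
histology_labels <- function() {
  c("adjacent_liver", "tumor", "usual_necrosis", "infarct_like_necrosis",
    "necrosis_unspecified", "fibrosis", "inflammation", "mucin_matrix")
}

#' Display palette for histology labels
#'
#' Colors follow the convention used for MSI segment display: liver blue,
#' tumor red, necrosis purple, fibrosis grey, inflammation green, and
#' mucin/matrix white.
#'
#' @return Named character vector mapping each label to a color.
#' @export
histology_palette <- function() {
  c(adjacent_liver        = "blue",
    tumor                 = "red",
    usual_necrosis        = "purple4",
    infarct_like_necrosis = "purple",
    necrosis_unspecified  = "purple3",
    fibrosis              = "grey",
    inflammation          = "green",
    mucin_matrix          = "white")
}

.assert_histology <- function(labels, allow_na = FALSE) {
  ok <- labels %in% histology_labels()
  if (allow_na) ok <- ok | is.na(labels)
  if (!all(ok)) {
    stop("unknown histology label(s): ",
         paste(unique(labels[!ok]), collapse = ", "))
  }
  invisible(labels)
}
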