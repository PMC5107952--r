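# Automated modified Tumor Regression Grade (mTRG).
#
# The grade summarizes how much of a lesion is still viable tumor (plus
# usual necrosis, the necrosis of tumor progression) versus replaced by
# fibrosis/inflammation and infarct-like necrosis (the necrosis of
# treatment response).  Grade 1 is complete response, grade 5 none;
# grades map onto three response strata used for survival analysis.

#' Lesion composition over the grading denominator
#'
#' @param viable_tumor,usual_necrosis,infarct_like_necrosis,fibrosis_inflammation
#'   Percentages (each >= 0) that must sum to 100.  Fibrosis and
#'   inflammation are merged because the grade does not distinguish
#'   them.
#' @return Object of class `composition`.
#' @export
composition <- function(viable_tumor = 0, usual_necrosis = 0,
                        infarct_like_necrosis = 0,
                        fibrosis_inflammation = 0) {
  p <- c(viable_tumor = viable_tumor, usual_necrosis = usual_necrosis,
         infarct_like_necrosis = infarct_like_necrosis,
         fibrosis_inflammation = fibrosis_inflammation)
  if (any(p < 0)) stop("composition percentages must be >= 0")
  if (abs(sum(p) - 100) > 1e-6)
    stop("composition percentages must sum to 100 (got ", sum(p), ")")
  structure(as.list(p), class = "composition")
}

#' Lesion composition from a per-pixel histology label map
#'
#' Counts pixels of the grading-relevant classes — viable tumor, usual
#' necrosis, infarct-like necrosis, fibrosis, inflammation — inside the
#' lesion mask and converts them to percentages of their total.
#' Adjacent liver, mucin/matrix, and unclassified pixels are excluded
#' from the denominator; fibrosis and inflammation are merged.
#' Unsubtyped necrosis (`necrosis_unspecified`) is counted as usual
#' necrosis, the prognostically conservative choice.
#'
#' @param labels Character histology label per pixel.
#' @param lesion_mask Logical or integer index of pixels belonging to
#'   the lesion; default all pixels (liver/matrix are excluded by class
#'   anyway).
#' @return A [composition()].
#' @export
composition_from_labels <- function(labels, lesion_mask = NULL) {
  .assert_histology(labels, allow_na = TRUE)
  if (is.null(lesion_mask)) lesion_mask <- seq_along(labels)
  lab <- labels[lesion_mask]
  n_vt  <- sum(lab == "tumor", na.rm = TRUE)
  n_un  <- sum(lab %in% c("usual_necrosis", "necrosis_unspecified"),
               na.rm = TRUE)
  n_iln <- sum(lab == "infarct_like_necrosis", na.rm = TRUE)
  n_fi  <- sum(lab %in% c("fibrosis", "inflammation"), na.rm = TRUE)
  total <- n_vt + n_un + n_iln + n_fi
  if (total == 0L)
    stop("lesion mask contains only excluded classes")
  composition(viable_tumor = 100 * n_vt / total,
              usual_necrosis = 100 * n_un / total,
              infarct_like_necrosis = 100 * n_iln / total,
              fibrosis_inflammation = 100 * n_fi / total)
}

#' Automated mTRG grade from a lesion composition
#'
#' With `T` = viable tumor + usual necrosis (%) and `F` =
#' fibrosis + inflammation (%), the grade is assigned top-down:
#' \itemize{
#'   \item `T == 0` (up to `tol`): grade 1 — tumor fully replaced.
#'   \item `T < 7`: grade 2 — rare residual tumor foci (the 7% cutoff
#'     operationalizes "rare").
#'   \item `7 <= T < 50`: grade 3.
#'   \item `T >= 50`, `F >= 5`: grade 4.
#'   \item `T >= 50`, `F < 5`: grade 5 — no meaningful fibrotic
#'     response.
#' }
#' Higher grade = worse response.
#'
#' @param c A [composition()].
#' @param tol Tolerance on the grade-1 "no tumor" condition (default 0;
#'   a small positive value absorbs classification noise).
#' @return Object of class `mtrg_grade`: list with integer `grade`,
#'   `t_percent`, `f_percent`.
#' @export
mtrg_score <- function(c, tol = 0) {
  stopifnot(inherits(c, "composition"))
  t_pct <- c$viable_tumor + c$usual_necrosis
  f_pct <- c$fibrosis_inflammation
  grade <- if (t_pct <= tol) 1L
  else if (t_pct < 7) 2L
  else if (t_pct < 50) 3L
  else if (f_pct >= 5) 4L
  else 5L
  structure(list(grade = grade, t_percent = t_pct, f_percent = f_pct),
            class = "mtrg_grade")
}

#' @export
print.mtrg_grade <- function(x, ...) {
  cat(sprintf("mTRG %d (tumor+UN %.1f%%, fibrosis+inflammation %.1f%%)\n",
              x$grade, x$t_percent, x$f_percent))
  invisible(x)
}

#' Response group from an mTRG grade
#'
#' Grades 1-2 are a major response, grade 3 partial, grades 4-5 minor.
#'
#' @param g An `mtrg_grade` or an integer grade 1-5.
#' @return `"major"`, `"partial"` or `"minor"`.
#' @export
response_group <- function(g) {
  grade <- if (inherits(g, "mtrg_grade")) g$grade else as.integer(g)
  if (is.na(grade) || grade < 1L || grade > 5L)
    stop("grade must be an integer in 1..5")
  c("major", "major", "partial", "minor", "minor")[grade]
}

#' Per-lesion grading report
#'
#' @param lesions Named list of per-pixel label vectors (one per
#'   lesion), or a list of lists with `labels` and optional
#'   `lesion_mask`.
#' @return data.frame: lesion id, the four composition percentages,
#'   `t_percent`, `f_percent`, `grade`, `response`.
#' @export
grade_lesions <- function(lesions) {
  ids <- names(lesions)
  if (is.null(ids)) ids <- paste0("lesion", seq_along(lesions))
  rows <- lapply(seq_along(lesions), function(i) {
    l <- lesions[[i]]
    labs <- if (is.list(l)) l$labels else l
    mask <- if (is.list(l)) l$lesion_mask else NULL
    comp <- composition_from_labels(labs, mask)
    g <- mtrg_score(comp)
    data.frame(lesion = ids[i],
               viable_tumor = comp$viable_tumor,
               usual_necrosis = comp$usual_necrosis,
               infarct_like_necrosis = comp$infarct_like_necrosis,
               fibrosis_inflammation = comp$fibrosis_inflammation,
               t_percent = g$t_percent, f_percent = g$f_percent,
               grade = g$grade, response = response_group(g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
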