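#' Best-location binocular merge (integrated visual field)
#'
#' Positionwise maximum of the two monocular sensitivity fields (both in
#' right-eye orientation): under binocular viewing each location is seen by
#' whichever eye is more sensitive there. The merged MD is the mean of the
#' monocular MDs when both are available.
#'
#' @param left,right [sensitivity_field()]s with the same layout.
#' @return A [sensitivity_field()] with `eye = "integrated"`.
#' @export
merge_ivf <- function(left, right) {
  if (!identical(attr(left, "layout"), attr(right, "layout")))
    stop("fields must share a layout")
  md <- mean(c(attr(left, "md"), attr(right, "md")))
  sensitivity_field(pmax(left$sensitivity_db, right$sensitivity_db),
                    attr(left, "layout"), md = md, eye = "integrated")
}

#' IVF score parameters
#'
#' @param thresholds the two dB class boundaries (default `c(10, 20)`): a
#'   location scores 0 at >= 20 dB, 1 in \[10, 20) and 2 below 10 dB. The
#'   middle class is half-open so the three classes tile the dB axis.
#' @return list of class `ivf_score_params`.
#' @export
ivf_score_params <- function(thresholds = c(10, 20)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  structure(list(thresholds = thresholds), class = "ivf_score_params")
}

#' Integrated visual field score
#'
#' Sums per-location defect penalties over the 52 non-blind-spot locations of
#' the 24-2 integrated field: 0 for a threshold of at least 20 dB, 1 for
#' \[10, 20) dB, 2 below 10 dB. Total range 0 (intact) to 104 (blind).
#'
#' @param field an integrated [sensitivity_field()].
#' @param params an [ivf_score_params()].
#' @return integer score.
#' @export
ivf_score <- function(field, params = ivf_score_params()) {
  s <- field$sensitivity_db[!field$blind_spot]
  lo <- params$thresholds[1]; hi <- params$thresholds[2]
  sum(ifelse(s >= hi, 0L, ifelse(s >= lo, 1L, 2L)))
}

#' Mean-deviation summaries for one patient
#'
#' @param md_left,md_right MD in dB per eye.
#' @param open_eye which eye was uncovered during the experiment
#'   (`"left"`/`"right"`).
#' @return list: `mean_md`, `md_open`, `md_covered`, `md_diff` (open minus
#'   covered; positive means the patient watched with the better eye) and
#'   `better_eye_used`.
#' @export
md_summaries <- function(md_left, md_right, open_eye = c("left", "right")) {
  open_eye <- match.arg(open_eye)
  md_open <- if (open_eye == "left") md_left else md_right
  md_covered <- if (open_eye == "left") md_right else md_left
  diff <- md_open - md_covered
  list(mean_md = mean(c(md_left, md_right)), md_open = md_open,
       md_covered = md_covered, md_diff = diff,
       better_eye_used = is.finite(diff) && diff > 0)
}
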