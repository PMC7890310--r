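#' Three-class survival label at a fixed horizon
#'
#' Recodes a censored endpoint (time, event) into the 3-class label used by
#' the causal-discovery stage: class 1 = the event never occurred during
#' follow-up; class 2 = the event occurred within the horizon (36 months by
#' default, boundary inclusive); class 3 = the event occurred after the
#' horizon. Patients censored before the horizon are unclassifiable and
#' violate the study's inclusion criterion of at least 36 months follow-up.
#'
#' @param time_months Positive event/censoring times in months.
#' @param event 0/1 event indicators.
#' @param horizon Horizon in months (default 36).
#' @return Integer vector with values in `{1, 2, 3}`.
#' @examples
#' three_class_label(c(20, 48, 50), c(1, 1, 0))  # 2, 3, 1
#' @export
three_class_label <- function(time_months, event, horizon = 36) {
  stopifnot(length(time_months) == length(event),
            all(event %in% 0:1), all(time_months > 0))
  bad <- which(event == 0 & time_months < horizon)
  if (length(bad)) {
    stop("patient ", bad[1], " censored at ", round(time_months[bad[1]], 2),
         " months: unclassifiable under study inclusion criteria ",
         "(censored before the ", horizon, "-month horizon)", call. = FALSE)
  }
  ifelse(event == 0, 1L, ifelse(time_months <= horizon, 2L, 3L))
}

#' Binary 3-year outcome from the 3-class label
#'
#' The positive class is an event within the horizon (class 2); classes 1
#' (event-free) and 3 (late event) are negative. With this convention the
#' positive prevalence equals one minus the 3-year event-free rate, which is
#' the reading consistent with the printed operating points of the source
#' series.
#'
#' @param label Integer labels in `{1, 2, 3}` from [three_class_label()].
#' @return Integer 0/1 vector.
#' @examples
#' binarize_3yr(c(1, 2, 3))  # 0, 1, 0
#' @export
binarize_3yr <- function(label) {
  stopifnot(all(label %in% 1:3))
  as.integer(label == 2L)
}

#' @rdname three_class_label
#' @param cohort A cohort table.
#' @param outcome `"pfs"` or `"os"`.
#' @return `cohort_label()` returns a list with the 3-class `label` and the
#'   binary `y` for the requested endpoint.
#' @export
cohort_label <- function(cohort, outcome = c("pfs", "os"), horizon = 36) {
  outcome <- match.arg(outcome)
  time <- cohort[[paste0(outcome, "_months")]]
  event <- cohort[[paste0(outcome, "_event")]]
  lab <- three_class_label(time, event, horizon)
  list(label = lab, y = binarize_3yr(lab))
}
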