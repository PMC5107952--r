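# Outcome analysis: Kaplan-Meier curves per response group, log-rank
# (Mantel-Cox) comparison, and grader-agreement correlation.  The
# estimators are delegated to the survival package; this module fixes
# the record layout and the conventions (events before censorings at
# tied times, which is survfit's behaviour).

#' Assemble survival records
#'
#' @param id Subject/lesion identifiers.
#' @param time Follow-up time in months (>= 0).
#' @param event 1 = event observed, 0 = censored.
#' @param group Grouping label (e.g. response group or grader).
#' @param chemo Optional logical: received chemotherapy (survival
#'   analyses are typically restricted to treated patients).
#' @return data.frame of class `survival_records`.
#' @export
survival_records <- function(id, time, event, group,
                             chemo = rep(TRUE, length(id))) {
  time <- as.numeric(time)
  if (any(time < 0)) stop("times must be >= 0")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  df <- data.frame(id = id, time = time, event = event,
                   group = as.character(group), chemo = as.logical(chemo),
                   stringsAsFactors = FALSE)
  class(df) <- c("survival_records", "data.frame")
  df
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over the distinct event times; subjects
#' censored at an event time are counted at risk for that time.
#'
#' @param records A [survival_records()] data.frame (or any data.frame
#'   with `time` and `event` columns).
#' @param chemo_only Restrict to chemotherapy-treated records when a
#'   `chemo` column is present (default `FALSE`).
#' @return data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
kaplan_meier <- function(records, chemo_only = FALSE) {
  records <- .filter_chemo(records, chemo_only)
  if (nrow(records) == 0L) stop("no records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at given times from a KM curve
#'
#' @param km A [kaplan_meier()] curve.
#' @param t Times at which to evaluate the step function.
#' @return Numeric survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i) == 0L) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' Compares the event-time distributions of two or more groups via the
#' observed-minus-expected event sums over the pooled event times.
#'
#' @param records A [survival_records()] data.frame with a `group`
#'   column, or a list of per-group data.frames.
#' @param chemo_only Restrict to chemotherapy-treated records.
#' @return List with `chi_square`, `df` (groups - 1), and `p_value`.
#' @export
logrank_test <- function(records, chemo_only = FALSE) {
  if (is.list(records) && !is.data.frame(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("group", seq_along(records))
    records <- do.call(rbind, lapply(seq_along(records), function(i) {
      r <- records[[i]]; r$group <- ids[i]; r
    }))
  }
  records <- .filter_chemo(records, chemo_only)
  groups <- unique(records$group)
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  if (any(tapply(records$time, records$group, max) == 0))
    stop("a group has all-zero follow-up")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records, rho = 0)
  df <- length(groups) - 1L
  list(chi_square = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Correlation between two graders' scores
#'
#' Pearson product-moment correlation between two equal-length grade
#' vectors (e.g. an automated grading vs a pathologist); Spearman rank
#' correlation available behind the `method` flag.
#'
#' @param a,b Numeric grade vectors, equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient r.
#' @export
grader_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("grade vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 paired grades")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant grade vector")
  stats::cor(a, b, method = method)
}

.filter_chemo <- function(records, chemo_only) {
  if (chemo_only && !is.null(records$chemo))
    records <- records[records$chemo, , drop = FALSE]
  records
}
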