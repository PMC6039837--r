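#' @title Test-retest reliability (intraclass correlation)
#'
#' @description
#' Run-to-run reliability of each graph measure is quantified with the
#' two-way-ANOVA intraclass correlation
#' ICC = (MS_b - MS_E) / (MS_b + (k - 1) MS_E), where MS_b is the
#' between-subject mean square, MS_E the mean square error after removing
#' subject and session main effects, and k the number of sessions. This is
#' the consistency form ICC(3,1). Ratings: poor (< 0.2), fair (0.2-0.4),
#' moderate (0.4-0.6), good (0.6-0.8), excellent (>= 0.8).
#' @name reliability
NULL

#' Two-way-ANOVA intraclass correlation
#'
#' @param values complete subjects x sessions numeric matrix (k >= 2
#'   sessions, >= 2 subjects).
#' @return object of class `icc_result`: `icc`, `ms_between`, `ms_error`,
#'   `k`, `rating`.
#' @export
icc_two_way <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 2) stop("need at least 2 sessions")
  if (n < 2) stop("need at least 2 subjects")
  if (any(!is.finite(values))) stop("missing cells in the subjects x sessions table")
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), times = k)),
                   session = factor(rep(seq_len(k), each = n)))
  tab <- suppressWarnings(
    stats::anova(stats::aov(y ~ subject + session, data = df)))
  ms_b <- tab["subject", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  icc <- (ms_b - ms_e) / (ms_b + (k - 1) * ms_e)
  structure(list(icc = icc, ms_between = ms_b, ms_error = ms_e, k = k,
                 rating = icc_rating(icc)),
            class = "icc_result")
}

#' Reliability rating band for an ICC value
#'
#' @param icc finite ICC value.
#' @return one of `"poor"`, `"fair"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
icc_rating <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc < 0.2) "poor"
  else if (icc < 0.4) "fair"
  else if (icc < 0.6) "moderate"
  else if (icc < 0.8) "good"
  else "excellent"
}

#' ICC table per measure x band x group
#'
#' Patients (responders and non-responders) are pooled into one group, as in
#' the reliability analysis this mirrors.
#'
#' @param per_run per-run feature table from [cohort_features()] (columns
#'   subject_id, group, band, run, modularity, transitivity, cpl).
#' @return data.frame: group, measure, band, icc, rating.
#' @export
icc_table <- function(per_run) {
  per_run$pool <- ifelse(per_run$group == "control", "controls", "patients")
  out <- list()
  for (pool in unique(per_run$pool)) {
    for (meas in c("cpl", "transitivity", "modularity")) {
      for (b in unique(per_run$band)) {
        sub <- per_run[per_run$pool == pool & per_run$band == b, ]
        wide <- stats::reshape(
          sub[, c("subject_id", "run", meas)],
          idvar = "subject_id", timevar = "run", direction = "wide")
        m <- as.matrix(wide[, -1, drop = FALSE])
        r <- icc_two_way(m)
        out[[length(out) + 1L]] <- data.frame(
          group = pool, measure = meas, band = b, icc = r$icc,
          rating = r$rating)
      }
    }
  }
  do.call(rbind, out)
}
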