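#' Empirical quintile cutoff for the poor-outcome definition
#'
#' Poor outcome after arthroplasty has no consensus definition; the
#' last-quintile construction labels the worst-scoring 20% of the cohort's
#' six-month totals as poor.  The cutoff is the empirical 80th percentile,
#' computed by linear interpolation between closest order statistics
#' (position \eqn{h = (n - 1) p + 1}; the default quantile convention of
#' most statistical software).
#'
#' @param scores Numeric vector of six-month total scores; \code{NA} dropped.
#' @param prob Percentile defining the cutoff (default 0.8, i.e. the last
#'   quintile).
#' @return The cutoff score.
#' @export
#' @examples
#' quintileCutoff(c(10, 20, 30, 40, 50)) # 42
quintileCutoff <- function(scores, prob = 0.8) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 5L) {
    stop("at least 5 non-missing scores are required to place a quintile cutoff",
      call. = FALSE
    )
  }
  unname(stats::quantile(scores, probs = prob, type = 7))
}

#' Label patients as poor / satisfactory outcome
#'
#' By default a patient is labelled \code{poor} when the six-month total
#' score is strictly greater than the cutoff, \code{satisfactory} otherwise.
#' Set \code{strict = FALSE} to include scores equal to the cutoff among the
#' poor outcomes.
#'
#' @param scores Numeric vector of six-month total scores.
#' @param cutoff Cutoff score in \code{[0, 100]} (see
#'   \code{\link{quintileCutoff}}).
#' @param strict Logical; use \code{score > cutoff} (default) rather than
#'   \code{score >= cutoff}.
#' @return An object of class \code{outcome_labelling}: list with
#'   \code{labels} (factor \code{satisfactory}/\code{poor}, \code{NA} for
#'   excluded patients), \code{cutoff}, \code{n_poor}, \code{n}.
#'   Patients with missing scores are excluded with a warning.
#' @export
labelOutcomes <- function(scores, cutoff, strict = TRUE) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0 || cutoff > 100) {
    stop("cutoff must be a single score in [0, 100]", call. = FALSE)
  }
  miss <- is.na(scores)
  if (any(miss)) {
    warning(sprintf(
      "%d patient(s) with missing six-month score excluded from labelling",
      sum(miss)
    ), call. = FALSE)
  }
  poor <- if (strict) scores > cutoff else scores >= cutoff
  labels <- factor(
    ifelse(poor, "poor", "satisfactory"),
    levels = c("satisfactory", "poor")
  )
  structure(
    list(
      labels = labels, cutoff = cutoff,
      n_poor = sum(poor, na.rm = TRUE), n = sum(!miss)
    ),
    class = "outcome_labelling"
  )
}

#' @export
print.outcome_labelling <- function(x, ...) {
  cat(sprintf(
    "Outcome labelling: %d / %d poor (%.1f%%), cutoff %.1f\n",
    x$n_poor, x$n, 100 * x$n_poor / x$n, x$cutoff
  ))
  invisible(x)
}

#' Write a labelled cohort to CSV
#'
#' @param ids Patient identifiers.
#' @param scores Six-month total scores.
#' @param labelling \code{\link{labelOutcomes}} result aligned with
#'   \code{ids}.
#' @param path Output file.
#' @return Invisibly, the written data frame.
#' @export
writeLabelledCohort <- function(ids, scores, labelling, path) {
  df <- data.frame(
    id = ids, total_6m = scores,
    cutoff = labelling$cutoff,
    outcome = as.character(labelling$labels),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
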