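# Diagnostic-validity panel for a binary prediction rule against the
# binary poor/satisfactory outcome: 2x2 table, Se/Sp/PPV/NPV with Wilson
# (or Clopper-Pearson) intervals, likelihood ratios with Simel log-method
# intervals, AUC = (Se + Sp)/2 with a Hanley-McNeil interval.

#' Cross-classify actual and predicted outcomes
#'
#' @param actual Labels \code{poor} / \code{satisfactory}.
#' @param predicted Labels \code{at_risk} / \code{not_at_risk}, aligned
#'   with \code{actual}.
#' @return Object of class \code{confusion_table}: named integer vector
#'   \code{(tp, fp, fn, tn)} where \code{tp} counts patients predicted
#'   at-risk whose actual outcome is poor.
#' @export
#' @examples
#' confusion(c("poor", "poor", "satisfactory"), c("at_risk", "not_at_risk", "not_at_risk"))
confusion <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted label vectors must have equal length", call. = FALSE)
  }
  actual <- as_outcome(actual)
  predicted <- as.character(predicted)
  if (!all(predicted %in% c("at_risk", "not_at_risk"))) {
    stop("predicted labels must be 'at_risk' or 'not_at_risk'", call. = FALSE)
  }
  confusionTable(
    tp = sum(actual == "poor" & predicted == "at_risk"),
    fp = sum(actual == "satisfactory" & predicted == "at_risk"),
    fn = sum(actual == "poor" & predicted == "not_at_risk"),
    tn = sum(actual == "satisfactory" & predicted == "not_at_risk")
  )
}

#' Build a confusion table from the four cell counts
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @return Object of class \code{confusion_table}.
#' @export
confusionTable <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.integer(counts), names = names(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x["tp"], x["fn"], x["fp"], x["tn"]),
    nrow = 2,
    dimnames = list(
      predicted = c("at_risk", "not_at_risk"),
      actual = c("poor", "satisfactory")
    )
  )
  print(m)
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' The interval obtained by inverting the score test; well-behaved at
#' small n and near the boundaries, always inside \code{[0, 1]}.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric \code{c(lo, hi)}.
#' @export
#' @examples
#' wilsonCi(23, 28) # c(0.644, 0.921)
wilsonCi <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("undefined proportion: zero trials", call. = FALSE)
  if (successes < 0 || successes > trials) {
    stop("successes must lie in [0, trials]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  centre <- (p + z^2 / (2 * trials)) / (1 + z^2 / trials)
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / (1 + z^2 / trials)
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Clopper-Pearson (exact binomial) interval
#'
#' Non-default alternative to \code{\link{wilsonCi}}.
#'
#' @inheritParams wilsonCi
#' @return Numeric \code{c(lo, hi)}.
#' @export
clopperPearsonCi <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("undefined proportion: zero trials", call. = FALSE)
  a <- (1 - level) / 2
  lo <- if (successes == 0) 0 else stats::qbeta(a, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else stats::qbeta(1 - a, successes + 1, trials - successes)
  c(lo = lo, hi = hi)
}

proportion_ci <- function(successes, trials, level, method) {
  switch(method,
    wilson = wilsonCi(successes, trials, level),
    `clopper-pearson` = clopperPearsonCi(successes, trials, level)
  )
}

#' Likelihood ratios with Simel log-method intervals
#'
#' Point estimates \eqn{LR+ = Se/(1 - Sp)} and \eqn{LR- = (1 - Se)/Sp};
#' intervals by exponentiating \eqn{\ln LR \pm z \, SE(\ln LR)} with
#' \eqn{SE^2(\ln LR+) = (1-Se)/(n_1 Se) + Sp/(n_0 (1-Sp))} and the
#' symmetric expression for LR-.
#'
#' @param table A \code{\link{confusionTable}}.
#' @param level Confidence level (default 0.95).
#' @return List with \code{lr_pos} and \code{lr_neg}, each
#'   \code{list(estimate, lo, hi, defined)}; a degenerate margin yields an
#'   infinite or undefined estimate flagged \code{defined = FALSE} with no
#'   interval.
#' @export
likelihoodRatios <- function(table, level = 0.95) {
  tp <- table["tp"]; fp <- table["fp"]; fn <- table["fn"]; tn <- table["tn"]
  n1 <- tp + fn; n0 <- fp + tn
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- tp / n1; sp <- tn / n0
  lr_pos <- if (n1 == 0 || n0 == 0 || sp >= 1) {
    list(estimate = if (n1 > 0 && se > 0) Inf else NA_real_, lo = NA_real_, hi = NA_real_, defined = FALSE)
  } else {
    est <- se / (1 - sp)
    if (tp == 0 || fp == 0) {
      list(estimate = unname(est), lo = NA_real_, hi = NA_real_, defined = FALSE)
    } else {
      s <- sqrt((1 - se) / (n1 * se) + sp / (n0 * (1 - sp)))
      list(
        estimate = unname(est),
        lo = unname(exp(log(est) - z * s)), hi = unname(exp(log(est) + z * s)),
        defined = TRUE
      )
    }
  }
  lr_neg <- if (n1 == 0 || n0 == 0 || sp <= 0) {
    list(estimate = NA_real_, lo = NA_real_, hi = NA_real_, defined = FALSE)
  } else {
    est <- (1 - se) / sp
    if (fn == 0 || tn == 0) {
      list(estimate = unname(est), lo = NA_real_, hi = NA_real_, defined = FALSE)
    } else {
      s <- sqrt(se / (n1 * (1 - se)) + (1 - sp) / (n0 * sp))
      list(
        estimate = unname(est),
        lo = unname(exp(log(est) - z * s)), hi = unname(exp(log(est) + z * s)),
        defined = TRUE
      )
    }
  }
  list(lr_pos = lr_pos, lr_neg = lr_neg)
}

hanley_mcneil_ci <- function(auc, n1, n0, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  s <- sqrt(max(v, 0))
  c(lo = max(0, auc - z * s), hi = min(1, auc + z * s))
}

#' Full diagnostic-validity panel
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values (Wilson or Clopper-Pearson intervals), both likelihood ratios
#' (Simel log-method intervals) and the AUC of the binary rule,
#' \eqn{(Se + Sp)/2}, with a Hanley-McNeil interval.  Metrics whose
#' denominator is empty are flagged undefined.
#'
#' @param table A \code{\link{confusionTable}}.
#' @param level Confidence level (default 0.95).
#' @param ci_method \code{"wilson"} (default) or \code{"clopper-pearson"}
#'   for the four proportions.
#' @return Object of class \code{validity_report}: data frame with rows
#'   \code{sensitivity, specificity, ppv, npv, lr_pos, lr_neg, auc} and
#'   columns \code{estimate, lo, hi, ci_method, defined}, plus attributes
#'   \code{table} and \code{level}.
#' @export
#' @examples
#' validityReport(confusionTable(23, 32, 5, 81))
validityReport <- function(table, level = 0.95,
                           ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  tp <- table["tp"]; fp <- table["fp"]; fn <- table["fn"]; tn <- table["tn"]
  n <- sum(table)
  if (n == 0) stop("empty confusion table", call. = FALSE)
  prop_row <- function(x, m) {
    if (m == 0) {
      data.frame(
        estimate = NA_real_, lo = NA_real_, hi = NA_real_,
        ci_method = ci_method, defined = FALSE, stringsAsFactors = FALSE
      )
    } else {
      ci <- proportion_ci(x, m, level, ci_method)
      data.frame(
        estimate = x / m, lo = unname(ci["lo"]), hi = unname(ci["hi"]),
        ci_method = ci_method, defined = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  rows <- rbind(
    sensitivity = prop_row(tp, tp + fn),
    specificity = prop_row(tn, tn + fp),
    ppv = prop_row(tp, tp + fp),
    npv = prop_row(tn, tn + fn)
  )
  lr <- likelihoodRatios(table, level)
  lr_rows <- do.call(rbind, lapply(lr, function(l) {
    data.frame(
      estimate = l$estimate, lo = l$lo, hi = l$hi,
      ci_method = "simel-log", defined = l$defined, stringsAsFactors = FALSE
    )
  }))
  rownames(lr_rows) <- c("lr_pos", "lr_neg")
  n1 <- tp + fn; n0 <- fp + tn
  auc_row <- if (n1 == 0 || n0 == 0) {
    data.frame(
      estimate = NA_real_, lo = NA_real_, hi = NA_real_,
      ci_method = "hanley-mcneil", defined = FALSE, stringsAsFactors = FALSE
    )
  } else {
    auc <- unname((tp / n1 + tn / n0) / 2)
    ci <- hanley_mcneil_ci(auc, n1, n0, level)
    data.frame(
      estimate = auc, lo = unname(ci["lo"]), hi = unname(ci["hi"]),
      ci_method = "hanley-mcneil", defined = TRUE, stringsAsFactors = FALSE
    )
  }
  rownames(auc_row) <- "auc"
  out <- rbind(rows, lr_rows, auc_row)
  structure(out, class = c("validity_report", "data.frame"),
    table = table, level = level)
}

metric_estimate <- function(report, metric) {
  if (inherits(report, "validity_report") || is.data.frame(report)) {
    report[metric, "estimate"]
  } else {
    report[[metric]]
  }
}

#' @export
print.validity_report <- function(x, digits = NULL, ...) {
  lvl <- attr(x, "level")
  cat(sprintf("Diagnostic validity panel (%.0f%% CIs)\n", 100 * lvl))
  fmt <- function(metric, est, lo, hi, pct, dig) {
    if (is.na(est)) {
      return(sprintf("  %-28s undefined\n", metric))
    }
    if (pct) {
      sprintf(
        "  %-28s %5.1f (%.1f-%.1f)\n", metric, 100 * est, 100 * lo, 100 * hi
      )
    } else {
      sprintf(
        "  %-28s %5.2f (%.2f-%.2f)\n", metric, est, lo, hi
      )
    }
  }
  labels <- c(
    sensitivity = "Sensitivity % ", specificity = "Specificity % ",
    ppv = "Positive predictive value % ", npv = "Negative predictive value % ",
    lr_pos = "Positive likelihood ratio", lr_neg = "Negative likelihood ratio",
    auc = "Area under ROC curve"
  )
  for (m in rownames(x)) {
    pct <- m %in% c("sensitivity", "specificity", "ppv", "npv")
    cat(fmt(labels[[m]], x[m, "estimate"], x[m, "lo"], x[m, "hi"], pct, 2))
  }
  invisible(x)
}

#' Write a validity panel as JSON
#'
#' Rows follow the conventional panel order (sensitivity, specificity,
#' PPV, NPV, LR+, LR-, AUC).
#'
#' @param report A \code{\link{validityReport}}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeReport <- function(report, path) {
  tab <- attr(report, "table")
  doc <- list(
    format = "womacpr_validity_report", version = 1L,
    level = attr(report, "level"),
    table = as.list(setNames(as.integer(tab), names(tab))),
    metrics = lapply(rownames(report), function(m) {
      list(
        metric = m, estimate = report[m, "estimate"],
        lo = report[m, "lo"], hi = report[m, "hi"],
        ci_method = report[m, "ci_method"], defined = report[m, "defined"]
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cohort-flow accounting proportions
#'
#' Standard observational-study flow proportions: eligibility =
#' eligible/assessed; participation = interviewed / (eligible +
#' unknown_eligibility x eligibility), crediting patients of unknown
#' eligibility at the observed eligibility rate; follow-up = completed /
#' (interviewed - excluded_post_interview).
#'
#' @param assessed Number of patients whose eligibility was assessed.
#' @param eligible Number found eligible.
#' @param interviewed Number interviewed at enrolment.
#' @param unknown_eligibility Number never assessed (unreachable/refused
#'   before assessment).
#' @param excluded_post_interview Number excluded after the enrolment
#'   interview for reasons independent of follow-up (e.g. surgery not
#'   performed).
#' @param completed Number completing the final follow-up.
#' @return List with \code{eligibility}, \code{participation},
#'   \code{follow_up} (each \code{NA} with a \code{defined} flag when its
#'   denominator is zero).
#' @export
#' @examples
#' cohortAccounting(
#'   assessed = 511, eligible = 220, interviewed = 197,
#'   unknown_eligibility = 77, excluded_post_interview = 44, completed = 141
#' )
cohortAccounting <- function(assessed, eligible, interviewed,
                             unknown_eligibility, excluded_post_interview,
                             completed) {
  counts <- c(assessed, eligible, interviewed, unknown_eligibility,
    excluded_post_interview, completed)
  if (any(counts < 0)) stop("all counts must be nonnegative", call. = FALSE)
  safe_div <- function(a, b) if (b <= 0) NA_real_ else a / b
  eligibility <- safe_div(eligible, assessed)
  participation <- if (is.na(eligibility)) NA_real_ else {
    safe_div(interviewed, eligible + unknown_eligibility * eligibility)
  }
  follow_up <- safe_div(completed, interviewed - excluded_post_interview)
  list(
    eligibility = eligibility,
    participation = participation,
    follow_up = follow_up,
    defined = c(
      eligibility = !is.na(eligibility),
      participation = !is.na(participation),
      follow_up = !is.na(follow_up)
    )
  )
}
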