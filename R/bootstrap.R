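# Fixed-rule bootstrap internal validation: resample patients with
# replacement, recompute the validity panel per resample from the fixed
# predictions, and summarize by percentile (or normal-approximation)
# bounds.  The rule is applied, not re-derived, per resample.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

boot_metrics <- function(tp, fp, fn, tn) {
  n1 <- tp + fn
  n0 <- fp + tn
  se <- if (n1 > 0) tp / n1 else NA_real_
  sp <- if (n0 > 0) tn / n0 else NA_real_
  c(
    sensitivity = se,
    specificity = sp,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    lr_pos = if (!is.na(se) && !is.na(sp) && sp < 1) se / (1 - sp) else NA_real_,
    lr_neg = if (!is.na(se) && !is.na(sp) && sp > 0) (1 - se) / sp else NA_real_,
    auc = if (!is.na(se) && !is.na(sp)) (se + sp) / 2 else NA_real_
  )
}

#' Bootstrap internal validation of a fixed rule
#'
#' Draws \code{B} resamples of patient indices with replacement (each of
#' size n), recomputes the validity panel per resample from the fixed
#' predicted labels, and reports the original-sample point estimate with
#' percentile bounds.  Resamples where a metric's denominator is empty are
#' excluded from that metric's percentiles and counted in
#' \code{n_undefined}.  With a fixed seed the whole result is
#' reproducible bit for bit.
#'
#' @param actual Labels \code{poor} / \code{satisfactory}.
#' @param predicted Fixed labels \code{at_risk} / \code{not_at_risk}.
#' @param B Number of resamples (default 1000).
#' @param level Interval level (default 0.95).
#' @param seed Mandatory integer seed, recorded in the result.
#' @param interval \code{"percentile"} (default) or \code{"normal"}
#'   (normal approximation using the bootstrap standard error).
#' @return Object of class \code{bootstrap_result}: data frame with rows
#'   per metric and columns \code{estimate, lo, hi, n_undefined}, plus
#'   attributes \code{B}, \code{level}, \code{seed}, \code{interval},
#'   \code{rng} (RNG kind).
#' @export
bootstrapValidate <- function(actual, predicted, B = 1000, level = 0.95,
                              seed, interval = c("percentile", "normal")) {
  interval <- match.arg(interval)
  if (missing(seed)) stop("a seed is mandatory for reproducible resampling", call. = FALSE)
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  actual <- as_outcome(actual)
  n <- length(actual)
  if (n == 0) stop("empty cohort", call. = FALSE)
  if (length(predicted) != n) {
    stop("actual and predicted must be aligned", call. = FALSE)
  }
  predicted <- as.character(predicted)
  # per-patient cell id: 1 = tp, 2 = fp, 3 = fn, 4 = tn
  cell <- ifelse(actual == "poor",
    ifelse(predicted == "at_risk", 1L, 3L),
    ifelse(predicted == "at_risk", 2L, 4L)
  )
  point <- boot_metrics(sum(cell == 1), sum(cell == 2), sum(cell == 3), sum(cell == 4))
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      res <- cell[sample.int(n, n, replace = TRUE)]
      k <- tabulate(res, nbins = 4L)
      boot_metrics(k[1], k[2], k[3], k[4])
    }, numeric(7))
  })
  a <- (1 - level) / 2
  z <- stats::qnorm(1 - a)
  summ <- lapply(rownames(draws), function(m) {
    v <- draws[m, ]
    def <- v[!is.na(v)]
    n_undef <- sum(is.na(v))
    if (!length(def)) {
      return(data.frame(
        estimate = point[[m]], lo = NA_real_, hi = NA_real_,
        n_undefined = n_undef, stringsAsFactors = FALSE
      ))
    }
    bounds <- if (interval == "percentile") {
      stats::quantile(def, probs = c(a, 1 - a), names = FALSE, type = 7)
    } else {
      point[[m]] + c(-1, 1) * z * stats::sd(def)
    }
    data.frame(
      estimate = point[[m]], lo = bounds[1], hi = bounds[2],
      n_undefined = n_undef, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, summ)
  rownames(out) <- rownames(draws)
  structure(out,
    class = c("bootstrap_result", "data.frame"),
    B = B, level = level, seed = seed, interval = interval,
    rng = "Mersenne-Twister/Inversion", n = n
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap validation: B = %d, %s %.0f%% bounds, seed %d (%s), n = %d\n",
    attr(x, "B"), attr(x, "interval"), 100 * attr(x, "level"),
    attr(x, "seed"), attr(x, "rng"), attr(x, "n")
  ))
  for (m in rownames(x)) {
    pct <- m %in% c("sensitivity", "specificity", "ppv", "npv")
    sc <- if (pct) 100 else 1
    dg <- if (pct) 1 else 2
    cat(sprintf(
      "  %-12s %.*f (%.*f-%.*f)%s\n",
      m, dg, sc * x[m, "estimate"], dg, sc * x[m, "lo"], dg, sc * x[m, "hi"],
      if (x[m, "n_undefined"] > 0) {
        sprintf("  [%d undefined resample(s) excluded]", x[m, "n_undefined"])
      } else ""
    ))
  }
  invisible(x)
}

#' Write a bootstrap result as JSON
#'
#' @param result A \code{\link{bootstrapValidate}} result.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeBootstrapResult <- function(result, path) {
  doc <- list(
    format = "womacpr_bootstrap_result", version = 1L,
    B = attr(result, "B"), level = attr(result, "level"),
    seed = attr(result, "seed"), interval = attr(result, "interval"),
    rng = attr(result, "rng"), n = attr(result, "n"),
    metrics = lapply(rownames(result), function(m) {
      list(
        metric = m, estimate = result[m, "estimate"],
        lo = result[m, "lo"], hi = result[m, "hi"],
        n_undefined = result[m, "n_undefined"]
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reconstruct a patient-level cohort from a 2x2 table
#'
#' Expands the four cells of a confusion table into aligned actual and
#' predicted label vectors (tp first, then fp, fn, tn), e.g. to bootstrap
#' a published table at patient level.
#'
#' @param table A \code{\link{confusionTable}}.
#' @return List with \code{actual} and \code{predicted} factors.
#' @export
cohortFromTable <- function(table) {
  list(
    actual = factor(
      rep(c("poor", "satisfactory", "poor", "satisfactory"), table[c("tp", "fp", "fn", "tn")]),
      levels = c("satisfactory", "poor")
    ),
    predicted = factor(
      rep(c("at_risk", "at_risk", "not_at_risk", "not_at_risk"), table[c("tp", "fp", "fn", "tn")]),
      levels = c("not_at_risk", "at_risk")
    )
  )
}
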