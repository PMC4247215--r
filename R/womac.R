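# WOMAC LK 3.0 structure: 5 pain, 2 stiffness, 17 function items, each
# answered on the 5-level Likert scale 0 (none) .. 4 (extreme).
WOMAC_PAIN <- paste0("P", 1:5)
WOMAC_STIFFNESS <- paste0("S", 1:2)
WOMAC_FUNCTION <- paste0("F", 1:17)

#' Names of the 24 WOMAC item columns
#'
#' Column order used throughout the package and in cohort files:
#' five pain items \code{P1..P5}, two stiffness items \code{S1..S2},
#' seventeen function items \code{F1..F17}.
#'
#' @param subscale One of \code{"all"}, \code{"pain"}, \code{"stiffness"},
#'   \code{"function"}.
#' @return Character vector of item names.
#' @export
#' @examples
#' womacItems("stiffness")
womacItems <- function(subscale = c("all", "pain", "stiffness", "function")) {
  subscale <- match.arg(subscale)
  switch(subscale,
    all = c(WOMAC_PAIN, WOMAC_STIFFNESS, WOMAC_FUNCTION),
    pain = WOMAC_PAIN,
    stiffness = WOMAC_STIFFNESS,
    `function` = WOMAC_FUNCTION
  )
}

# Short descriptions of the items, used when rendering rules as
# questionnaires (standard WOMAC LK item wording, abbreviated).
womacItemLabels <- function() {
  c(
    P1 = "pain walking on a flat surface",
    P2 = "pain going up or down stairs",
    P3 = "pain at night while in bed",
    P4 = "pain sitting or lying",
    P5 = "pain standing upright",
    S1 = "stiffness after first wakening in the morning",
    S2 = "stiffness later in the day",
    F1 = "difficulty descending stairs",
    F2 = "difficulty ascending stairs",
    F3 = "difficulty rising from sitting",
    F4 = "difficulty standing",
    F5 = "difficulty bending to floor",
    F6 = "difficulty walking on flat surface",
    F7 = "difficulty getting in/out of car",
    F8 = "difficulty going shopping",
    F9 = "difficulty putting on socks/stockings",
    F10 = "difficulty rising from bed",
    F11 = "difficulty taking off socks/stockings",
    F12 = "difficulty lying in bed",
    F13 = "difficulty getting in/out of bath",
    F14 = "difficulty sitting",
    F15 = "difficulty getting on/off toilet",
    F16 = "difficulty with heavy domestic duties",
    F17 = "difficulty with light domestic duties"
  )
}

check_item_values <- function(x, what = "item") {
  x <- as.numeric(x)
  bad <- !is.na(x) & (x < 0 | x > 4 | x != round(x))
  if (any(bad)) {
    stop(sprintf(
      "%s values must be integers in [0, 4]; offending value(s): %s",
      what, paste(unique(x[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Construct a single-timepoint WOMAC response
#'
#' @param pain Numeric vector of 5 pain item answers (0-4, \code{NA} allowed).
#' @param stiffness Numeric vector of 2 stiffness item answers.
#' @param physical Numeric vector of 17 physical-function item answers.
#' @param timepoint \code{"baseline"} or \code{"six_month"}.
#' @return An object of class \code{womac_response}: a named numeric vector
#'   of the 24 items with a \code{timepoint} attribute.
#' @export
#' @examples
#' r <- womacResponse(rep(2, 5), rep(1, 2), rep(2, 17))
#' scoreWomac(r)
womacResponse <- function(pain, stiffness, physical,
                          timepoint = c("baseline", "six_month")) {
  timepoint <- match.arg(timepoint)
  if (length(pain) != 5L || length(stiffness) != 2L || length(physical) != 17L) {
    stop("WOMAC subscales must have exactly 5 (pain), 2 (stiffness) and 17 (function) items",
      call. = FALSE
    )
  }
  items <- c(
    check_item_values(pain, "pain"),
    check_item_values(stiffness, "stiffness"),
    check_item_values(physical, "function")
  )
  names(items) <- womacItems()
  structure(items, timepoint = timepoint, class = "womac_response")
}

#' Score one WOMAC subscale on the standardized 0-100 scale
#'
#' Standardization maps the raw item sum onto 0-100 with 0 meaning no
#' symptoms. Missing items are handled guideline-style: when at least
#' \code{min_present} of the subscale's items are answered, missing answers
#' are imputed with the mean of the answered items; otherwise the subscale
#' is invalid and \code{NA} is returned.
#'
#' @param items Numeric vector of item answers in 0-4, \code{NA} = missing.
#' @param subscale_size Expected number of items (5, 2 or 17 for WOMAC).
#' @param min_present Minimum fraction of answered items required (default 0.8).
#' @return Score in \code{[0, 100]}, or \code{NA_real_} when too few items
#'   are answered.
#' @export
#' @examples
#' scoreSubscale(c(2, 1, 3, 2, 2), 5) # 50
#' scoreSubscale(c(2, 2, 2, 2, NA), 5) # mean-imputed, still 50
scoreSubscale <- function(items, subscale_size = length(items), min_present = 0.8) {
  if (length(items) != subscale_size) {
    stop(sprintf(
      "expected %d items, got %d", subscale_size, length(items)
    ), call. = FALSE)
  }
  items <- check_item_values(items)
  n_present <- sum(!is.na(items))
  if (n_present < min_present * subscale_size) {
    return(NA_real_)
  }
  imputed <- impute_subscale(items)
  sum(imputed) / (4 * subscale_size) * 100
}

impute_subscale <- function(items) {
  if (anyNA(items)) {
    items[is.na(items)] <- mean(items, na.rm = TRUE)
  }
  items
}

#' Score a full WOMAC response
#'
#' Produces standardized pain, stiffness and function subscale scores and
#' the total score, each on 0-100 with 0 best.  Two total conventions are
#' supported: \code{"mean_subscales"} (default), the unweighted mean of the
#' three standardized subscale scores — the convention under which the
#' reference cohort's printed subscale and total means are mutually
#' consistent — and \code{"sum_items"}, the sum of all 24 (mean-imputed)
#' items divided by the maximum raw sum 96, times 100.  Either way the
#' total is valid only when all three subscales are valid.
#'
#' @param response A \code{\link{womacResponse}} object, or a named numeric
#'   vector containing the 24 item columns \code{P1..F17}.
#' @param min_present Passed to \code{\link{scoreSubscale}}.
#' @param total Total-score convention, \code{"mean_subscales"} or
#'   \code{"sum_items"}.
#' @return An object of class \code{womac_scores}: list with elements
#'   \code{pain}, \code{stiffness}, \code{physical}, \code{total} and a
#'   named logical \code{valid}.
#' @export
scoreWomac <- function(response, min_present = 0.8,
                       total = c("mean_subscales", "sum_items")) {
  total <- match.arg(total)
  items <- as.numeric(response[womacItems()])
  if (anyNA(names(response)) || !all(womacItems() %in% names(response))) {
    stop("response must carry the 24 named WOMAC items P1..P5, S1..S2, F1..F17",
      call. = FALSE
    )
  }
  names(items) <- womacItems()
  sub <- list(
    pain = items[WOMAC_PAIN],
    stiffness = items[WOMAC_STIFFNESS],
    physical = items[WOMAC_FUNCTION]
  )
  scores <- vapply(sub, function(x) scoreSubscale(x, length(x), min_present), numeric(1))
  valid <- !is.na(scores)
  total <- if (!all(valid)) {
    NA_real_
  } else if (total == "mean_subscales") {
    mean(scores)
  } else {
    sum(vapply(sub, function(x) sum(impute_subscale(check_item_values(x))), numeric(1))) / 96 * 100
  }
  structure(
    list(
      pain = unname(scores["pain"]),
      stiffness = unname(scores["stiffness"]),
      physical = unname(scores["physical"]),
      total = total,
      valid = c(valid, total = !is.na(total))
    ),
    class = "womac_scores"
  )
}

#' @export
print.womac_scores <- function(x, ...) {
  cat("WOMAC standardized scores (0-100, 0 = best):\n")
  for (nm in c("pain", "stiffness", "physical", "total")) {
    v <- x[[nm]]
    cat(sprintf(
      "  %-9s %s\n", nm,
      if (is.na(v)) "invalid (too many missing items)" else sprintf("%5.1f", v)
    ))
  }
  invisible(x)
}

#' Read a patient cohort file
#'
#' Expects a CSV with one row per patient and timepoint, columns
#' \code{id}, \code{timepoint} (\code{baseline} / \code{six_month}),
#' the 24 item columns \code{P1..P5, S1..S2, F1..F17} (blank = missing),
#' and optionally further covariate columns, which are kept.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.  On invalid content an error of class
#'   \code{womacpr_validation_error} is raised whose \code{report} field
#'   is a data frame of (row, column, value, problem) records.
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "timepoint", womacItems())
  missing_cols <- setdiff(required, names(df))
  problems <- list()
  if (length(missing_cols)) {
    problems[[length(problems) + 1L]] <- data.frame(
      row = NA_integer_, column = missing_cols, value = NA_character_,
      problem = "missing required column", stringsAsFactors = FALSE
    )
  } else {
    bad_tp <- which(!df$timepoint %in% c("baseline", "six_month"))
    if (length(bad_tp)) {
      problems[[length(problems) + 1L]] <- data.frame(
        row = bad_tp, column = "timepoint", value = as.character(df$timepoint[bad_tp]),
        problem = "timepoint must be 'baseline' or 'six_month'", stringsAsFactors = FALSE
      )
    }
    for (col in womacItems()) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which((!is.na(df[[col]]) & df[[col]] != "" & is.na(v)) |
        (!is.na(v) & (v < 0 | v > 4 | v != round(v))))
      if (length(bad)) {
        problems[[length(problems) + 1L]] <- data.frame(
          row = bad, column = col, value = as.character(df[[col]][bad]),
          problem = "item answers must be integers in [0, 4] or blank",
          stringsAsFactors = FALSE
        )
      }
      df[[col]] <- v
    }
  }
  if (length(problems)) {
    report <- do.call(rbind, problems)
    cond <- structure(
      class = c("womacpr_validation_error", "error", "condition"),
      list(
        message = sprintf(
          "cohort file '%s' failed validation (%d problem(s)); see the 'report' field",
          path, nrow(report)
        ),
        call = sys.call(-1), report = report
      )
    )
    stop(cond)
  }
  df
}

#' Score every row of a cohort table
#'
#' @param cohort Data frame as returned by \code{\link{readCohort}}.
#' @param min_present Passed to \code{\link{scoreSubscale}}.
#' @param total Total-score convention, see \code{\link{scoreWomac}}.
#' @return Data frame with columns \code{id}, \code{timepoint},
#'   \code{pain}, \code{stiffness}, \code{physical}, \code{total},
#'   \code{valid}.
#' @export
scoreCohort <- function(cohort, min_present = 0.8,
                        total = c("mean_subscales", "sum_items")) {
  total <- match.arg(total)
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    s <- scoreWomac(unlist(cohort[i, womacItems()]), min_present = min_present, total = total)
    data.frame(
      id = cohort$id[i], timepoint = cohort$timepoint[i],
      pain = s$pain, stiffness = s$stiffness, physical = s$physical,
      total = s$total, valid = unname(s$valid["total"]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
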