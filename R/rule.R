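# Sequential question-based prediction rules: the clinical, flattened form
# of a classification tree.  Each question names one item and routes every
# answer level 0..4 either to a later question or to a terminal class.

RULE_CLASSES <- c("at_risk", "not_at_risk")

#' Construct a sequential prediction rule
#'
#' A rule is an ordered list of questions.  Each question holds an item
#' identifier and a branch map assigning every answer level \code{0..4}
#' (none / mild / moderate / severe / extreme) an action: \code{"q<k>"}
#' (continue with question k, k strictly greater than the current index,
#' so every answer pattern terminates) or a terminal class
#' \code{"at_risk"} / \code{"not_at_risk"}.
#'
#' @param questions List of \code{list(item = , branches = )} entries;
#'   \code{branches} is a named vector or list with names \code{"0".."4"}.
#' @param name Optional rule name.
#' @param note Optional free-text annotation (e.g. provenance).
#' @return Object of class \code{prediction_rule}.
#' @export
predictionRule <- function(questions, name = NULL, note = NULL) {
  if (!length(questions)) stop("a rule needs at least one question", call. = FALSE)
  for (k in seq_along(questions)) {
    q <- questions[[k]]
    if (is.null(q$item) || !is.character(q$item)) {
      stop(sprintf("question %d lacks an item identifier", k), call. = FALSE)
    }
    br <- unlist(q$branches)
    if (!identical(sort(names(br)), as.character(0:4))) {
      stop(sprintf(
        "question %d must map every answer level 0..4", k
      ), call. = FALSE)
    }
    for (lev in as.character(0:4)) {
      a <- br[[lev]]
      if (a %in% RULE_CLASSES) next
      if (grepl("^q[0-9]+$", a)) {
        target <- as.integer(sub("^q", "", a))
        if (target <= k || target > length(questions)) {
          stop(sprintf(
            "question %d, level %s: jump '%s' must point to a later question",
            k, lev, a
          ), call. = FALSE)
        }
      } else {
        stop(sprintf(
          "question %d, level %s: unknown action '%s'", k, lev, a
        ), call. = FALSE)
      }
    }
    questions[[k]]$branches <- as.list(br[as.character(0:4)])
  }
  structure(
    list(questions = questions, name = name, note = note),
    class = "prediction_rule"
  )
}

#' Number of questions in a rule
#' @param rule A \code{prediction_rule}.
#' @return Integer count.
#' @export
nQuestions <- function(rule) length(rule$questions)

#' Distinct items a rule asks about
#'
#' An item may be asked about more than once (at different thresholds), so
#' this can be smaller than \code{\link{nQuestions}}.
#'
#' @param rule A \code{prediction_rule}.
#' @return Sorted character vector of distinct item identifiers.
#' @export
ruleItems <- function(rule) {
  sort(unique(vapply(rule$questions, `[[`, character(1), "item")))
}

#' Flatten a classification tree into a sequential rule
#'
#' Internal nodes become questions in preorder; answers \code{<= t} follow
#' the left child, answers \code{> t} the right child; leaves become
#' terminal classes.  Applying the flattened rule reproduces
#' \code{\link[=predict.womac_tree]{predict}} on the source tree for every
#' possible record.
#'
#' @param tree A \code{womac_tree} with labelled leaves.
#' @param name Optional rule name.
#' @return A \code{prediction_rule}.
#' @export
flattenTree <- function(tree, name = NULL) {
  if (is.null(tree$root$class)) stop("tree has unlabelled leaves", call. = FALSE)
  if (is.null(tree$root$split)) {
    # single-leaf tree: one vacuous question on any predictor, all levels
    # routed straight to the majority class
    item <- tree$predictors[1]
    br <- as.list(setNames(rep(tree$root$class, 5), as.character(0:4)))
    return(predictionRule(list(list(item = item, branches = br)), name = name))
  }
  # preorder numbering of internal nodes
  questions <- list()
  number <- function(node) {
    if (is.null(node$split)) {
      return(node$class)
    }
    k <- length(questions) + 1L
    questions[[k]] <<- list(item = node$split$predictor, branches = NULL, threshold = node$split$threshold)
    left <- number(node$left)
    right <- number(node$right)
    questions[[k]]$targets <<- list(left = left, right = right)
    paste0("q", k)
  }
  number(tree$root)
  qs <- lapply(questions, function(q) {
    t <- q$threshold
    acts <- c(
      rep(q$targets$left, t + 1),
      rep(q$targets$right, 4 - t)
    )
    list(item = q$item, branches = as.list(setNames(acts, as.character(0:4))))
  })
  predictionRule(qs, name = name)
}

#' Apply a prediction rule to patient answers
#'
#' Walks the sequential questions for each row and returns the terminal
#' class.  Every item a question tests must be present; there are no
#' surrogate routes.
#'
#' @param rule A \code{prediction_rule}.
#' @param data Data frame (or single named vector) holding the questioned
#'   item columns with integer answers 0-4.
#' @return Factor with levels \code{not_at_risk}, \code{at_risk}.
#' @export
applyRule <- function(rule, data) {
  if (!is.data.frame(data)) data <- as.data.frame(as.list(data))
  classify <- function(i) {
    k <- 1L
    repeat {
      q <- rule$questions[[k]]
      v <- data[[q$item]][i]
      if (is.null(v) || is.na(v)) {
        stop(sprintf(
          "row %d cannot be classified: questioned item '%s' is missing",
          i, q$item
        ), call. = FALSE)
      }
      if (!v %in% 0:4) {
        stop(sprintf(
          "row %d: item '%s' answer %s outside the 0..4 levels", i, q$item, v
        ), call. = FALSE)
      }
      a <- q$branches[[as.character(v)]]
      if (a %in% RULE_CLASSES) {
        return(a)
      }
      k <- as.integer(sub("^q", "", a))
    }
  }
  out <- vapply(seq_len(nrow(data)), classify, character(1))
  factor(out, levels = c("not_at_risk", "at_risk"))
}

#' Select the final rule under a sensitivity-first policy
#'
#' Mirrors the standard derivation policy for screening rules: discard
#' candidates whose specificity is below an acceptability floor, then pick
#' the candidate with the highest sensitivity; break ties by the fewest
#' questions, then the fewest distinct items, then input order.
#'
#' @param candidates List of \code{list(rule = , report = )} entries, where
#'   \code{report} is a \code{\link{validityReport}} (or any list exposing
#'   \code{sensitivity} and \code{specificity} point estimates).
#' @param min_specificity Specificity floor (default 0.70).
#' @return The selected \code{prediction_rule}, with the winning candidate
#'   index in attribute \code{"candidate"}.
#' @export
selectRule <- function(candidates, min_specificity = 0.70) {
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  se <- vapply(candidates, function(c) metric_estimate(c$report, "sensitivity"), numeric(1))
  sp <- vapply(candidates, function(c) metric_estimate(c$report, "specificity"), numeric(1))
  keep <- which(!is.na(sp) & sp >= min_specificity)
  if (!length(keep)) {
    stop(sprintf(
      "no candidate reaches the specificity floor %.2f (best: %.2f); consider lowering the floor",
      min_specificity, max(sp, na.rm = TRUE)
    ), call. = FALSE)
  }
  nq <- vapply(candidates, function(c) nQuestions(c$rule), integer(1))
  ni <- vapply(candidates, function(c) length(ruleItems(c$rule)), integer(1))
  ord <- keep[order(-se[keep], nq[keep], ni[keep], keep)]
  winner <- ord[1]
  structure(candidates[[winner]]$rule, candidate = winner)
}

#' @export
print.prediction_rule <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.prediction_rule <- function(x, ...) {
  labels <- womacItemLabels()
  lev_names <- c("none", "mild", "moderate", "severe", "extreme")
  out <- sprintf(
    "Sequential prediction rule%s (%d questions, %d distinct items)",
    if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
    nQuestions(x), length(ruleItems(x))
  )
  if (!is.null(x$note)) out <- c(out, paste0("  note: ", x$note))
  for (k in seq_along(x$questions)) {
    q <- x$questions[[k]]
    lab <- if (q$item %in% names(labels)) labels[[q$item]] else q$item
    out <- c(out, sprintf("  Q%d. %s [%s]?", k, lab, q$item))
    # group consecutive levels sharing an action
    acts <- unlist(q$branches)
    runs <- rle(unname(acts))
    pos <- cumsum(c(0, runs$lengths))
    for (r in seq_along(runs$values)) {
      lv <- (pos[r]):(pos[r + 1] - 1)
      rng <- if (length(lv) == 1) lev_names[lv + 1] else {
        paste(lev_names[lv[1] + 1], "-", lev_names[lv[length(lv)] + 1])
      }
      act <- runs$values[r]
      act_txt <- switch(act,
        at_risk = "AT RISK",
        not_at_risk = "not at risk",
        paste0("go to Q", sub("^q", "", act))
      )
      out <- c(out, sprintf("      %-20s -> %s", rng, act_txt))
    }
  }
  out
}

#' Serialize / deserialize a rule as JSON
#'
#' Schema: \code{\{name, note, questions: [\{item, branches\}], classes\}}.
#'
#' @param rule A \code{prediction_rule}.
#' @param path File path.
#' @return \code{writeRule}: invisibly, the path. \code{readRule}: the rule.
#' @export
writeRule <- function(rule, path) {
  doc <- list(
    format = "womacpr_rule", version = 1L,
    name = rule$name, note = rule$note,
    questions = lapply(rule$questions, function(q) {
      list(item = q$item, branches = q$branches)
    }),
    classes = as.list(RULE_CLASSES)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRule
#' @export
readRule <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "womacpr_rule")) {
    stop("not a womacpr rule file", call. = FALSE)
  }
  predictionRule(
    lapply(doc$questions, function(q) {
      list(item = q$item, branches = lapply(q$branches, as.character))
    }),
    name = doc$name, note = doc$note
  )
}

#' The bundled five-item default rule
#'
#' A sequential rule over the five WOMAC items reported as the best
#' preoperative predictors of poor six-month outcome: taking off socks
#' (F11), getting on/off the toilet (F15, asked at two thresholds),
#' morning stiffness after first wakening (S1), rising from bed (F10) and
#' light domestic duties (F17).  The published figures specifying the
#' exact branch thresholds are not reproducible from text, so the bundled
#' thresholds are a synthetic stand-in consistent with the published
#' narrative (a mild-difficulty toilet branch toward at-risk early, a
#' severe-difficulty branch on the same item toward not-at-risk later);
#' they are calibrated to, and shipped with, this package's synthetic
#' cohort generator, and are not the authors' rule.
#'
#' @return A \code{prediction_rule}.
#' @export
defaultRule <- function() {
  path <- system.file("extdata", "default_rule_synthetic.json", package = "womacpr")
  if (path == "") stop("bundled rule file not found", call. = FALSE)
  readRule(path)
}
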