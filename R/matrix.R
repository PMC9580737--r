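#' Build a single threshold rule for a scoring matrix
#'
#' A rule awards `points` when its predicate holds for the observation's value
#' in `category`. Predicates mirror the cells of published scoring tables:
#' strict `lt`/`gt`, an inclusive `range`, and `eq0` (presence/absence rules
#' such as "0 mature epithelial cells = 1"). Ties at a strict threshold score
#' nothing, and `eq0` fires only on exact zero — averaged real-valued inputs
#' must truly be zero, because the underlying rule scores per-field
#' presence/absence.
#'
#' @param category Observation count category the rule reads, or the derived
#'   category `"gn_rods_combined"` (short + long Gram-negative rods, computed
#'   on the fly when a matrix references it).
#' @param op One of `"lt"`, `"gt"`, `"range"`, `"eq0"`.
#' @param threshold Finite threshold for `lt`/`gt`.
#' @param lo,hi Inclusive bounds for `range` (`lo <= hi`).
#' @param points Non-negative integer awarded when the predicate holds. Zero
#'   is legal (a published matrix carries a zero-weighted cell verbatim).
#'
#' @return A `category_rule` object.
#' @examples
#' category_rule("immune_cells", "gt", threshold = 1, points = 3)
#' category_rule("gp_diplococci", "range", lo = 0, hi = 1, points = 1)
#' @export
category_rule <- function(category, op = c("lt", "gt", "range", "eq0"),
                          threshold = NULL, lo = NULL, hi = NULL, points = 1) {
  op <- match.arg(op)
  known <- c(count_categories(), "gn_rods_combined",
             "mucus_grade", "scant_bacteria")
  if (!is.character(category) || length(category) != 1 ||
      !category %in% known) {
    abort(sprintf(
      "`category` must be one of: %s.", paste(known, collapse = ", ")
    ))
  }
  if (!is.numeric(points) || length(points) != 1 || points < 0 ||
      points != as.integer(points)) {
    abort("`points` must be a single non-negative integer.")
  }
  if (op %in% c("lt", "gt")) {
    if (is.null(threshold) || !is.finite(threshold)) {
      abort(sprintf("op `%s` needs a finite `threshold`.", op))
    }
  } else if (op == "range") {
    if (is.null(lo) || is.null(hi) || !is.finite(lo) || !is.finite(hi)) {
      abort("op `range` needs finite `lo` and `hi`.")
    }
    if (lo > hi) abort("`range` rule needs lo <= hi.")
  }
  structure(
    list(category = category, op = op,
         threshold = if (op %in% c("lt", "gt")) as.numeric(threshold),
         lo = if (op == "range") as.numeric(lo),
         hi = if (op == "range") as.numeric(hi),
         points = as.integer(points)),
    class = "category_rule"
  )
}

rule_predicate <- function(rule, values) {
  switch(rule$op,
    lt = values < rule$threshold,
    gt = values > rule$threshold,
    range = values >= rule$lo & values <= rule$hi,
    eq0 = values == 0
  )
}

rule_label <- function(rule) {
  pred <- switch(rule$op,
    lt = paste0("<", rule$threshold),
    gt = paste0(">", rule$threshold),
    range = paste0(rule$lo, "-", rule$hi),
    eq0 = "0"
  )
  sprintf("%s %s = %d", rule$category, pred, rule$points)
}

#' Fixed score cut-off policy
#'
#' @param value Cut-off score.
#' @param orientation `"ge"` ("score >= value is inflamed", the subsample A
#'   convention) or `"gt"` ("score > value is abnormal", the Nugent-style
#'   convention). Both appear in the field; neither is canonical.
#' @return A cut-off policy usable in [scoring_matrix()] / [call_inflamed()].
#' @export
cutoff_fixed <- function(value, orientation = c("ge", "gt")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    abort("`value` must be a single finite number.")
  }
  structure(list(type = "fixed", value = as.numeric(value),
                 orientation = orientation),
            class = "score_cutoff")
}

#' Youden-derived cut-off policy (resolved from data during evaluation)
#' @return A cut-off policy usable in [scoring_matrix()].
#' @export
cutoff_youden <- function() {
  structure(list(type = "youden"), class = "score_cutoff")
}

#' Assemble a Gram-stain scoring matrix
#'
#' A scoring matrix is a named set of threshold rules over morphotype and
#' host-cell categories; an image's score is the sum of points over rules
#' whose predicate holds, so the maximum possible score is the sum of points.
#'
#' @param matrix_id Name of the matrix (e.g. `"final_reduced"` or a
#'   user-defined id).
#' @param rules List of [category_rule()] objects with unique categories.
#' @param cutoff A [cutoff_fixed()] or [cutoff_youden()] policy (may be
#'   `NULL`; [call_inflamed()] then requires an explicit cut-off).
#' @return A `scoring_matrix` object.
#' @examples
#' m <- scoring_matrix("demo", list(
#'   category_rule("immune_cells", "gt", threshold = 1, points = 3),
#'   category_rule("mature_ec", "eq0", points = 1)
#' ), cutoff = cutoff_fixed(2))
#' max_possible_score(m)
#' @export
scoring_matrix <- function(matrix_id, rules = list(), cutoff = NULL) {
  if (!is.character(matrix_id) || length(matrix_id) != 1 ||
      !nzchar(matrix_id)) {
    abort("`matrix_id` must be a non-empty string.")
  }
  if (inherits(rules, "category_rule")) rules <- list(rules)
  ok <- vapply(rules, inherits, logical(1), what = "category_rule")
  if (!all(ok)) abort("`rules` must be a list of category_rule objects.")
  cats <- vapply(rules, `[[`, character(1), "category")
  if (anyDuplicated(cats)) {
    abort(sprintf("duplicate rule categories: %s",
                  paste(unique(cats[duplicated(cats)]), collapse = ", ")))
  }
  if (!is.null(cutoff) && !inherits(cutoff, "score_cutoff")) {
    abort("`cutoff` must come from cutoff_fixed() or cutoff_youden().")
  }
  structure(list(matrix_id = matrix_id, rules = rules, cutoff = cutoff),
            class = "scoring_matrix")
}

#' Maximum possible total score of a matrix
#'
#' The sum of points over all rules (an empty matrix scores 0).
#'
#' @param matrix A [scoring_matrix()].
#' @return Non-negative integer.
#' @examples
#' max_possible_score(builtin_matrix("v2.1")) # 10
#' max_possible_score(builtin_matrix("final_reduced")) # 7
#' @export
max_possible_score <- function(matrix) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  if (length(matrix$rules) == 0) return(0L)
  sum(vapply(matrix$rules, `[[`, integer(1), "points"))
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("<scoring_matrix> %s (max score %d)\n",
              x$matrix_id, max_possible_score(x)))
  for (r in x$rules) cat("  ", rule_label(r), "\n", sep = "")
  if (is.null(x$cutoff)) {
    cat("  cutoff: none\n")
  } else if (x$cutoff$type == "youden") {
    cat("  cutoff: youden (resolve from data)\n")
  } else {
    cat(sprintf("  cutoff: score %s %s => inflamed\n",
                if (x$cutoff$orientation == "ge") ">=" else ">",
                format(x$cutoff$value)))
  }
  invisible(x)
}

#' List the packaged scoring matrices
#'
#' Eight published matrices ship with the package: the p-value-weighted
#' first pass `v1.0`, the count-based refinements `v2.1`, `v2.2`, `v3.1`,
#' `v4` and `v2-c`, the score-based `vSubC` expanded system, and the
#' `final_reduced` four-category system (Gram-positive diplococci,
#' combined Gram-negative rods, immune cells, mature epithelial cells).
#'
#' @return Character vector of matrix ids.
#' @export
builtin_matrix_ids <- function() {
  c("v1.0", "v2.1", "v2.2", "v3.1", "v4", "v2-c", "vSubC", "final_reduced")
}

#' Load a packaged scoring matrix by id
#'
#' @param matrix_id One of [builtin_matrix_ids()].
#' @return A [scoring_matrix()].
#' @examples
#' builtin_matrix("final_reduced")
#' @export
builtin_matrix <- function(matrix_id) {
  ids <- builtin_matrix_ids()
  if (!is.character(matrix_id) || length(matrix_id) != 1 ||
      !matrix_id %in% ids) {
    abort(sprintf("unknown matrix id %s; available: %s",
                  deparse(matrix_id), paste(ids, collapse = ", ")))
  }
  fname <- paste0(gsub("[^A-Za-z0-9._-]", "_", matrix_id), ".yaml")
  path <- system.file("extdata", "matrices", fname, package = "gramscore")
  if (!nzchar(path)) abort(sprintf("packaged config for %s not found", matrix_id))
  read_matrix_config(path)
}

#' Read a scoring-matrix config file
#'
#' Configs are YAML with fields `matrix_id`, `cutoff` (either `youden` or a
#' mapping `{value, orientation}`), and `rules`, one mapping per rule with
#' `category`, `op` (`lt`, `gt`, `range`, `eq0`), `threshold` or `lo`/`hi`,
#' and `points`.
#'
#' @param path File path.
#' @return A [scoring_matrix()].
#' @export
read_matrix_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$matrix_id)) abort(sprintf("%s: missing matrix_id", path))
  rules <- lapply(cfg$rules, function(r) {
    category_rule(r$category, r$op, threshold = r$threshold,
                  lo = r$lo, hi = r$hi, points = r$points %||% 1)
  })
  cutoff <- NULL
  if (!is.null(cfg$cutoff)) {
    if (identical(cfg$cutoff, "youden")) {
      cutoff <- cutoff_youden()
    } else {
      cutoff <- cutoff_fixed(cfg$cutoff$value,
                             cfg$cutoff$orientation %||% "ge")
    }
  }
  scoring_matrix(cfg$matrix_id, rules, cutoff)
}

#' Write a scoring matrix to a config file
#'
#' @param matrix A [scoring_matrix()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_matrix_config <- function(matrix, path) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  cfg <- list(
    matrix_id = matrix$matrix_id,
    cutoff = if (is.null(matrix$cutoff)) NULL
             else if (matrix$cutoff$type == "youden") "youden"
             else list(value = matrix$cutoff$value,
                       orientation = matrix$cutoff$orientation),
    rules = lapply(matrix$rules, function(r) {
      out <- list(category = r$category, op = r$op, points = r$points)
      if (!is.null(r$threshold)) out$threshold <- r$threshold
      if (!is.null(r$lo)) { out$lo <- r$lo; out$hi <- r$hi }
      out
    })
  )
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}
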