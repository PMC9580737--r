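# Cytokine-based inflammation labeling. ELISA optical densities (ODs) are
# categorized low/high (or low/med/high) against within-cohort percentile
# splits and combined by k-of-n positivity rules into a binary
# inflamed/normal reference label.

#' Cytokine names accepted in panels
#'
#' IL-6 and IL-17A are accepted in input but used by no built-in model:
#' they are rarely detected in ovine vaginal fluid. The four model
#' cytokines are TNF-alpha, IL-8, IL-1beta and CXCL10.
#'
#' @param model_only If `TRUE`, only the four cytokines the built-in models
#'   use.
#' @return Character vector.
#' @export
cytokine_names <- function(model_only = FALSE) {
  if (model_only) c("TNFA", "IL8", "IL1B", "CXCL10")
  else c("IL1B", "IL6", "IL8", "IL17A", "CXCL10", "TNFA")
}

#' Built-in and custom inflammation models
#'
#' An inflammation model turns categorized cytokine ODs into a binary label:
#' a sample is inflamed when at least `n_required` of the model's cytokines
#' are "positive". Built-ins:
#' \describe{
#'   \item{Infl1}{binary low/high; 3 of 4 high (TNFA, IL8, IL1B, CXCL10).
#'     The recommended standard.}
#'   \item{Infl1_tertile}{the initial tertile variant of Infl1: 3 of 4 in
#'     the medium or high tertile.}
#'   \item{Infl2}{tertile; 2 of 4 high.}
#'   \item{Infl3}{tertile; IL-8 and IL-1beta only, 1 medium-or-high.}
#'   \item{Infl4}{binary; IL-8 and IL-1beta only, 1 high.}
#' }
#'
#' @param model_id A built-in id above, or a new id when the other
#'   arguments are supplied.
#' @param grouping `"binary"` or `"tertile"` OD categorization.
#' @param cytokines Cytokine subset the model reads.
#' @param n_required Number of positive cytokines required for "inflamed".
#' @param positive Which categories count as positive: `"high"` or
#'   `"med_or_high"` (tertile grouping only).
#' @return An `inflammation_model` object.
#' @examples
#' inflammation_model("Infl1")
#' inflammation_model("strict", "binary", c("IL8", "IL1B", "TNFA"), 3)
#' @export
inflammation_model <- function(model_id, grouping = NULL, cytokines = NULL,
                               n_required = NULL,
                               positive = c("high", "med_or_high")) {
  builtins <- list(
    Infl1 = list(grouping = "binary",
                 cytokines = cytokine_names(TRUE), n_required = 3,
                 positive = "high"),
    Infl1_tertile = list(grouping = "tertile",
                         cytokines = cytokine_names(TRUE), n_required = 3,
                         positive = "med_or_high"),
    Infl2 = list(grouping = "tertile",
                 cytokines = cytokine_names(TRUE), n_required = 2,
                 positive = "high"),
    Infl3 = list(grouping = "tertile",
                 cytokines = c("IL8", "IL1B"), n_required = 1,
                 positive = "med_or_high"),
    Infl4 = list(grouping = "binary",
                 cytokines = c("IL8", "IL1B"), n_required = 1,
                 positive = "high")
  )
  if (model_id %in% names(builtins) && is.null(grouping)) {
    spec <- builtins[[model_id]]
  } else {
    if (is.null(grouping) || is.null(cytokines) || is.null(n_required)) {
      abort(sprintf(
        "unknown built-in model %s; custom models need grouping, cytokines and n_required. Built-ins: %s",
        deparse(model_id), paste(names(builtins), collapse = ", ")
      ))
    }
    grouping <- match.arg(grouping, c("binary", "tertile"))
    positive <- match.arg(positive)
    if (grouping == "binary" && positive == "med_or_high") {
      abort("`med_or_high` positivity needs tertile grouping.")
    }
    if (!all(cytokines %in% cytokine_names())) {
      abort(sprintf("unknown cytokine(s): %s",
                    paste(setdiff(cytokines, cytokine_names()),
                          collapse = ", ")))
    }
    if (n_required < 1 || n_required > length(cytokines)) {
      abort("`n_required` must be between 1 and the number of cytokines.")
    }
    spec <- list(grouping = grouping, cytokines = cytokines,
                 n_required = as.integer(n_required), positive = positive)
  }
  structure(c(list(model_id = model_id), spec), class = "inflammation_model")
}

#' @export
print.inflammation_model <- function(x, ...) {
  cat(sprintf("<inflammation_model> %s: %s grouping; %d of %d %s (%s)\n",
              x$model_id, x$grouping, x$n_required, length(x$cytokines),
              if (x$positive == "high") "high" else "medium-or-high",
              paste(x$cytokines, collapse = ", ")))
  invisible(x)
}

#' Compute OD categorization thresholds within a cohort
#'
#' Binary grouping splits each cytokine at the cohort's 50th percentile
#' (or mean, an option mirroring the looser "above the mean" description
#' sometimes used for the same rule); tertile grouping uses the empirical
#' 33.33rd/66.67th percentiles. Values exactly equal to a split fall in the
#' lower category. Thresholds are always derived from the cohort being
#' labeled unless a persisted thresholds object is reused.
#'
#' @param panels Data frame with `sample_id` and one numeric OD column per
#'   cytokine.
#' @param grouping `"binary"` or `"tertile"`.
#' @param split_statistic `"median"` (the operational default) or `"mean"`
#'   (binary grouping only).
#' @param cytokines Cytokines to threshold; defaults to the model cytokines
#'   present in `panels`.
#' @return A `cytokine_thresholds` object: tibble with `cytokine`,
#'   `split_1`, `split_2` (`NA` for binary) plus grouping metadata.
#' @examples
#' p <- tibble::tibble(sample_id = as.character(1:10), IL8 = 1:10)
#' cytokine_thresholds(p, "binary", cytokines = "IL8")
#' @export
cytokine_thresholds <- function(panels,
                                grouping = c("binary", "tertile"),
                                split_statistic = c("median", "mean"),
                                cytokines = NULL) {
  grouping <- match.arg(grouping)
  split_statistic <- match.arg(split_statistic)
  panels <- as_tibble(panels)
  if (nrow(panels) < 2) abort("need at least 2 panels to derive thresholds.")
  cytokines <- cytokines %||%
    intersect(cytokine_names(TRUE), names(panels))
  if (length(cytokines) == 0) abort("no model cytokine columns found.")
  if (grouping == "tertile" && split_statistic == "mean") {
    abort("mean split statistic applies to binary grouping only.")
  }
  rows <- purrr::map(cytokines, function(cy) {
    v <- panels[[cy]]
    if (is.null(v)) abort(sprintf("missing OD column `%s`.", cy))
    v <- v[!is.na(v)]
    if (length(v) < 2) abort(sprintf("cytokine %s has < 2 OD values.", cy))
    if (any(v < 0)) abort(sprintf("negative OD values for %s.", cy))
    if (diff(range(v)) == 0) {
      warn(sprintf(
        "cytokine %s has constant OD; degenerate threshold, all samples 'low'.",
        cy
      ))
    }
    if (grouping == "binary") {
      s1 <- if (split_statistic == "median") unname(quantile(v, 0.5))
            else mean(v)
      tibble(cytokine = cy, split_1 = s1, split_2 = NA_real_)
    } else {
      qs <- unname(quantile(v, c(1 / 3, 2 / 3)))
      tibble(cytokine = cy, split_1 = qs[1], split_2 = qs[2])
    }
  })
  out <- bind_rows(rows)
  structure(out, class = c("cytokine_thresholds", class(out)),
            grouping = grouping, split_statistic = split_statistic,
            n_panels = nrow(panels))
}

# Categorize OD values against thresholds: 1 = low, 2 = med, 3 = high
# (binary: 1 = low, 3 = high). Ties go to the lower category.
categorize_od <- function(values, split_1, split_2) {
  if (is.na(split_2)) {
    ifelse(values > split_1, 3L, 1L)
  } else {
    ifelse(values > split_2, 3L, ifelse(values > split_1, 2L, 1L))
  }
}

#' Label samples inflamed/normal from cytokine panels
#'
#' Categorizes each model cytokine against within-cohort thresholds and
#' applies the model's k-of-n positivity rule. Deterministic given
#' (panels, model, split statistic).
#'
#' @param panels Data frame with `sample_id` and OD columns.
#' @param model An [inflammation_model()] or built-in model id
#'   (default `"Infl1"`).
#' @param thresholds Optional persisted [cytokine_thresholds()] (to label
#'   new samples against an earlier cohort); must match the model's
#'   grouping. Default: recomputed from `panels`.
#' @param split_statistic Passed to [cytokine_thresholds()] when thresholds
#'   are recomputed.
#' @return Tibble with `sample_id`, `n_positive`, and logical `inflamed`.
#' @examples
#' p <- tibble::tibble(
#'   sample_id = as.character(1:4),
#'   TNFA = c(1, 1, 5, 6), IL8 = c(1, 2, 5, 6),
#'   IL1B = c(1, 2, 5, 6), CXCL10 = c(1, 2, 5, 6)
#' )
#' label_inflammation(p, "Infl1")
#' @export
label_inflammation <- function(panels, model = "Infl1", thresholds = NULL,
                               split_statistic = c("median", "mean")) {
  if (is.character(model)) model <- inflammation_model(model)
  stopifnot(inherits(model, "inflammation_model"))
  panels <- as_tibble(panels)
  missing_cy <- setdiff(model$cytokines, names(panels))
  if (length(missing_cy) > 0) {
    abort(sprintf("panels lack model cytokine(s): %s",
                  paste(missing_cy, collapse = ", ")))
  }
  for (cy in model$cytokines) {
    if (anyNA(panels[[cy]])) {
      abort(sprintf(
        "missing OD for model cytokine %s (sample %s).", cy,
        panels$sample_id[which(is.na(panels[[cy]]))[1]]
      ))
    }
  }
  if (is.null(thresholds)) {
    thresholds <- cytokine_thresholds(
      panels, grouping = model$grouping,
      split_statistic = match.arg(split_statistic),
      cytokines = model$cytokines
    )
  } else {
    if (!inherits(thresholds, "cytokine_thresholds")) {
      abort("`thresholds` must come from cytokine_thresholds().")
    }
    if (!identical(attr(thresholds, "grouping"), model$grouping)) {
      abort(sprintf("thresholds grouping (%s) does not match model grouping (%s).",
                    attr(thresholds, "grouping"), model$grouping))
    }
  }
  min_cat <- if (model$positive == "high") 3L else 2L
  pos <- matrix(FALSE, nrow = nrow(panels), ncol = length(model$cytokines))
  for (j in seq_along(model$cytokines)) {
    cy <- model$cytokines[j]
    th <- thresholds[thresholds$cytokine == cy, , drop = FALSE]
    if (nrow(th) != 1) {
      abort(sprintf("thresholds lack cytokine %s.", cy))
    }
    cat_j <- categorize_od(panels[[cy]], th$split_1, th$split_2)
    pos[, j] <- cat_j >= min_cat
  }
  n_positive <- as.integer(rowSums(pos))
  tibble(
    sample_id = panels$sample_id,
    n_positive = n_positive,
    inflamed = n_positive >= model$n_required
  )
}

#' Persist and reload categorization thresholds
#'
#' Thresholds are stored as a small YAML file so that new samples can be
#' labeled against an earlier cohort's splits.
#'
#' @param thresholds A [cytokine_thresholds()] object.
#' @param path File path.
#' @return `write_thresholds()`: `path`, invisibly. `read_thresholds()`:
#'   a `cytokine_thresholds` object.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "cytokine_thresholds"))
  yaml::write_yaml(list(
    grouping = attr(thresholds, "grouping"),
    split_statistic = attr(thresholds, "split_statistic"),
    n_panels = attr(thresholds, "n_panels"),
    thresholds = purrr::pmap(
      list(thresholds$cytokine, thresholds$split_1, thresholds$split_2),
      function(cy, s1, s2) {
        out <- list(cytokine = cy, split_1 = s1)
        if (!is.na(s2)) out$split_2 <- s2
        out
      }
    )
  ), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  tbl <- bind_rows(lapply(cfg$thresholds, function(x) {
    tibble(cytokine = x$cytokine, split_1 = x$split_1,
           split_2 = x$split_2 %||% NA_real_)
  }))
  structure(tbl, class = c("cytokine_thresholds", class(tbl)),
            grouping = cfg$grouping, split_statistic = cfg$split_statistic,
            n_panels = cfg$n_panels)
}
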