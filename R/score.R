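#' Score Gram-stain field observations with a scoring matrix
#'
#' Applies each rule of `matrix` to each quality-`ok` observation and sums
#' the points of the rules whose predicate holds. The derived category
#' `gn_rods_combined` (short + long Gram-negative rods) is computed on the
#' fly when the matrix references it.
#'
#' @param observations Data frame of per-field observations; must contain
#'   `image_id`, `sample_id`, `quality` and every count category the matrix
#'   references (see [read_observations()] for the full column set).
#' @param matrix A [scoring_matrix()].
#' @param drop_excluded If `TRUE` (default) rows with `quality != "ok"` are
#'   dropped with a message; if `FALSE` their presence is an error. Only
#'   quality-`ok` fields are scoreable.
#' @return Tibble with `image_id`, `sample_id`, `matrix_id` and integer
#'   `score`; one row per scoreable observation. Scores are bounded by
#'   `[0, max_possible_score(matrix)]`.
#' @examples
#' obs <- tibble::tibble(
#'   image_id = "img1", sample_id = "s1",
#'   gp_diplococci = 0, gn_rods_short = 0, gn_rods_long = 0,
#'   immune_cells = 0, mature_ec = 0, quality = "ok"
#' )
#' score_images(obs, builtin_matrix("final_reduced"))
#' @export
score_images <- function(observations, matrix, drop_excluded = TRUE) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  obs <- as_tibble(observations)
  for (col in c("image_id", "sample_id", "quality")) {
    if (!col %in% names(obs)) abort(sprintf("missing column `%s`.", col))
  }
  bad <- obs$quality != "ok"
  if (any(bad)) {
    if (!drop_excluded) {
      abort(sprintf(
        "%d observation(s) are not quality 'ok' and cannot be scored (e.g. image %s).",
        sum(bad), obs$image_id[which(bad)[1]]
      ))
    }
    inform(sprintf("excluding %d non-'ok' quality observation(s).", sum(bad)))
    obs <- obs[!bad, , drop = FALSE]
  }
  obs <- add_derived_categories(obs)
  needed <- vapply(matrix$rules, `[[`, character(1), "category")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0) {
    abort(sprintf("observations lack categories referenced by %s: %s",
                  matrix$matrix_id, paste(missing_cols, collapse = ", ")))
  }
  score <- integer(nrow(obs))
  for (rule in matrix$rules) {
    v <- obs[[rule$category]]
    if (anyNA(v)) {
      abort(sprintf(
        "missing value in category `%s` for image(s): %s",
        rule$category,
        paste(head(obs$image_id[is.na(v)], 3), collapse = ", ")
      ))
    }
    if (any(v < 0)) {
      abort(sprintf("negative values in category `%s`.", rule$category))
    }
    score <- score + ifelse(rule_predicate(rule, v), rule$points, 0L)
  }
  tibble(
    image_id = obs$image_id,
    sample_id = obs$sample_id,
    matrix_id = matrix$matrix_id,
    score = as.integer(score)
  )
}

#' Per-category rule scores (points earned per category)
#'
#' Same contract as [score_images()] but returns one column per rule
#' category holding the points that rule contributed (0 when the predicate
#' does not hold). Used as the predictor table for [lr_diagnostics()].
#'
#' @inheritParams score_images
#' @return Tibble with `image_id`, `sample_id`, one integer column per rule
#'   category, and the `score` total.
#' @export
rule_scores <- function(observations, matrix, drop_excluded = TRUE) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  obs <- as_tibble(observations)
  bad <- obs$quality != "ok"
  if (any(bad)) {
    if (!drop_excluded) abort("non-'ok' quality observations present.")
    obs <- obs[!bad, , drop = FALSE]
  }
  obs <- add_derived_categories(obs)
  out <- tibble(image_id = obs$image_id, sample_id = obs$sample_id)
  for (rule in matrix$rules) {
    v <- obs[[rule$category]]
    if (is.null(v)) abort(sprintf("missing category `%s`.", rule$category))
    out[[rule$category]] <- ifelse(rule_predicate(rule, v),
                                   rule$points, 0L)
  }
  out$score <- as.integer(rowSums(out[, setdiff(names(out),
                                                c("image_id", "sample_id")),
                                      drop = FALSE]))
  out
}

#' Average image scores into per-sample scores
#'
#' Real-world use scores 5–10 fields per slide and averages them into a
#' single per-sample score. Samples with zero scoreable images yield an
#' explicit `NA` score, never zero.
#'
#' @param image_scores Tibble from [score_images()] (needs `sample_id` and
#'   `score`).
#' @param samples Optional character vector of sample ids that must appear
#'   in the output; samples without any scoreable image get `n_images = 0`
#'   and `score = NA`.
#' @return Tibble with `sample_id`, `n_images`, and mean `score`.
#' @examples
#' score_samples(tibble::tibble(sample_id = c("a", "a"), score = c(4, 6)))
#' @export
score_samples <- function(image_scores, samples = NULL) {
  tbl <- as_tibble(image_scores)
  if (!all(c("sample_id", "score") %in% names(tbl))) {
    abort("`image_scores` needs columns sample_id and score.")
  }
  out <- tbl |>
    group_by(.data$sample_id) |>
    summarise(n_images = dplyr::n(), score = mean(.data$score),
              .groups = "drop")
  if (!is.null(samples)) {
    missing <- setdiff(samples, out$sample_id)
    if (length(missing) > 0) {
      warn(sprintf("%d sample(s) have no scoreable images: %s",
                   length(missing),
                   paste(head(missing, 5), collapse = ", ")))
      out <- bind_rows(out, tibble(sample_id = missing, n_images = 0L,
                                   score = NA_real_))
    }
    out <- out[match(samples, out$sample_id), , drop = FALSE]
  }
  out
}

#' Call scores inflamed or normal under a fixed cut-off
#'
#' @param score Numeric vector of (image or sample) scores.
#' @param cutoff Either a [scoring_matrix()] whose cut-off policy is fixed,
#'   a [cutoff_fixed()] object, or a single number (interpreted with
#'   `orientation`). A matrix with a `youden` policy must be resolved from
#'   data first (see [youden_cutoff()] / [develop_iteration()]).
#' @param orientation Used only when `cutoff` is a bare number: `"ge"`
#'   (score >= cut-off is inflamed) or `"gt"` (score > cut-off).
#' @return Logical vector, `TRUE` = inflamed.
#' @examples
#' call_inflamed(c(5, 6), cutoff_fixed(6, "ge")) # FALSE TRUE
#' call_inflamed(5, 4, orientation = "gt")       # TRUE
#' @export
call_inflamed <- function(score, cutoff, orientation = c("ge", "gt")) {
  if (inherits(cutoff, "scoring_matrix")) {
    pol <- cutoff$cutoff
    if (is.null(pol)) {
      abort(sprintf("matrix %s has no cut-off policy.", cutoff$matrix_id))
    }
    if (pol$type == "youden") {
      abort(paste0(
        "matrix ", cutoff$matrix_id, " uses a data-derived (Youden) cut-off; ",
        "evaluate it against labeled data first (youden_cutoff() or ",
        "develop_iteration()) and pass the resolved cut-off."
      ))
    }
    cutoff <- pol
  }
  if (is.numeric(cutoff) && length(cutoff) == 1) {
    cutoff <- cutoff_fixed(cutoff, match.arg(orientation))
  }
  if (!inherits(cutoff, "score_cutoff") || cutoff$type != "fixed") {
    abort("`cutoff` must be a fixed cut-off (value + orientation).")
  }
  if (cutoff$orientation == "ge") score >= cutoff$value else score > cutoff$value
}
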