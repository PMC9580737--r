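# Iterative development/validation machinery: group summaries and Welch
# t-tests per category, p-value-banded weight assignment, concordance,
# ROC AUC by cut-off sweep, Youden cut-off, and logistic-regression sign
# diagnostics.

#' Two-sample t-test from summary statistics
#'
#' Closed-form two-sample t-test from group means, SDs and sizes, as used
#' when weighting scoring categories from published group summaries. The
#' Welch (unequal-variance) form is the default — group SDs of morphotype
#' counts are routinely unequal — with the pooled-variance Student form as
#' an option.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param variant `"welch"` (default) or `"student"`.
#' @return One-row tibble with `t`, `df`, `p_value` (two-sided). When both
#'   SDs are zero: equal means give `t = 0, p = 1`; unequal means give
#'   `p = 0` with a warning.
#' @examples
#' t_test_from_summary(8.3, 8.1, 97, 16.7, 12.3, 72)
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2.")
  if (sd1 < 0 || sd2 < 0) abort("SDs must be non-negative.")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (variant == "welch") {
    se2 <- v1 + v2
    df <- if (se2 > 0) {
      se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    } else {
      n1 + n2 - 2
    }
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (mean1 == mean2) {
      return(tibble(t = 0, df = df, p_value = 1))
    }
    warn("both SDs are zero with unequal means; p = 0.")
    return(tibble(t = sign(mean1 - mean2) * Inf, df = df, p_value = 0))
  }
  t <- (mean1 - mean2) / sqrt(se2)
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Per-category group summaries with significance tests
#'
#' Splits per-field observations by the cytokine-derived inflamed/normal
#' label and reports, per count category, the group means, sample SDs
#' (n - 1 denominator) and counts, with a two-sided two-sample t-test.
#' Fields with a missing value in a category are excluded category-wise, so
#' per-category counts can differ. No multiple-testing correction is
#' applied across the category tests (mirroring how such scoring systems
#' are developed); a note to that effect travels with the result.
#'
#' @param observations Per-field observation tibble (quality-`ok` rows are
#'   used; others are dropped).
#' @param labels Tibble with `sample_id` and `inflamed` (logical or
#'   inflamed/normal labels).
#' @param categories Count categories to summarize; defaults to all present
#'   (plus derived `gn_rods_combined`).
#' @param variant t-test variant, see [t_test_from_summary()].
#' @return Tibble with one row per category: group means/SDs/counts, `t`,
#'   `df`, `p_value`. Categories where a group has fewer than 2 values get
#'   `NA` statistics with a warning.
#' @export
summarize_groups <- function(observations, labels,
                             categories = NULL,
                             variant = c("welch", "student")) {
  variant <- match.arg(variant)
  obs <- as_tibble(observations)
  if ("quality" %in% names(obs)) obs <- obs[obs$quality == "ok", ]
  obs <- add_derived_categories(obs)
  labels <- as_tibble(labels)
  labels$inflamed <- as_inflamed(labels$inflamed)
  obs <- left_join(obs, labels[, c("sample_id", "inflamed")],
                   by = "sample_id")
  if (anyNA(obs$inflamed)) {
    abort("some observations have samples without labels.")
  }
  if (length(unique(obs$inflamed)) < 2) {
    abort("both inflamed and normal labels must be present.")
  }
  categories <- categories %||%
    intersect(c(count_categories(), "gn_rods_combined"), names(obs))
  rows <- purrr::map(categories, function(cat) {
    v <- obs[[cat]]
    vi <- v[obs$inflamed & !is.na(v)]
    vn <- v[!obs$inflamed & !is.na(v)]
    base <- tibble(
      category = cat,
      mean_inflamed = mean(vi), sd_inflamed = sd(vi),
      n_inflamed = length(vi),
      mean_normal = mean(vn), sd_normal = sd(vn),
      n_normal = length(vn)
    )
    if (length(vi) < 2 || length(vn) < 2) {
      warn(sprintf("category %s has a group with < 2 values; p omitted.",
                   cat))
      return(bind_cols(base, tibble(t = NA_real_, df = NA_real_,
                                    p_value = NA_real_)))
    }
    tt <- t_test_from_summary(base$mean_inflamed, base$sd_inflamed,
                              base$n_inflamed, base$mean_normal,
                              base$sd_normal, base$n_normal,
                              variant = variant)
    bind_cols(base, tt)
  })
  out <- bind_rows(rows)
  attr(out, "note") <-
    "p-values are unadjusted; no multiple-testing correction across categories."
  out
}

#' Assign rule weights from p-value bands
#'
#' Smaller p-values earn larger point weights. With the default bands,
#' `p < 1e-8` earns 3 points, `1e-8 <= p < 5e-4` earns 2, `5e-4 <= p <
#' alpha` earns 1, and categories at or above `alpha` are excluded
#' (0 points). The default bands reproduce the published first-pass weight
#' assignment from its printed p-values.
#'
#' @param p_values Named numeric vector (names = categories) in `[0, 1]`.
#' @param alpha Significance gate; categories with `p >= alpha` get 0.
#' @param bands Ascending band thresholds below `alpha`; a p-value below
#'   `k` of them earns `k + 1` points.
#' @return Tibble with `category`, `p_value`, `points`, sorted by
#'   ascending p-value.
#' @examples
#' assign_weights(c(immune_cells = 5.7e-10, gp_diplococci = 8.3e-4,
#'                  gn_cocci = 0.14))
#' @export
assign_weights <- function(p_values, alpha = 0.05, bands = c(1e-8, 5e-4)) {
  if (is.null(names(p_values)) || any(!nzchar(names(p_values)))) {
    abort("`p_values` must be named by category.")
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  bands <- sort(bands)
  if (any(bands >= alpha)) abort("`bands` must all lie below `alpha`.")
  pts <- ifelse(
    is.na(p_values) | p_values >= alpha, 0L,
    1L + rowSums(outer(p_values, bands, `<`))
  )
  tibble(category = names(p_values),
         p_value = unname(p_values),
         points = as.integer(pts)) |>
    arrange(.data$p_value)
}

#' Concordance between score-based calls and reference labels
#'
#' @param calls Logical (or inflamed/normal) score-based calls.
#' @param labels Reference labels of the same length.
#' @return One-row tibble with `n_concordant`, `n_discordant`, `total` and
#'   integer `percent` (round half up of `100 * n_concordant / total`).
#' @examples
#' concordance(rep(c(TRUE, FALSE), c(132, 39)), rep(TRUE, 171)) # 77%
#' @export
concordance <- function(calls, labels) {
  calls <- as_inflamed(calls, "calls")
  labels <- as_inflamed(labels, "labels")
  if (length(calls) == 0) abort("empty input.")
  if (length(calls) != length(labels)) {
    abort("`calls` and `labels` must have equal length.")
  }
  nc <- sum(calls == labels)
  total <- length(calls)
  tibble(n_concordant = nc, n_discordant = total - nc, total = total,
         percent = as.integer(round_half_up(100 * nc / total)))
}

#' ROC curve and AUC by cut-off sweep
#'
#' Sweeps every distinct score as a cut-off (orientation: higher score
#' means inflamed; a score at or above the cut-off is called inflamed) and
#' reports sensitivity/specificity per cut-off. The AUC is the area under
#' the resulting step curve with tied scores traversed diagonally, which
#' equals the Mann-Whitney probability that a random inflamed sample
#' outscores a random normal one, ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Reference labels (logical or inflamed/normal), same
#'   length; both classes must be present.
#' @return A `roc_eval` object: ROC points, `auc`, class counts. Use
#'   [tidy()] for the points, [glance()] for the summary, [autoplot()] for
#'   the curve, and [youden_cutoff()] for the optimal cut-off.
#' @examples
#' r <- roc_auc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
#' glance(r) # AUC 0.875
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_inflamed(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both inflamed and normal labels must be present.")
  }
  cutoffs <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cutoffs, function(c) sum(scores >= c & labels) / n_pos,
                 numeric(1))
  spec <- vapply(cutoffs, function(c) sum(scores < c & !labels) / n_neg,
                 numeric(1))
  points <- tibble(cutoff = cutoffs, sensitivity = sens,
                   specificity = spec)
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("<roc_eval> AUC %.3f (%d inflamed vs %d normal, %d cut-offs)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Youden-optimal score cut-off
#'
#' Returns the cut-off maximizing J = sensitivity + specificity - 1 over
#' the swept cut-offs, ties broken toward the lowest cut-off, reported with
#' the orientation "score >= cut-off means inflamed".
#'
#' @param roc A `roc_eval` from [roc_auc()], or its points tibble.
#' @return One-row tibble with `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`.
#' @examples
#' youden_cutoff(roc_auc(c(1, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE)))
#' @export
youden_cutoff <- function(roc) {
  points <- if (inherits(roc, "roc_eval")) roc$points else as_tibble(roc)
  if (nrow(points) == 0) abort("need at least one ROC point.")
  j <- points$sensitivity + points$specificity - 1
  # group floating-point-equal J values before tie-breaking: J differences
  # are multiples of 1/(n_pos * n_neg), far above rounding noise
  j_grouped <- round(j, 10)
  best <- max(j_grouped)
  idx <- which(j_grouped == best)
  idx <- idx[which.min(points$cutoff[idx])]
  tibble(cutoff = points$cutoff[idx], youden_j = j[idx],
         sensitivity = points$sensitivity[idx],
         specificity = points$specificity[idx])
}

#' Evaluate a set of scores against reference labels
#'
#' Bundles concordance, the ROC sweep, AUC and the Youden cut-off for one
#' (scores, labels) pairing — the per-iteration evaluation report of the
#' development workflow.
#'
#' @inheritParams roc_auc
#' @param cutoff Cut-off used for the concordance calls: a
#'   [cutoff_fixed()], a bare number (orientation `ge`), or `"youden"`
#'   (default) to resolve the cut-off from these data.
#' @return A `gram_eval` object; [glance()] gives the one-row summary,
#'   [tidy()] the ROC points, [autoplot()] the curve.
#' @export
evaluate_scores <- function(scores, labels, cutoff = "youden") {
  labels <- as_inflamed(labels)
  roc <- roc_auc(scores, labels)
  yj <- youden_cutoff(roc)
  resolved <- if (identical(cutoff, "youden")) {
    cutoff_fixed(yj$cutoff, "ge")
  } else if (is.numeric(cutoff)) {
    cutoff_fixed(cutoff, "ge")
  } else if (inherits(cutoff, "score_cutoff") && cutoff$type == "fixed") {
    cutoff
  } else {
    abort("`cutoff` must be 'youden', a number, or cutoff_fixed().")
  }
  keep <- !is.na(scores) & !is.na(labels)
  conc <- concordance(call_inflamed(scores[keep], resolved), labels[keep])
  structure(list(roc = roc, youden = yj, concordance = conc,
                 cutoff = resolved,
                 cutoff_source = if (identical(cutoff, "youden")) "youden"
                                 else "fixed"),
            class = "gram_eval")
}

#' @export
print.gram_eval <- function(x, ...) {
  cat(sprintf(
    "<gram_eval> AUC %.3f; Youden cut-off %g (J = %.2f); concordance %d/%d (%d%%) at cut-off %s%g\n",
    x$roc$auc, x$youden$cutoff, x$youden$youden_j,
    x$concordance$n_concordant, x$concordance$total, x$concordance$percent,
    if (x$cutoff$orientation == "ge") ">=" else ">", x$cutoff$value
  ))
  invisible(x)
}

#' Multivariate logistic-regression diagnostics for scoring categories
#'
#' Fits a multivariate logistic regression of the inflamed label on the
#' per-category rule scores and reports coefficient signs as weighting
#' guidance: a positive sign means earning that category's points pushes
#' toward "inflamed". Zero-variance categories are dropped with a notice;
#' (quasi-)complete separation is detected and flagged rather than left to
#' diverge silently. The fit is diagnostic only — the reproducible ROC is
#' computed on the total score, not on this model.
#'
#' @param predictors Per-category rule-score tibble from [rule_scores()]
#'   (id and total-score columns are ignored), or any numeric predictor
#'   tibble.
#' @param labels Labels of the same length (logical or inflamed/normal).
#' @return A `gram_lr` object; [tidy()] gives per-term estimates and signs,
#'   [glance()] the fit summary (including the separation flag).
#' @export
lr_diagnostics <- function(predictors, labels) {
  x <- as_tibble(predictors)
  x <- x[, setdiff(names(x), c("image_id", "sample_id", "score")),
         drop = FALSE]
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  if (ncol(x) < 2) abort("need at least 2 predictor categories.")
  y <- as_inflamed(labels)
  if (length(y) != nrow(x)) abort("labels length must match predictors.")
  if (length(unique(y)) < 2) abort("both labels must be present.")
  zero_var <- vapply(x, function(v) sd(v) == 0, logical(1))
  dropped <- names(x)[zero_var]
  if (length(dropped) > 0) {
    inform(sprintf("dropping zero-variance categor%s: %s",
                   if (length(dropped) > 1) "ies" else "y",
                   paste(dropped, collapse = ", ")))
    x <- x[, !zero_var, drop = FALSE]
  }
  if (ncol(x) == 0) abort("no informative predictors remain.")
  dat <- bind_cols(x, tibble(.inflamed = y))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.inflamed ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # glm can converge onto a separated solution without warning; fitted
  # probabilities numerically at 0/1 are the reliable symptom
  eps <- 1e-8
  if (any(fitted(fit) < eps) || any(fitted(fit) > 1 - eps)) {
    separation <- TRUE
  }
  cf <- summary(fit)$coefficients
  est <- unname(cf[, "Estimate"])
  tab <- tibble(
    term = rownames(cf),
    estimate = est,
    std_error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "z value"]),
    p_value = unname(cf[, "Pr(>|z|)"]),
    sign = ifelse(est > 0, "positive",
                  ifelse(est < 0, "negative", "zero"))
  )
  structure(list(fit = fit, table = tab, dropped = dropped,
                 separation = separation, n = nrow(dat)),
            class = "gram_lr")
}

#' @export
print.gram_lr <- function(x, ...) {
  cat(sprintf("<gram_lr> logistic diagnostics on %d observations%s\n",
              x$n,
              if (x$separation) " [complete separation flagged]" else ""))
  print(as.data.frame(x$table[, c("term", "estimate", "sign", "p_value")]),
        row.names = FALSE, digits = 3)
  if (length(x$dropped) > 0) {
    cat("dropped (zero variance):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run one development iteration over candidate scoring matrices
#'
#' Scores every observation under every candidate matrix, evaluates each
#' candidate at the per-image and per-sample-averaged level against the
#' cytokine-derived labels (concordance at the matrix's cut-off policy —
#' Youden policies are resolved from these data — plus ROC AUC and Youden
#' cut-off), and recommends a candidate: highest sample-level AUC, ties
#' broken toward higher concordance and then fewer rules.
#'
#' @param observations Per-field observation tibble.
#' @param labels Tibble with `sample_id` and `inflamed`.
#' @param candidates List of [scoring_matrix()] objects and/or built-in
#'   matrix ids.
#' @param levels Evaluation levels, subset of `c("image", "sample")`.
#' @return A `gram_development` object; [tidy()] gives the per-matrix
#'   per-level report, [glance()] the recommended row, [autoplot()] an AUC
#'   dot plot, `$evals` the underlying `gram_eval` objects.
#' @export
develop_iteration <- function(observations, labels, candidates,
                              levels = c("image", "sample")) {
  levels <- match.arg(levels, several.ok = TRUE)
  if (inherits(candidates, "scoring_matrix") || is.character(candidates)) {
    candidates <- as.list(candidates)
  }
  if (length(candidates) == 0) abort("need at least one candidate matrix.")
  candidates <- lapply(candidates, function(m) {
    if (is.character(m)) builtin_matrix(m) else m
  })
  labels <- as_tibble(labels)
  labels$inflamed <- as_inflamed(labels$inflamed)
  rows <- list()
  evals <- list()
  for (m in candidates) {
    img <- score_images(observations, m)
    img_lab <- left_join(img, labels[, c("sample_id", "inflamed")],
                         by = "sample_id")
    if (anyNA(img_lab$inflamed)) {
      abort(sprintf("unlabeled samples present (e.g. %s).",
                    img_lab$sample_id[which(is.na(img_lab$inflamed))[1]]))
    }
    smp <- score_samples(img)
    smp_lab <- left_join(smp, labels[, c("sample_id", "inflamed")],
                         by = "sample_id")
    for (lev in levels) {
      d <- if (lev == "image") img_lab else smp_lab
      pol <- if (!is.null(m$cutoff) && m$cutoff$type == "fixed") m$cutoff
             else "youden"
      ev <- evaluate_scores(d$score, d$inflamed, cutoff = pol)
      key <- paste(m$matrix_id, lev, sep = "/")
      evals[[key]] <- ev
      rows[[key]] <- tibble(
        matrix_id = m$matrix_id, level = lev, n = length(d$score),
        auc = ev$roc$auc,
        youden_cutoff = ev$youden$cutoff, youden_j = ev$youden$youden_j,
        cutoff_used = ev$cutoff$value,
        cutoff_source = ev$cutoff_source,
        n_concordant = ev$concordance$n_concordant,
        n_discordant = ev$concordance$n_discordant,
        percent_concordance = ev$concordance$percent,
        max_score = max_possible_score(m),
        n_rules = length(m$rules)
      )
    }
  }
  report <- bind_rows(rows)
  rec_level <- if ("sample" %in% levels) "sample" else levels[1]
  rec <- report |>
    filter(.data$level == rec_level) |>
    arrange(desc(.data$auc), desc(.data$percent_concordance),
            .data$n_rules)
  structure(list(report = report, evals = evals,
                 recommended = rec$matrix_id[1],
                 recommendation_level = rec_level),
            class = "gram_development")
}

#' @export
print.gram_development <- function(x, ...) {
  cat(sprintf("<gram_development> %d candidate(s); recommended: %s (%s level)\n",
              length(unique(x$report$matrix_id)), x$recommended,
              x$recommendation_level))
  print(as.data.frame(x$report[, c("matrix_id", "level", "n", "auc",
                                   "youden_cutoff",
                                   "percent_concordance")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}
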