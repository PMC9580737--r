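# Builders for observation rows and small labeled cohorts; all fixtures
# are constructed in code.

make_obs <- function(n = 1, ..., quality = "ok") {
  out <- tibble::tibble(
    image_id = sprintf("img%03d", seq_len(n)),
    sample_id = sprintf("s%03d", seq_len(n)),
    gp_cocci = 0, gp_rods = 0, gp_diplococci = 0, gp_pleomorphic = 0,
    gn_cocci = 0, gn_rods_short = 0, gn_rods_long = 0,
    immune_cells = 0, mature_ec = 0, intermediate_ec = 0,
    parabasal_ec = 0, mucus_grade = 0L, scant_bacteria = 0L,
    quality = quality
  )
  overrides <- list(...)
  for (name in names(overrides)) out[[name]] <- overrides[[name]]
  out
}

# Random count observations for property tests.
random_obs <- function(n, seed) {
  withr::with_seed(seed, make_obs(
    n,
    gp_cocci = rpois(n, 6), gp_rods = rpois(n, 4),
    gp_diplococci = rpois(n, 1), gp_pleomorphic = rpois(n, 1),
    gn_cocci = rpois(n, 10), gn_rods_short = rpois(n, 12),
    gn_rods_long = rpois(n, 2), immune_cells = rpois(n, 1),
    mature_ec = rpois(n, 1), intermediate_ec = rpois(n, 1),
    parabasal_ec = rpois(n, 1)
  ))
}

# Published per-category p row, as a named vector.
printed_p_row <- function() {
  s <- subsample_a_summary()
  p <- s[s$group == "inflamed", ]
  stats::setNames(p$printed_p, p$category)
}

# Brute-force Mann-Whitney AUC with ties counted 1/2: the independent
# oracle for the ROC sweep.
mw_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden sweep oracle: best J over all distinct cut-offs under
# the "score >= c is inflamed" orientation.
sweep_youden <- function(scores, labels) {
  best <- -Inf
  best_c <- NA
  for (c in sort(unique(scores))) {
    sens <- mean(scores[labels] >= c)
    spec <- mean(scores[!labels] < c)
    j <- sens + spec - 1
    if (j > best + 1e-12) {
      best <- j
      best_c <- c
    }
  }
  list(cutoff = best_c, j = best)
}
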