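# Frozen oracle values computed independently (closed form via
# scipy.stats.ttest_ind_from_stats) from the published group summaries.
welch_oracle <- list(
  gn_rods_short = list(args = c(8.3, 8.1, 97, 16.7, 12.3, 72),
                       t = -5.040123406594, df = 115.2356315524,
                       p = 1.743522200388e-06),
  immune_cells = list(args = c(2.0, 2.8, 98, 0.1, 0.3, 72),
                      t = 6.665640946733, df = 100.0215700227,
                      p = 1.460317270535e-09)
)

test_that("Welch t from summaries matches the independent closed-form oracle", {
  for (name in names(welch_oracle)) {
    o <- welch_oracle[[name]]
    got <- do.call(t_test_from_summary, as.list(o$args))
    expect_equal(got$t, o$t, tolerance = 1e-10, info = name)
    expect_equal(got$df, o$df, tolerance = 1e-10, info = name)
    expect_equal(got$p_value, o$p, tolerance = 1e-10, info = name)
  }
  # pooled-variance option, same oracle source
  pooled <- t_test_from_summary(8.3, 8.1, 97, 16.7, 12.3, 72,
                                variant = "student")
  expect_equal(pooled$t, -5.345761488497, tolerance = 1e-10)
  expect_equal(pooled$df, 167)
  expect_equal(pooled$p_value, 2.9203185817e-07, tolerance = 1e-9)
})

test_that("degenerate summary inputs follow the documented conventions", {
  eq <- t_test_from_summary(2, 1, 10, 2, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)
  zero_eq <- t_test_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(zero_eq$p_value, 1)
  expect_warning(zero_ne <- t_test_from_summary(3, 0, 5, 4, 0, 5),
                 "SDs are zero")
  expect_equal(zero_ne$p_value, 0)
  expect_error(t_test_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("group summaries split by label with category-wise missing exclusion", {
  obs <- dplyr::bind_rows(
    make_obs(3, immune_cells = c(2, 2, 2)),
    make_obs(3, immune_cells = c(2, 2, 2))
  )
  obs$image_id <- sprintf("i%d", 1:6)
  obs$sample_id <- sprintf("s%d", 1:6)
  labels <- tibble::tibble(sample_id = obs$sample_id,
                           inflamed = rep(c(TRUE, FALSE), each = 3))
  gs <- summarize_groups(obs, labels, categories = "immune_cells")
  expect_equal(gs$mean_inflamed, gs$mean_normal)
  expect_equal(gs$t, 0)
  expect_equal(gs$p_value, 1)
  # NA in one group excluded category-wise, counts reflect it
  obs$gp_cocci <- c(NA, 1, 2, 3, 4, 5)
  gs2 <- summarize_groups(obs, labels,
                          categories = c("gp_cocci", "immune_cells"))
  expect_identical(gs2$n_inflamed[gs2$category == "gp_cocci"], 2L)
  expect_identical(gs2$n_inflamed[gs2$category == "immune_cells"], 3L)
  # < 2 values in a group: p omitted with a warning
  obs$gn_cocci <- c(1, NA, NA, 1, 2, 3)
  expect_warning(
    gs3 <- summarize_groups(obs, labels, categories = "gn_cocci"),
    "< 2 values")
  expect_true(is.na(gs3$p_value))
})

test_that("default p-value bands reproduce the published first-pass weights", {
  weights <- assign_weights(printed_p_row())
  got <- setNames(weights$points, weights$category)
  expected <- c(
    gp_cocci = 1L, gp_rods = 1L, gp_diplococci = 1L, gn_rods_short = 2L,
    gn_rods_long = 2L, immune_cells = 3L, mature_ec = 1L,
    gp_pleomorphic = 0L, gn_cocci = 0L, intermediate_ec = 0L,
    parabasal_ec = 0L, mucus_grade = 0L, scant_bacteria = 0L
  )
  expect_identical(got[names(expected)], expected)
  # band boundaries: strict below each band edge, gate at alpha
  edge <- assign_weights(c(a = 1e-8, b = 5e-4, c = 0.05, d = 0.049))
  expect_identical(setNames(edge$points, edge$category)[c("a", "b", "c", "d")],
                   c(a = 2L, b = 1L, c = 0L, d = 1L))
  expect_error(assign_weights(c(a = 1.2)), "\\[0, 1\\]")
  expect_error(assign_weights(c(0.1)), "named")
})

test_that("concordance recomputes the published percentages and rounds half up", {
  cases <- list(
    # n_concordant, total, expected percent (published rows)
    c(132, 171, 77), c(138, 171, 81), c(136, 171, 80), c(130, 171, 76),
    c(115, 169, 68), c(128, 168, 76), c(122, 169, 72), c(129, 168, 77)
  )
  for (case in cases) {
    calls <- rep(c(TRUE, FALSE), c(case[1], case[2] - case[1]))
    got <- concordance(calls, rep(TRUE, case[2]))
    expect_identical(got$n_concordant, as.integer(case[1]))
    expect_identical(got$percent, as.integer(case[3]),
                     info = sprintf("%d/%d", case[1], case[2]))
  }
  expect_identical(concordance(c(TRUE, TRUE), c(TRUE, TRUE))$percent, 100L)
  # half-up at .5: 153/200 = 76.5 -> 77
  expect_identical(
    concordance(rep(c(TRUE, FALSE), c(153, 47)), rep(TRUE, 200))$percent,
    77L)
  expect_error(concordance(logical(), logical()), "empty")
  expect_error(concordance(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("ROC sweep handles separation, ties and the published-style example", {
  perfect <- roc_auc(c(1, 1, 9, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)
  flat <- roc_auc(rep(3, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(flat$auc, 0.5)
  tied <- roc_auc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tied$auc, 0.875)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("ROC AUC equals the brute-force Mann-Whitney statistic on random instances", {
  for (seed in 1:60) {
    withr::with_seed(seed, {
      n <- sample(4:50, 1)
      scores <- sample(0:10, n, replace = TRUE)
      labels <- c(TRUE, FALSE,
                  sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    })
    expect_equal(roc_auc(scores, labels)$auc, mw_auc(scores, labels),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("the Youden cut-off attains the exhaustive-sweep maximum with low ties", {
  simple <- youden_cutoff(roc_auc(c(1, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(simple$cutoff, 2)
  expect_equal(simple$youden_j, 1)
  flat <- youden_cutoff(roc_auc(rep(4, 4), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(flat$youden_j, 0)
  for (seed in 1:60) {
    withr::with_seed(seed, {
      n <- sample(4:40, 1)
      scores <- sample(0:7, n, replace = TRUE)
      labels <- c(TRUE, FALSE,
                  sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    })
    got <- youden_cutoff(roc_auc(scores, labels))
    ref <- sweep_youden(scores, labels)
    expect_equal(got$youden_j, ref$j, tolerance = 1e-12)
    expect_equal(got$cutoff, ref$cutoff, info = paste("seed", seed))
  }
})

test_that("logistic diagnostics report signs, drop dead categories and flag separation", {
  withr::with_seed(7, {
    n <- 60
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    dat <- tibble::tibble(
      immune_cells = ifelse(labels, 3L, 0L),   # perfectly informative
      mature_ec = sample(0:1, n, replace = TRUE),
      gn_cocci = 0L                            # zero variance
    )
  })
  expect_message(fit <- lr_diagnostics(dat, labels), "zero-variance")
  expect_identical(fit$dropped, "gn_cocci")
  expect_true(fit$separation)
  tab <- tidy(fit)
  expect_identical(tab$sign[tab$term == "immune_cells"], "positive")
  expect_error(lr_diagnostics(dat, rep(TRUE, nrow(dat))), "both labels")
  expect_error(lr_diagnostics(dat[, 1, drop = FALSE], labels),
               "at least 2")
})

test_that("coefficient signs recover the generative directions across replicates", {
  cfg <- generator_config(n_inflamed = 50, n_normal = 50)
  hits <- c(immune = 0, rods = 0)
  n_rep <- 40
  for (seed in seq_len(n_rep)) {
    co <- suppressMessages(generate_cohort(cfg, seed = 5000 + seed))
    obs <- gramscore:::add_derived_categories(co$observations)
    merged <- dplyr::left_join(obs, co$truth, by = "sample_id")
    fit <- suppressMessages(
      lr_diagnostics(merged[, c("gp_diplococci", "gn_rods_combined",
                                "immune_cells", "mature_ec")],
                     merged$inflamed))
    tab <- tidy(fit)
    # immune-cell counts rise with inflammation; Gram-negative rod loads
    # are heavier in normals, so on raw counts the rod coefficient is
    # negative
    hits["immune"] <- hits["immune"] +
      (tab$estimate[tab$term == "immune_cells"] > 0)
    hits["rods"] <- hits["rods"] +
      (tab$estimate[tab$term == "gn_rods_combined"] < 0)
  }
  expect_gte(hits[["immune"]] / n_rep, 0.95)
  expect_gte(hits[["rods"]] / n_rep, 0.95)
})

test_that("develop_iteration reports every candidate at both levels and breaks ties to fewer rules", {
  cfg <- generator_config(n_inflamed = 30, n_normal = 30)
  co <- suppressMessages(generate_cohort(cfg, seed = 77))
  labels <- co$truth
  dev <- develop_iteration(co$observations, labels, "v2.1")
  expect_identical(nrow(dev$report), 2L)
  expect_setequal(dev$report$level, c("image", "sample"))
  expect_true(all(!is.na(dev$report$auc)))
  expect_true(all(dev$report$n_concordant + dev$report$n_discordant ==
                    dev$report$n))
  # adding a rule that can never fire leaves the AUC unchanged; the tie
  # must break toward the smaller matrix
  base <- builtin_matrix("final_reduced")
  padded <- scoring_matrix(
    "padded", c(base$rules,
                list(category_rule("gn_cocci", "gt", threshold = 1e9,
                                   points = 2))),
    cutoff = cutoff_youden())
  dev2 <- develop_iteration(co$observations, labels, list(padded, base))
  rep2 <- dev2$report[dev2$report$level == "sample", ]
  expect_equal(rep2$auc[rep2$matrix_id == "padded"],
               rep2$auc[rep2$matrix_id == "final_reduced"])
  expect_identical(dev2$recommended, "final_reduced")
  # reproducible end-to-end under a fixed seed
  dev3 <- develop_iteration(co$observations, labels, list(padded, base))
  expect_identical(dev2$report, dev3$report)
})

test_that("per-sample averaging changes concordance only modestly on synthetic data", {
  cfg <- generator_config(n_inflamed = 60, n_normal = 60)
  co <- suppressMessages(generate_cohort(cfg, seed = 99))
  dev <- develop_iteration(co$observations, co$truth, "final_reduced")
  by_level <- setNames(dev$report$percent_concordance, dev$report$level)
  expect_lt(abs(by_level[["image"]] - by_level[["sample"]]), 15)
})
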