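test_that("final_reduced scores the published group mean profiles as expected", {
  final <- builtin_matrix("final_reduced")
  inflamed_profile <- make_obs(1, gp_diplococci = 0.4, gn_rods_short = 8.3,
                               gn_rods_long = 0.5, immune_cells = 2.0,
                               mature_ec = 0.4)
  normal_profile <- make_obs(1, gp_diplococci = 1.5, gn_rods_short = 16.7,
                             gn_rods_long = 1.9, immune_cells = 0.1,
                             mature_ec = 0.8)
  expect_identical(score_images(inflamed_profile, final)$score, 6L)
  expect_identical(score_images(normal_profile, final)$score, 0L)
  # all-zero field: diplococci in [0,1], rods < 15, mature exactly 0
  expect_identical(score_images(make_obs(1), final)$score, 4L)
})

test_that("scores are bounded, deterministic, and use the derived rod category", {
  obs <- random_obs(120, seed = 11)
  for (id in builtin_matrix_ids()) {
    m <- builtin_matrix(id)
    s1 <- score_images(obs, m)$score
    s2 <- score_images(obs, m)$score
    expect_identical(s1, s2, info = id)
    expect_true(all(s1 >= 0 & s1 <= max_possible_score(m)), info = id)
  }
  # gn_rods_combined equals short + long wherever referenced
  final <- builtin_matrix("final_reduced")
  at_edge <- make_obs(1, gn_rods_short = 14, gn_rods_long = 1,
                      immune_cells = 5, gp_diplococci = 3, mature_ec = 1)
  over_edge <- dplyr::mutate(at_edge, gn_rods_long = 2)
  expect_identical(score_images(at_edge, final)$score, 3L + 0L)  # 15 not < 15
  expect_identical(score_images(over_edge, final)$score, 3L)
})

test_that("final_reduced score is monotone in immune cells and drops when rods cross 15", {
  final <- builtin_matrix("final_reduced")
  base <- random_obs(60, seed = 21)
  for (delta in c(1, 3, 10)) {
    more <- dplyr::mutate(base, immune_cells = immune_cells + delta)
    expect_true(all(score_images(more, final)$score >=
                      score_images(base, final)$score))
  }
  low_rods <- make_obs(1, gn_rods_short = 5, immune_cells = 3)
  high_rods <- dplyr::mutate(low_rods, gn_rods_short = 20)
  expect_true(score_images(high_rods, final)$score <=
                score_images(low_rods, final)$score)
})

test_that("non-ok observations are excluded or rejected, never scored", {
  obs <- dplyr::bind_rows(make_obs(2), make_obs(1, quality = "blurry"))
  obs$image_id <- c("a", "b", "c")
  m <- builtin_matrix("final_reduced")
  expect_message(out <- score_images(obs, m), "excluding 1")
  expect_identical(out$image_id, c("a", "b"))
  expect_error(score_images(obs, m, drop_excluded = FALSE), "quality")
})

test_that("missing category values are rejected with the category named", {
  obs <- make_obs(2)
  obs$immune_cells[2] <- NA_real_
  expect_error(score_images(obs, builtin_matrix("final_reduced")),
               "immune_cells")
  slim <- make_obs(1)[, c("image_id", "sample_id", "quality")]
  expect_error(score_images(slim, builtin_matrix("final_reduced")),
               "gp_diplococci")
})

test_that("sample averaging is the arithmetic mean and empties are explicit NA", {
  expect_equal(
    score_samples(tibble::tibble(sample_id = rep("a", 3),
                                 score = c(6, 6, 6)))$score, 6)
  expect_equal(
    score_samples(tibble::tibble(sample_id = c("a", "a"),
                                 score = c(4, 6)))$score, 5)
  expect_warning(
    out <- score_samples(tibble::tibble(sample_id = character(),
                                        score = integer()),
                         samples = "lonely"),
    "no scoreable images")
  expect_identical(out$n_images, 0L)
  expect_true(is.na(out$score))
})

test_that("fixed cut-off calls honour both published orientations", {
  expect_true(call_inflamed(6, cutoff_fixed(6, "ge")))
  expect_false(call_inflamed(5, cutoff_fixed(6, "ge")))
  expect_true(call_inflamed(5, 4, orientation = "gt"))
  expect_false(call_inflamed(4, 4, orientation = "gt"))
  expect_true(call_inflamed(6, builtin_matrix("v2.1")))
  expect_error(call_inflamed(5, builtin_matrix("final_reduced")),
               "Youden")
})

test_that("rule_scores decomposes the total score by category", {
  obs <- random_obs(25, seed = 33)
  m <- builtin_matrix("final_reduced")
  rs <- rule_scores(obs, m)
  expect_setequal(
    setdiff(names(rs), c("image_id", "sample_id", "score")),
    c("gp_diplococci", "gn_rods_combined", "immune_cells", "mature_ec")
  )
  expect_identical(rs$score, score_images(obs, m)$score)
})
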