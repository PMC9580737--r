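make_ct <- function(n, strata, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n)),
    community_type = sample(strata, n, replace = TRUE)
  ))
}

test_that("the default plan partitions 264 samples into 53/53/53/53/52", {
  ct <- make_ct(264, paste0("CT", 1:5), seed = 3)
  out <- stratified_partition(ct, subsample_plan(seed = 9))
  expect_identical(
    as.integer(table(out$subsample)[c("A", "B", "C", "D", "E")]),
    c(53L, 53L, 53L, 53L, 52L)
  )
  expect_setequal(out$sample_id, ct$sample_id)
  expect_identical(anyDuplicated(out$sample_id), 0L)
})

test_that("a single stratum with sizes (2,2) splits four samples evenly", {
  ct <- tibble::tibble(sample_id = letters[1:4], community_type = "CT1")
  out <- stratified_partition(ct, subsample_plan(c(A = 2, B = 2), seed = 1))
  expect_identical(as.integer(table(out$subsample)), c(2L, 2L))
})

test_that("the partition is reproducible and per-stratum substreams are stable", {
  ct <- make_ct(120, paste0("CT", 1:4), seed = 8)
  plan <- subsample_plan(c(A = 40, B = 40, C = 40), seed = 123)
  expect_identical(stratified_partition(ct, plan),
                   stratified_partition(ct, plan))
  # adding a new stratum leaves draws of existing strata untouched
  extra <- tibble::tibble(sample_id = sprintf("x%02d", 1:30),
                          community_type = "CT9")
  ct2 <- dplyr::bind_rows(ct, extra)
  plan2 <- subsample_plan(c(A = 50, B = 50, C = 50), seed = 123)
  out1 <- stratified_partition(ct, plan)
  out2 <- stratified_partition(ct2, plan2)
  merged <- dplyr::inner_join(out1, out2, by = "sample_id",
                              suffix = c("_old", "_new"))
  same <- mean(merged$subsample_old == merged$subsample_new)
  # old strata keep identical shuffles; only capacity-driven remainder
  # placement may move a handful of samples
  expect_gt(same, 0.9)
})

test_that("stratum counts stay within 1 of exact proportionality", {
  for (seed in 1:5) {
    ct <- make_ct(200, paste0("CT", 1:6), seed = seed)
    sizes <- c(A = 50, B = 50, C = 50, D = 50)
    out <- stratified_partition(ct, subsample_plan(sizes, seed = seed))
    tab <- table(out$community_type, out$subsample)
    for (stratum in rownames(tab)) {
      quota <- sum(tab[stratum, ]) * sizes / 200
      expect_true(all(abs(tab[stratum, names(sizes)] - quota) <= 1 + 1e-9),
                  info = sprintf("seed %d stratum %s", seed, stratum))
    }
  }
})

test_that("invalid plans are rejected", {
  ct <- make_ct(10, "CT1")
  expect_error(stratified_partition(ct, subsample_plan(c(A = 4, B = 4))),
               "sum to")
  ct_na <- ct
  ct_na$community_type[1] <- NA
  expect_error(stratified_partition(ct_na,
                                    subsample_plan(c(A = 5, B = 5))),
               "CT label")
})

test_that("KS equivalence matches the ECDF definition and the asymptotic oracle", {
  expect_equal(ks_equivalence(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_equivalence(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(ks_equivalence(1:5, 6:10)$statistic, 1)
  expect_equal(ks_equivalence(c(1, 2, 3), c(1, 2, 4))$statistic, 1 / 3)
  # asymptotic p agrees with stats::ks.test on tie-free data
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- rnorm(40)
      y <- rnorm(35, mean = 0.5)
    })
    ours <- ks_equivalence(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
  expect_error(ks_equivalence(numeric(), 1:3), "non-empty")
})

test_that("KS D is symmetric and invariant under increasing recoding", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- sample(1:5, 30, replace = TRUE)
      b <- sample(1:5, 25, replace = TRUE)
    })
    d_ab <- ks_equivalence(a, b)$statistic
    expect_equal(ks_equivalence(b, a)$statistic, d_ab)
    recode <- function(v) v^3 + 10  # strictly increasing
    expect_equal(ks_equivalence(recode(a), recode(b))$statistic, d_ab)
  }
})

test_that("the equivalence report covers every pair with KS and chi-square checks", {
  ct <- make_ct(264, paste0("CT", 1:5), seed = 12)
  out <- stratified_partition(ct, subsample_plan(seed = 4))
  eq <- partition_equivalence(out)
  expect_identical(nrow(eq), 10L)
  expect_true(all(eq$ks_d >= 0 & eq$ks_d <= 1))
  expect_true(all(eq$ks_p >= 0 & eq$ks_p <= 1))
  expect_true(all(eq$chisq_p >= 0 & eq$chisq_p <= 1))
  # a stratified partition should look equivalent
  expect_true(all(eq$ks_p > 0.05))
})
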