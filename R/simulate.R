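# Seeded synthetic cohort generator. Emulates the tabular layer of a
# sheep vaginal-product safety study: per-field morphotype counts with
# group-conditional means/SDs, per-sample cytokine ODs with an
# inflammation shift, community-type labels, and the true status needed
# for recovery testing.

#' Published per-category group summary (subsample A)
#'
#' The printed per-category means, sample SDs, observation counts and
#' two-sided p-values for the inflamed and normal groups of the initial
#' development subsample. These summaries seed the generator defaults and
#' the weight-calibration checks.
#'
#' @return Tibble with `category`, `group`, `mean`, `sd`, `n`, `printed_p`.
#' @export
subsample_a_summary <- function() {
  path <- system.file("extdata", "subsample_a_summary.csv",
                      package = "gramscore")
  readr::read_csv(path, col_types = readr::cols(
    category = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Build a synthetic-cohort generator configuration
#'
#' All arguments override fields of the packaged defaults (see
#' [default_generator_config()]); per-category count targets are the
#' published subsample A means/SDs for each status. Counts are negative
#' binomial parameterized by (mean, SD) — morphotype counts are strongly
#' overdispersed — with an automatic fallback to a discretized truncated
#' normal for (mean, SD) pairs with variance at or below the mean, for
#' which the negative binomial has no parameterization.
#'
#' @param ... Named overrides of the default config fields (e.g.
#'   `n_inflamed`, `n_normal`, `images_per_sample`, `quality_fail_rate`,
#'   `sample_effect_sd`, `counts`, `cytokines`, `ct`).
#' @return A `generator_config` object.
#' @examples
#' cfg <- generator_config(n_inflamed = 20, n_normal = 20)
#' @export
generator_config <- function(...) {
  cfg <- default_generator_config()
  overrides <- list(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0) {
      abort(sprintf("unknown config field(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    cfg <- modifyList(unclass(cfg), overrides)
  }
  validate_generator_config(cfg)
}

#' Packaged default generator configuration
#'
#' Reads the packaged defaults whose per-category count targets equal the
#' published subsample A group means/SDs for both statuses.
#'
#' @return A `generator_config` object.
#' @examples
#' cfg <- default_generator_config()
#' cfg$counts$immune_cells$mean_inflamed # 2.0
#' @export
default_generator_config <- function() {
  path <- system.file("extdata", "generator_defaults.yaml",
                      package = "gramscore")
  validate_generator_config(yaml::read_yaml(path))
}

#' Read or write a generator configuration file
#' @param path YAML file path.
#' @param config A `generator_config` object (write only).
#' @return `read_generator_config()`: a `generator_config`;
#'   `write_generator_config()`: `path`, invisibly.
#' @export
read_generator_config <- function(path) {
  validate_generator_config(yaml::read_yaml(path))
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_inflamed < 0 || cfg$n_normal < 0) {
    abort("sample counts must be non-negative.")
  }
  ips <- cfg$images_per_sample
  if (length(ips) != 2 || ips[1] < 1 || ips[1] > ips[2]) {
    abort("`images_per_sample` must be a range c(lo, hi) with lo >= 1.")
  }
  for (cat in names(cfg$counts)) {
    tg <- cfg$counts[[cat]]
    if (any(unlist(tg) < 0)) {
      abort(sprintf("negative mean/SD target for %s.", cat))
    }
  }
  if (cfg$quality_fail_rate < 0 || cfg$quality_fail_rate >= 1) {
    abort("`quality_fail_rate` must be in [0, 1).")
  }
  if (abs(sum(cfg$ct$probs) - 1) > 1e-8) {
    abort("CT probabilities must sum to 1.")
  }
  if (length(cfg$ct$probs) != length(cfg$ct$levels)) {
    abort("CT levels and probs must have equal length.")
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d inflamed + %d normal samples; %d-%d images/sample; %d count categories (%s); CT levels: %s\n",
    x$n_inflamed, x$n_normal, x$images_per_sample[1],
    x$images_per_sample[2], length(x$counts), x$count_family,
    paste(x$ct$levels, collapse = ", ")
  ))
  invisible(x)
}

# Draw n counts with target (mean, sd), scaled per observation by a
# multiplicative factor. Negative binomial keeps its size (overdispersion)
# fixed while the mean is scaled; infeasible (var <= mean) targets fall
# back to a discretized normal censored at zero.
draw_counts <- function(n, mean, sd, factor = rep(1, n)) {
  if (n == 0) return(integer(0))
  if (mean == 0) return(integer(n))
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    rnbinom(n, size = size, mu = mean * factor)
  } else {
    pmax(0L, as.integer(round(rnorm(n, mean * factor, sd))))
  }
}

#' Generate a synthetic cohort
#'
#' Draws per-field morphotype observations, per-sample cytokine panels and
#' CT labels with the group-conditional structure of the generator config.
#' Images of one sample share a log-scale random intercept so per-sample
#' averaging is non-trivial. Fully reproducible under `seed`.
#'
#' @param config A `generator_config`.
#' @param seed Integer master seed.
#' @return List of tibbles: `observations` (one row per imaged field, in
#'   the standard observation-table format), `cytokines` (one row per
#'   sample), `ct` (`sample_id`, `community_type`), `truth` (`sample_id`,
#'   logical `inflamed`). Zero-sample configs give empty tables.
#' @examples
#' cohort <- generate_cohort(generator_config(n_inflamed = 5, n_normal = 5),
#'                           seed = 1)
#' nrow(cohort$truth)
#' @export
generate_cohort <- function(config = default_generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  n_total <- config$n_inflamed + config$n_normal
  if (n_total == 0) {
    return(list(
      observations = empty_observations(),
      cytokines = tibble(sample_id = character(),
                         !!!setNames(rep(list(numeric()), 6),
                                     cytokine_names())),
      ct = tibble(sample_id = character(), community_type = character()),
      truth = tibble(sample_id = character(), inflamed = logical())
    ))
  }
  fallback <- names(config$counts)[vapply(
    config$counts,
    function(tg) tg$sd_inflamed^2 <= tg$mean_inflamed ||
      tg$sd_normal^2 <= tg$mean_normal,
    logical(1)
  )]
  if (length(fallback) > 0) {
    inform(paste0(
      "count categories using the discretized-normal fallback ",
      "(variance <= mean for at least one status): ",
      paste(fallback, collapse = ", ")
    ))
  }
  withr::with_seed(as.integer(seed), {
    truth <- tibble(
      sample_id = sprintf("S%04d", seq_len(n_total)),
      inflamed = rep(c(TRUE, FALSE),
                     c(config$n_inflamed, config$n_normal))
    )
    ct <- tibble(
      sample_id = truth$sample_id,
      community_type = sample(config$ct$levels, n_total, replace = TRUE,
                              prob = config$ct$probs)
    )
    ips <- config$images_per_sample
    n_img <- sample(seq(ips[1], ips[2]), n_total, replace = TRUE)
    sample_effect <- exp(rnorm(n_total, 0, config$sample_effect_sd))
    obs <- tibble(
      sample_id = rep(truth$sample_id, n_img),
      inflamed = rep(truth$inflamed, n_img),
      .factor = rep(sample_effect, n_img)
    )
    obs$image_id <- sprintf("I%05d", seq_len(nrow(obs)))
    for (cat in names(config$counts)) {
      tg <- config$counts[[cat]]
      v <- integer(nrow(obs))
      for (status in c(TRUE, FALSE)) {
        idx <- which(obs$inflamed == status)
        m <- if (status) tg$mean_inflamed else tg$mean_normal
        s <- if (status) tg$sd_inflamed else tg$sd_normal
        v[idx] <- draw_counts(length(idx), m, s, obs$.factor[idx])
      }
      obs[[cat]] <- v
    }
    mucus_p <- ifelse(obs$inflamed, config$mucus_prevalence$inflamed,
                      config$mucus_prevalence$normal)
    present <- rbinom(nrow(obs), 1, mucus_p) == 1
    obs$mucus_grade <- ifelse(present,
                              sample(1:3, nrow(obs), replace = TRUE), 0L)
    scant_p <- ifelse(obs$inflamed, config$scant_prob$inflamed,
                      config$scant_prob$normal)
    obs$scant_bacteria <- rbinom(nrow(obs), 1, scant_p)
    fail <- runif(nrow(obs)) < config$quality_fail_rate
    obs$quality <- ifelse(
      fail,
      sample(c("blurry", "too_sparse", "too_dense", "duplicate"),
             nrow(obs), replace = TRUE),
      "ok"
    )
    cy <- config$cytokines
    panels <- tibble(sample_id = truth$sample_id)
    for (name in cytokine_names()) {
      base <- cy$baseline_meanlog[[name]] %||% 0
      shift <- ifelse(truth$inflamed & name %in% cytokine_names(TRUE),
                      cy$inflamed_shift_log, 0)
      panels[[name]] <- exp(rnorm(n_total, base + shift, cy$sdlog))
    }
    list(
      observations = obs[, observation_columns()],
      cytokines = panels,
      ct = ct,
      truth = truth
    )
  })
}

empty_observations <- function() {
  cols <- observation_columns()
  out <- tibble(image_id = character(), sample_id = character())
  for (cat in count_categories()) out[[cat]] <- numeric()
  out$mucus_grade <- integer()
  out$scant_bacteria <- integer()
  out$quality <- character()
  out[, cols]
}
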