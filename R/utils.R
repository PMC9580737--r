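# Internal helpers shared across modules.

# Round half away from zero (R's round() is banker's rounding); concordance
# percentages are reported round-half-up to match clinical score tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 31-bit seed derived from a master seed and a string key, so
# per-stratum draws consume independent substreams and adding a stratum does
# not perturb the others. Plain polynomial hash; collisions are harmless
# (draws would still be valid, just coupled).
derive_seed <- function(master_seed, key) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer((as.numeric(master_seed) %% m + h) %% m)
}

# Columns holding per-field counts, in canonical order.
count_categories <- function() {
  c(
    "gp_cocci", "gp_rods", "gp_diplococci", "gp_pleomorphic",
    "gn_cocci", "gn_rods_short", "gn_rods_long",
    "immune_cells", "mature_ec", "intermediate_ec", "parabasal_ec"
  )
}

observation_columns <- function() {
  c(
    "image_id", "sample_id", count_categories(),
    "mucus_grade", "scant_bacteria", "quality"
  )
}

quality_levels <- function() {
  c("ok", "blurry", "too_sparse", "too_dense", "duplicate")
}

# Add the derived combined Gram-negative rod category when absent.
add_derived_categories <- function(tbl) {
  if (!"gn_rods_combined" %in% names(tbl) &&
      all(c("gn_rods_short", "gn_rods_long") %in% names(tbl))) {
    tbl$gn_rods_combined <- tbl$gn_rods_short + tbl$gn_rods_long
  }
  tbl
}

# Coerce a two-level label vector to logical "is inflamed".
as_inflamed <- function(labels, arg = "labels") {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1, NA))) {
    return(labels == 1)
  }
  if (is.character(labels) || is.factor(labels)) {
    lab <- tolower(as.character(labels))
    known <- c(
      "inflamed" = TRUE, "y" = TRUE, "yes" = TRUE, "abnormal" = TRUE,
      "normal" = FALSE, "n" = FALSE, "no" = FALSE
    )
    if (all(lab %in% c(names(known), NA))) {
      return(unname(known[lab]))
    }
  }
  abort(sprintf(
    "`%s` must be logical, 0/1, or inflamed/normal (Y/N) labels.", arg
  ))
}
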