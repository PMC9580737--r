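# Reading and writing the pipeline's table formats. CSV, UTF-8, header
# required, "." decimal; TSV via `tsv = TRUE`.

delim_of <- function(tsv) if (tsv) "\t" else ","

#' Read a per-field observation table
#'
#' The observation table holds one row per imaged microscope field with the
#' exact header `image_id, sample_id, gp_cocci, gp_rods, gp_diplococci,
#' gp_pleomorphic, gn_cocci, gn_rods_short, gn_rods_long, immune_cells,
#' mature_ec, intermediate_ec, parabasal_ec, mucus_grade, scant_bacteria,
#' quality`. Counts are non-negative (integers for raw per-field counts;
#' reals are permitted for averaged inputs), `mucus_grade` is 0-3,
#' `quality` one of ok/blurry/too_sparse/too_dense/duplicate. Missing
#' numeric cells are disallowed for quality-`ok` rows.
#'
#' @param path File path.
#' @param tsv Read tab-separated instead of comma-separated.
#' @return Validated tibble.
#' @export
read_observations <- function(path, tsv = FALSE) {
  tbl <- readr::read_delim(path, delim = delim_of(tsv),
                           col_types = readr::cols(
                             image_id = readr::col_character(),
                             sample_id = readr::col_character(),
                             quality = readr::col_character(),
                             .default = readr::col_double()
                           ), progress = FALSE)
  validate_observations(tbl, context = path)
}

validate_observations <- function(tbl, context = "observations") {
  missing_cols <- setdiff(observation_columns(), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  context, paste(missing_cols, collapse = ", ")))
  }
  bad_q <- setdiff(unique(tbl$quality), quality_levels())
  if (length(bad_q) > 0) {
    abort(sprintf("%s: unknown quality value(s): %s",
                  context, paste(bad_q, collapse = ", ")))
  }
  ok <- tbl$quality == "ok"
  num_cols <- c(count_categories(), "mucus_grade", "scant_bacteria")
  for (col in num_cols) {
    v <- tbl[[col]]
    if (any(is.na(v[ok]))) {
      abort(sprintf(
        "%s: missing %s for quality-ok row(s) (e.g. image %s).",
        context, col, tbl$image_id[ok & is.na(v)][1]
      ))
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("%s: negative values in %s.", context, col))
    }
  }
  if (any(!tbl$mucus_grade[ok] %in% 0:3)) {
    abort(sprintf("%s: mucus_grade must be 0-3.", context))
  }
  as_tibble(tbl)
}

#' Read a per-sample cytokine OD table
#'
#' Header: `sample_id, IL1B, IL6, IL8, IL17A, CXCL10, TNFA`. Blank cells
#' are allowed only for IL6/IL17A (the cytokines no built-in model uses).
#'
#' @inheritParams read_observations
#' @return Validated tibble.
#' @export
read_cytokines <- function(path, tsv = FALSE) {
  tbl <- readr::read_delim(path, delim = delim_of(tsv),
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             .default = readr::col_double()
                           ), progress = FALSE)
  missing_cols <- setdiff(c("sample_id", cytokine_names()), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  for (cy in cytokine_names(TRUE)) {
    if (anyNA(tbl[[cy]])) {
      abort(sprintf("%s: missing OD for model cytokine %s (sample %s).",
                    path, cy, tbl$sample_id[is.na(tbl[[cy]])][1]))
    }
    if (any(tbl[[cy]] < 0)) {
      abort(sprintf("%s: negative OD in %s.", path, cy))
    }
  }
  as_tibble(tbl)
}

#' Read a community-type table
#'
#' Header: `sample_id, community_type`; one row per sample.
#'
#' @inheritParams read_observations
#' @return Validated tibble.
#' @export
read_ct <- function(path, tsv = FALSE) {
  tbl <- readr::read_delim(path, delim = delim_of(tsv),
                           col_types = readr::cols(
                             .default = readr::col_character()
                           ), progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "community_type"), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(tbl$community_type)) {
    abort(sprintf("%s: missing community_type value(s).", path))
  }
  as_tibble(tbl)
}

#' Write pipeline tables
#'
#' @param tbl Table to write.
#' @param path Destination path.
#' @param tsv Write tab-separated instead of comma-separated.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path, tsv = FALSE) {
  readr::write_delim(tbl, path, delim = delim_of(tsv), progress = FALSE)
  invisible(path)
}
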