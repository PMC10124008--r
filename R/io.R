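#' Read a feature-abundance table
#'
#' Reads a TSV of abundances (relative abundance, LFQ protein-group
#' intensity, or metabolite peak area) into a samples-by-features tibble.
#' The first column of the table holds ids (sample ids when
#' `orientation = "samples_in_rows"`, feature ids otherwise); the header
#' holds the other axis.
#'
#' @param path TSV file path. Header row of ids, "." decimal, UTF-8.
#' @param orientation Whether samples are in rows (default) or columns.
#' @param mode What the values are: `"relative_abundance"` (must lie in
#'   \[0, 1\] with per-sample sums at most 1), `"lfq_intensity"` or
#'   `"metabolite_peak"` (non-negative, 0 = not detected).
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per feature, carrying the `mode` as an attribute. Feature order is
#'   preserved from the file.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows",
                                               "samples_in_cols"),
                               mode = c("relative_abundance",
                                        "lfq_intensity",
                                        "metabolite_peak")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) abort("feature table needs an id column plus data")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate ids in first column of ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort(paste0("duplicate ids in header of ", path))
  }
  body <- raw[-1]
  for (j in seq_along(body)) {
    parsed <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(parsed) & !is.na(body[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                    body[[j]][bad[1]], bad[1], names(body)[j], path))
    }
    body[[j]] <- parsed
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_in_cols") m <- t(m)
  validate_abundance(m, mode, path)
  out <- matrix_to_df(m)
  attr(out, "mode") <- mode
  out
}

validate_abundance <- function(m, mode, what = "matrix") {
  if (anyNA(m)) abort(paste0("missing values in ", what))
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative value at sample '%s', feature '%s' in %s",
                  rownames(m)[ij[1]], colnames(m)[ij[2]], what))
  }
  if (mode == "relative_abundance") {
    if (any(m > 1)) abort(paste0("relative abundances > 1 in ", what))
    sums <- rowSums(m)
    if (any(sums > 1 + 1e-6)) {
      abort(paste0("per-sample relative-abundance sums exceed 1 in ", what))
    }
  }
  invisible(TRUE)
}

#' Read a mood panel
#'
#' Reads a samples-by-factors TSV of mood questionnaire scores and tags each
#' factor with its polarity. Column names are matched to the configured
#' factor names after trimming, case-folding and unifying en-dash/hyphen
#' variants, and are renamed to the canonical spelling.
#'
#' @param path TSV file path; first column sample ids, one column per factor.
#' @param polarity A tibble with columns `factor` and `polarity` defining the
#'   expected factor set; defaults to the 19-factor POMS + SCL-90 panel of
#'   [default_mood_factors()].
#' @return A tibble `sample_id` + one numeric column per factor, in the
#'   order of `polarity$factor`, with the polarity tibble attached as the
#'   `"polarity"` attribute.
#' @export
read_mood_panel <- function(path, polarity = default_mood_factors()) {
  stopifnot(is.data.frame(polarity),
            all(c("factor", "polarity") %in% names(polarity)),
            all(polarity$polarity %in% c("positive", "negative")))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) abort("duplicate sample ids in mood panel")
  have <- normalize_factor_name(names(raw)[-1])
  want <- normalize_factor_name(polarity$factor)
  missing <- polarity$factor[!want %in% have]
  if (length(missing) > 0) {
    abort(paste0("mood panel is missing factor column(s): ",
                 paste(missing, collapse = ", ")))
  }
  idx <- match(want, have) + 1L
  out <- raw[c(1L, idx)]
  names(out) <- c("sample_id", polarity$factor)
  out$sample_id <- ids
  if (anyNA(out[-1])) abort("missing values in mood panel")
  attr(out, "polarity") <- tibble::as_tibble(polarity[c("factor", "polarity")])
  out
}

#' Panel polarity accessor
#'
#' @param panel A mood panel read by [read_mood_panel()] or generated by
#'   [generate_cohort()].
#' @return The factor/polarity tibble attached to the panel.
#' @export
panel_polarity <- function(panel) {
  pol <- attr(panel, "polarity")
  if (is.null(pol)) abort("panel has no polarity attribute")
  pol
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `gender`
#'   (`female`/`male`), `timepoint` (integer day index, strictly increasing
#'   within a subject) and optionally `phase`.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    subject_id = readr::col_character(),
    gender = readr::col_character(),
    timepoint = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "gender", "timepoint")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0) {
    abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(md$sample_id)) abort("duplicate sample_id in metadata")
  if (!all(md$gender %in% c("female", "male"))) {
    abort("gender must be 'female' or 'male'")
  }
  ok <- tapply(md$timepoint, md$subject_id,
               function(t) all(diff(t) > 0))
  if (!all(unlist(ok))) {
    abort("timepoints must be strictly increasing within each subject")
  }
  invisible(md)
}

#' Write and re-read a screen result
#'
#' `write_screen_report()` serializes a [screen_features()] result to a
#' directory of TSVs: `features.tsv` (per-feature vote counts and flags),
#' `pairs.tsv` (the long feature-by-factor VIP/R/P table, one row per pair),
#' `candidates.tsv` (candidate features with their sign class) and
#' `config.yml`. `read_screen_report()` reconstructs the result; integers
#' round-trip exactly and reals to full double precision.
#'
#' @param result A `psy_screen` object.
#' @param dir Output directory (created if absent).
#' @return `write_screen_report()` returns `dir` invisibly;
#'   `read_screen_report()` returns a `psy_screen`.
#' @export
write_screen_report <- function(result, dir) {
  stopifnot(inherits(result, "psy_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$features, file.path(dir, "features.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$pairs, file.path(dir, "pairs.tsv"),
                   progress = FALSE)
  cand <- dplyr::filter(result$features, .data$candidate)
  readr::write_tsv(cand[c("feature_id", "vip_votes", "corr_votes",
                          "sign_class")],
                   file.path(dir, "candidates.tsv"), progress = FALSE)
  write_run_config(result$config, file.path(dir, "config.yml"))
  readr::write_tsv(result$factors, file.path(dir, "factors.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_screen_report
#' @export
read_screen_report <- function(dir) {
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_types = readr::cols(
                                feature_id = readr::col_character(),
                                vip_votes = readr::col_integer(),
                                corr_votes = readr::col_integer(),
                                key = readr::col_logical(),
                                candidate = readr::col_logical(),
                                sign_class = readr::col_character()
                              ), progress = FALSE)
  pairs <- readr::read_tsv(file.path(dir, "pairs.tsv"),
                           col_types = readr::cols(
                             feature_id = readr::col_character(),
                             factor = readr::col_character(),
                             .default = readr::col_double()
                           ), progress = FALSE)
  factors <- readr::read_tsv(file.path(dir, "factors.tsv"),
                             col_types = readr::cols(
                               factor = readr::col_character(),
                               polarity = readr::col_character(),
                               n_components = readr::col_integer(),
                               .default = readr::col_double()
                             ), progress = FALSE)
  config <- read_run_config(file.path(dir, "config.yml"))
  new_screen_result(features, pairs, factors, config)
}
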