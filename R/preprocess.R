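#' Log2/quotient normalization
#'
#' Normalizes an abundance tibble for regression analysis: each feature is
#' log2-transformed after adding a pseudocount, then divided by its
#' across-sample mean of the log values (the quotient step), so that every
#' feature fluctuates around 1 on a common multiplicative scale. The log is
#' taken first because the raw quotient of compositional values is already
#' scale-free; set `log_first = FALSE` to divide the raw values by their
#' mean before taking logs instead.
#'
#' The quotient divides by the *absolute* mean of the log values: for
#' relative abundances the logs are negative, and dividing by a negative
#' mean would invert every feature's orientation, silently flipping the sign
#' of all downstream correlations. Features whose post-log mean is exactly 0
#' are divided by 1 (guard against blow-up); the output is finite
#' everywhere.
#'
#' @param data Samples-by-features tibble, first column `sample_id`.
#' @param pseudocount_policy `"half_min_nonzero"` (half the smallest nonzero
#'   value of the whole matrix — the default, standard compositional
#'   practice) or `"fixed"`.
#' @param pseudocount The constant used when `pseudocount_policy = "fixed"`.
#'   A fixed pseudocount of 0 is permitted for strictly positive data.
#' @param log_first Take logs before the quotient step (default `TRUE`).
#' @return A tibble of the same shape with normalized values.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
#'                       taxon_a = c(1, 2, 4), taxon_b = c(4, 4, 4))
#' normalize_abundance(tbl, pseudocount_policy = "fixed", pseudocount = 0)
normalize_abundance <- function(data,
                                pseudocount_policy = c("half_min_nonzero",
                                                       "fixed"),
                                pseudocount = 1e-6,
                                log_first = TRUE) {
  pseudocount_policy <- match.arg(pseudocount_policy)
  m <- df_to_matrix(data)
  if (any(m < 0)) abort("normalize_abundance requires non-negative values")
  all_zero <- colSums(m > 0) == 0
  if (any(all_zero)) {
    abort(paste0("feature(s) with all-zero values: ",
                 paste(head(colnames(m)[all_zero], 5), collapse = ", "),
                 "; run filter_prevalence() first"))
  }
  c_j <- switch(pseudocount_policy,
    half_min_nonzero = min(m[m > 0]) / 2,
    fixed = pseudocount
  )
  if (any(m + c_j <= 0)) {
    abort("zeros present with pseudocount 0; use a positive pseudocount")
  }
  if (log_first) {
    lg <- log2(m + c_j)
    mu <- abs(colMeans(lg))      # |mean|: keep each feature's orientation
    mu[mu == 0] <- 1
    out <- sweep(lg, 2, mu, "/")
  } else {
    mu <- colMeans(m)
    mu[mu == 0] <- 1
    out <- log2(sweep(m, 2, mu, "/") + c_j)
  }
  if (!all(is.finite(out))) abort("normalization produced non-finite values")
  res <- matrix_to_df(out)
  attr(res, "mode") <- attr(data, "mode")
  attr(res, "normalized") <- TRUE
  res
}

#' Prevalence filter
#'
#' Keeps a feature only if, in *every* group of samples (typically one group
#' per crew/subject group), the fraction of samples in which it is detected
#' (value > 0) is at least `min_fraction`. This is the >= 50%-per-group
#' presence rule used to reduce sparse protein-group matrices before
#' multivariate analysis.
#'
#' @param data Samples-by-features tibble, first column `sample_id`.
#' @param groups Character (or factor) vector assigning each sample, in row
#'   order, to a group; or a metadata tibble with `sample_id` plus a
#'   `group_col` column.
#' @param min_fraction Minimum detected fraction per group, compared with
#'   `>=`. Default 0.5.
#' @param group_col Column of `groups` to use when it is a tibble. Default
#'   `"subject_id"`.
#' @return The filtered tibble (feature order preserved). The per-feature,
#'   per-group prevalence report is attached as attribute
#'   `"prevalence_report"` and retrievable with [prevalence_report()].
#' @export
filter_prevalence <- function(data, groups, min_fraction = 0.5,
                              group_col = "subject_id") {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  m <- df_to_matrix(data)
  if (is.data.frame(groups)) {
    idx <- match(rownames(m), groups$sample_id)
    if (anyNA(idx)) abort("groups tibble does not cover all samples")
    groups <- as.character(groups[[group_col]][idx])
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) {
    abort("'groups' must assign every sample to a group")
  }
  if (any(table(groups) == 0)) abort("empty group")
  by_group <- rowsum((m > 0) + 0, groups)          # detections per group
  n_group <- as.vector(table(groups)[rownames(by_group)])
  frac <- sweep(by_group, 1, n_group, "/")
  keep <- apply(frac >= min_fraction, 2, all)
  report <- tibble::as_tibble(as.table(frac), .name_repair = "minimal")
  names(report) <- c("group", "feature_id", "prevalence")
  report <- dplyr::mutate(
    report,
    kept = .data$feature_id %in% colnames(m)[keep]
  )
  inform(sprintf("prevalence filter (>= %.0f%% per group): %d -> %d features",
                 100 * min_fraction, ncol(m), sum(keep)))
  out <- data[c(1L, which(keep) + 1L)]
  attr(out, "mode") <- attr(data, "mode")
  attr(out, "prevalence_report") <- report
  attr(out, "dropped") <- colnames(m)[!keep]
  out
}

#' @rdname filter_prevalence
#' @param x A tibble returned by `filter_prevalence()`.
#' @export
prevalence_report <- function(x) {
  rep <- attr(x, "prevalence_report")
  if (is.null(rep)) abort("no prevalence report attached")
  rep
}

#' Horizon transform of a factor time series
#'
#' Median-centers a mood-factor series and returns the band width used to
#' slice horizon graphs: the median absolute deviation from the median.
#' Cooler/warmer horizon bands then show date ranges where the factor runs
#' above/below its own median.
#'
#' @param series Numeric vector, length >= 2.
#' @return A list with `centered` (series minus its median) and `band_width`
#'   (median of |centered|, unscaled MAD).
#' @export
#' @examples
#' horizon_transform(c(1, 2, 3, 4, 5))
horizon_transform <- function(series) {
  if (!is.numeric(series) || length(series) < 2) {
    abort("series must be numeric with length >= 2")
  }
  centered <- series - median(series)
  list(centered = centered, band_width = median(abs(centered)))
}

#' Horizon transform of every factor in a mood panel
#'
#' @param panel Mood panel tibble (`sample_id` + factor columns).
#' @param metadata Optional metadata tibble supplying `subject_id` and
#'   `timepoint` for each sample; when given, series are centered per
#'   subject.
#' @return Long tibble: `sample_id`, (`subject_id`, `timepoint` if given),
#'   `factor`, `score`, `centered`, `band_width`.
#' @export
horizon_panel <- function(panel, metadata = NULL) {
  long <- tidyr::pivot_longer(panel, -"sample_id",
                              names_to = "factor", values_to = "score")
  if (!is.null(metadata)) {
    long <- dplyr::left_join(
      long, metadata[c("sample_id", "subject_id", "timepoint")],
      by = "sample_id"
    )
    grouping <- c("factor", "subject_id")
  } else {
    grouping <- "factor"
  }
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(
      centered = .data$score - median(.data$score),
      band_width = median(abs(.data$score - median(.data$score)))
    ) |>
    dplyr::ungroup()
}
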