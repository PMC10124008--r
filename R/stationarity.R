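#' Sample autocorrelation function
#'
#' Computes the biased (common-denominator) sample ACF used in standard ACF
#' plots: `r_k = sum_{t=1..n-k} (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t -
#' xbar)^2`, with `r_0 = 1` exactly.
#'
#' @param series Numeric time series (ordered, treated as equally spaced).
#' @param max_lag Largest lag; requires `length(series) >= max_lag + 2`.
#' @return Numeric vector of length `max_lag + 1`, autocorrelations at lags
#'   `0..max_lag`.
#' @export
#' @examples
#' sample_acf(rep(c(1, -1), 5), max_lag = 1)  # r_1 = -0.9
sample_acf <- function(series, max_lag) {
  n <- length(series)
  stopifnot(max_lag >= 1)
  if (n < max_lag + 2) abort("series too short for requested max_lag")
  if (anyNA(series)) abort("missing values in series")
  if (var(series) == 0) abort("constant series: ACF undefined")
  r <- as.vector(stats::acf(series, lag.max = max_lag, plot = FALSE,
                            demean = TRUE, type = "correlation")$acf)
  r[1] <- 1
  r
}

#' Ljung-Box portmanteau test
#'
#' The Q statistic summarizing autocorrelation up to lag `h`:
#' `Q = n (n + 2) * sum_{k=1..h} r_k^2 / (n - k)`, referred to a chi-square
#' distribution with `h` degrees of freedom (upper tail). Large Q / small P
#' indicate serial dependence, i.e. the series fails the stationary
#' white-noise gate.
#'
#' @param acf_values Autocorrelations at lags `1, 2, ...` (lag 0 excluded);
#'   the first `h` values are used.
#' @param n Series length the ACF was computed from.
#' @param h Number of lags in the statistic; must satisfy `h < n`.
#' @return A list with `q_stat` and `q_pvalue`.
#' @export
#' @examples
#' ljung_box(0.2, n = 100, h = 1)  # Q ~ 4.1212
ljung_box <- function(acf_values, n, h = length(acf_values)) {
  if (h >= n) abort("h must be smaller than the series length n")
  if (h < 1 || length(acf_values) < h) abort("need ACF values for lags 1..h")
  r <- acf_values[seq_len(h)]
  q <- n * (n + 2) * sum(r^2 / (n - seq_len(h)))
  list(q_stat = q, q_pvalue = pchisq(q, df = h, lower.tail = FALSE))
}

#' Per-subject stationarity assessment of a variable panel
#'
#' The gate applied before correlating microbiome and mood time series: each
#' (subject, variable) series is treated as a candidate stationary stochastic
#' process and flagged stationary only if (i) every sample autocorrelation at
#' lags `1..max_lag` falls inside the white-noise confidence band
#' `+/- z_{1-alpha/2} / sqrt(n)` and (ii) the Ljung-Box P-value at `max_lag`
#' exceeds `alpha`. Series are never pooled across subjects. Series shorter
#' than 4 points (or with zero variance) are reported with status
#' `"insufficient"` rather than raising an error.
#'
#' @param data Tibble `sample_id` + numeric variable columns (a mood panel or
#'   abundance table).
#' @param metadata Metadata tibble with `sample_id`, `subject_id`,
#'   `timepoint`; series are ordered by `timepoint` within subject.
#' @param max_lag Largest lag tested; default `min(10, floor(n/2) - 1)` per
#'   series.
#' @param alpha Significance level for both the confidence band and the
#'   Ljung-Box test. Default 0.05.
#' @return Long tibble with one row per (subject, variable, lag):
#'   `subject_id`, `variable`, `n`, `lag`, `acf`, `conf_bound`, `q_stat`,
#'   `q_pvalue`, `status` (`"stationary"`, `"nonstationary"`,
#'   `"insufficient"`). Rows with status `"insufficient"` carry `NA` in the
#'   numeric columns and `lag = NA`.
#' @export
assess_stationarity <- function(data, metadata, max_lag = NULL,
                                alpha = 0.05) {
  validate_metadata(metadata)
  m <- df_to_matrix(data)
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx)) abort("metadata does not cover all samples")
  md <- metadata[idx, ]
  subjects <- unique(md$subject_id)
  res <- purrr::map_dfr(subjects, function(s) {
    rows <- which(md$subject_id == s)
    rows <- rows[order(md$timepoint[rows])]
    purrr::map_dfr(colnames(m), function(v) {
      x <- m[rows, v]
      n <- length(x)
      lag_cap <- max_lag %||% min(10L, floor(n / 2) - 1L)
      if (n < 4 || lag_cap < 1 || var(x) == 0 || n < lag_cap + 2) {
        return(tibble::tibble(
          subject_id = s, variable = v, n = n, lag = NA_integer_,
          acf = NA_real_, conf_bound = NA_real_, q_stat = NA_real_,
          q_pvalue = NA_real_, status = "insufficient"
        ))
      }
      r <- sample_acf(x, lag_cap)[-1]
      bound <- qnorm(1 - alpha / 2) / sqrt(n)
      lb <- ljung_box(r, n = n, h = lag_cap)
      flag <- all(abs(r) <= bound) && lb$q_pvalue > alpha
      tibble::tibble(
        subject_id = s, variable = v, n = n, lag = seq_len(lag_cap),
        acf = r, conf_bound = bound, q_stat = lb$q_stat,
        q_pvalue = lb$q_pvalue,
        status = if (flag) "stationary" else "nonstationary"
      )
    })
  })
  res
}

#' One-row-per-series summary of a stationarity assessment
#'
#' @param assessment Output of [assess_stationarity()].
#' @return Tibble `subject_id`, `variable`, `n`, `q_stat`, `q_pvalue`,
#'   `status`.
#' @export
stationarity_summary <- function(assessment) {
  dplyr::distinct(assessment, .data$subject_id, .data$variable, .data$n,
                  .data$q_stat, .data$q_pvalue, .data$status)
}
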