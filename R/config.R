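#' Default mood-panel factor names
#'
#' The 19-factor mood panel combines the Profile of Mood States (POMS; seven
#' factors plus the Total Mood Disturbance summary) with the Symptom
#' Checklist-90 (SCL-90; ten symptom factors plus the SUM-SCL total).
#' Vigour-activity and Self-esteem are the two positive-polarity factors
#' (higher score = better mood); all other factors score in the
#' symptom-burden (negative) direction.
#'
#' @return A tibble with columns `factor` and `polarity`
#'   (`"positive"`/`"negative"`), 19 rows.
#' @export
#' @examples
#' default_mood_factors()
default_mood_factors <- function() {
  poms <- c("TMD", "Tension-anxiety", "Anger-hostility", "Fatigue-inertia",
            "Depression-dejection", "Confusion-bewilderment",
            "Vigour-activity", "Self-esteem")
  scl <- c("SUM-SCL", "Somatization", "Obsessive-compulsive",
           "Interpersonal sensitivity", "Depression", "Anxiety", "Hostility",
           "Phobic anxiety", "Paranoid ideation", "Psychoticism",
           "Additional items")
  tibble::tibble(
    factor = c(poms, scl),
    polarity = ifelse(c(poms, scl) %in% c("Vigour-activity", "Self-esteem"),
                      "positive", "negative")
  )
}

#' Screening run configuration
#'
#' Bundles every tunable threshold of the candidate-psychobiotic screen.
#' Defaults follow the published screening rule set: features are *key* when
#' VIP >= 1 in more than 50% of the mood factors, and *candidates* when
#' additionally |Spearman R| >= 0.5 with P < 0.001 in more than 50% of the
#' factors; the protein-group variant of the screen lowers the correlation
#' cutoff to 0.35 (set `r_threshold = 0.35`). "More than 50%" is strict:
#' with 19 factors a feature needs votes in at least 10.
#'
#' @param vip_threshold Minimum VIP score for a factor to count as a VIP
#'   vote. Default 1.
#' @param r_threshold Minimum |Spearman R| for a correlation vote. Default
#'   0.5 (use 0.35 for LFQ protein-group matrices).
#' @param p_threshold Maximum Spearman P for a correlation vote. Default
#'   0.001.
#' @param factor_vote_fraction Fraction of factors that must vote, exceeded
#'   strictly. Default 0.5.
#' @param sign_alpha Significance level for the sign-consistency
#'   classification. Default 0.05.
#' @param max_components Largest number of PLS components considered when
#'   selecting the model size by leave-one-out Q2. Default 10 (capped at
#'   `min(n - 2, p)` at fit time).
#' @param scale Autoscale (unit variance) predictor columns inside each PLS
#'   fit. Default `TRUE`.
#' @param normalize_panel Also log2/quotient-normalize the mood panel before
#'   PLS. Default `FALSE`: mood scores enter as recorded.
#' @param p_method Spearman P-value method, `"t_approx"` or `"exact_perm"`
#'   (full permutation enumeration, only for n <= 8).
#' @param pseudocount_policy `"half_min_nonzero"` or `"fixed"`.
#' @param pseudocount Value of the fixed pseudocount when
#'   `pseudocount_policy = "fixed"`.
#' @param positive_factors Names of the positive-polarity mood factors.
#' @param seed Integer seed recorded with the run.
#'
#' @return A list with class `"psy_config"`.
#' @export
#' @examples
#' cfg <- run_config(r_threshold = 0.35)  # protein-group variant
#' cfg$r_threshold
run_config <- function(vip_threshold = 1,
                       r_threshold = 0.5,
                       p_threshold = 0.001,
                       factor_vote_fraction = 0.5,
                       sign_alpha = 0.05,
                       max_components = 10,
                       scale = TRUE,
                       normalize_panel = FALSE,
                       p_method = c("t_approx", "exact_perm"),
                       pseudocount_policy = c("half_min_nonzero", "fixed"),
                       pseudocount = 1e-6,
                       positive_factors = c("Vigour-activity", "Self-esteem"),
                       seed = 1L) {
  p_method <- match.arg(p_method)
  pseudocount_policy <- match.arg(pseudocount_policy)
  stopifnot(vip_threshold > 0, r_threshold > 0, p_threshold > 0,
            factor_vote_fraction > 0, factor_vote_fraction < 1,
            max_components >= 1, sign_alpha > 0, sign_alpha < 1)
  structure(
    list(
      vip_threshold = vip_threshold,
      r_threshold = r_threshold,
      p_threshold = p_threshold,
      factor_vote_fraction = factor_vote_fraction,
      sign_alpha = sign_alpha,
      max_components = as.integer(max_components),
      scale = scale,
      normalize_panel = normalize_panel,
      p_method = p_method,
      pseudocount_policy = pseudocount_policy,
      pseudocount = pseudocount,
      positive_factors = positive_factors,
      seed = as.integer(seed)
    ),
    class = "psy_config"
  )
}

#' @export
print.psy_config <- function(x, ...) {
  cat("<psy_config>\n")
  cat(sprintf("  VIP threshold:        %.3g\n", x$vip_threshold))
  cat(sprintf("  |R| threshold:        %.3g\n", x$r_threshold))
  cat(sprintf("  P threshold:          %.3g\n", x$p_threshold))
  cat(sprintf("  vote fraction:        > %.3g\n", x$factor_vote_fraction))
  cat(sprintf("  sign alpha:           %.3g\n", x$sign_alpha))
  cat(sprintf("  max PLS components:   %d\n", x$max_components))
  cat(sprintf("  autoscale:            %s\n", x$scale))
  cat(sprintf("  positive factors:     %s\n",
              paste(x$positive_factors, collapse = ", ")))
  invisible(x)
}

#' Read or write a run configuration as a flat YAML key-value file
#'
#' @param path File path.
#' @param config A `psy_config` object (for writing).
#' @return `read_run_config()` returns a `psy_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "psy_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
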