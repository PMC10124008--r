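#' Synthetic cohort configuration
#'
#' Defines the study conditions emulated by the generator: a small closed
#' cohort (default 8 subjects, 4 female / 4 male, 13 timepoints each, ~104
#' samples), a 19-factor mood panel driven by a per-subject latent mood
#' state, and a compositional taxon table in which a small planted set
#' tracks that latent state.
#'
#' The latent mood state of each subject is a stationary AR(1) process with
#' coefficient `ar_phi` and standard-normal innovations. Positive-polarity
#' factors read the state with loading `+lambda`, negative-polarity factors
#' with `-lambda`, plus noise; scores are then rescaled to plausible
#' questionnaire ranges (POMS-like factors to mean 10, sd 4; SCL-like to
#' mean 1.5, sd 0.4 — cosmetic, since the screen is rank- and scale-free).
#' Taxon log-abundances combine a per-taxon baseline, per-subject and gender
#' offsets, the planted effect `effect_size * sign * state` (planted taxa
#' only), and noise, and are closed to relative abundances per sample
#' (logistic-normal composition).
#'
#' @param n_subjects Number of subjects (even; half female). Default 8.
#' @param timepoints_per_subject Timepoints per subject. Default 13.
#' @param n_taxa Number of taxa. Default 200.
#' @param n_planted Number of planted mood-tracking taxa. Default 5.
#' @param effect_size Loading of the latent state on planted-taxon
#'   log-abundance (beta). Default 1.
#' @param planted_sign Sign of each planted loading (+1 mood-tracking, -1
#'   anti-tracking); length 1 or `n_planted`. Default +1.
#' @param ar_phi AR(1) coefficient of the latent state, |phi| < 1.
#'   Default 0.3.
#' @param lambda Loading of the latent state on the mood factors. Default 1.
#' @param factor_noise_sd Factor noise sd (latent scale). Default 0.5.
#' @param taxon_noise_sd Taxon log-abundance noise sd. Default 0.5.
#' @param subject_offset_sd Sd of per-subject, per-taxon offsets.
#'   Default 0.5.
#' @param gender_offset_sd Sd of per-taxon gender effects. Default 0.5.
#' @param baseline_sd Sd of per-taxon baseline log-abundances. Default 1.5.
#' @param n_metabolites Number of metabolites for
#'   [generate_metabolites()]. Default 50.
#' @param metabolite_alpha Loading of planted-taxon log-abundance on linked
#'   metabolites. Default 1.
#' @param metabolite_noise_sd Metabolite log-scale noise sd (also the sd of
#'   unlinked log-normal metabolites). Default 1.
#' @param seed Integer seed; every generator call is reproducible from it.
#' @return A list with class `"psy_cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 8,
                          timepoints_per_subject = 13,
                          n_taxa = 200,
                          n_planted = 5,
                          effect_size = 1,
                          planted_sign = 1,
                          ar_phi = 0.3,
                          lambda = 1,
                          factor_noise_sd = 0.5,
                          taxon_noise_sd = 0.5,
                          subject_offset_sd = 0.5,
                          gender_offset_sd = 0.5,
                          baseline_sd = 1.5,
                          n_metabolites = 50,
                          metabolite_alpha = 1,
                          metabolite_noise_sd = 1,
                          seed = 1L) {
  stopifnot(abs(ar_phi) < 1, n_planted < n_taxa, n_subjects >= 2,
            timepoints_per_subject >= 4,
            factor_noise_sd >= 0, taxon_noise_sd >= 0,
            subject_offset_sd >= 0, gender_offset_sd >= 0)
  planted_sign <- rep_len(sign(planted_sign), n_planted)
  if (any(planted_sign == 0)) abort("planted_sign must be +1 or -1")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      timepoints_per_subject = as.integer(timepoints_per_subject),
      n_taxa = as.integer(n_taxa),
      n_planted = as.integer(n_planted),
      effect_size = effect_size,
      planted_sign = planted_sign,
      ar_phi = ar_phi,
      lambda = lambda,
      factor_noise_sd = factor_noise_sd,
      taxon_noise_sd = taxon_noise_sd,
      subject_offset_sd = subject_offset_sd,
      gender_offset_sd = gender_offset_sd,
      baseline_sd = baseline_sd,
      n_metabolites = as.integer(n_metabolites),
      metabolite_alpha = metabolite_alpha,
      metabolite_noise_sd = metabolite_noise_sd,
      seed = as.integer(seed)
    ),
    class = "psy_cohort_config"
  )
}

# stationary AR(1): x_1 ~ N(0, 1/(1 - phi^2)), innovations N(0, 1)
ar1_series <- function(n, phi) {
  x <- numeric(n)
  x[1] <- rnorm(1, sd = 1 / sqrt(1 - phi^2))
  for (t in seq_len(n - 1)) x[t + 1] <- phi * x[t] + rnorm(1)
  x
}

#' Generate a synthetic cohort with planted signal taxa
#'
#' @param config A [cohort_config()].
#' @return A list with class `"psy_cohort"`:
#'   * `abundance` — samples-by-taxa tibble of relative abundances (rows sum
#'     to 1), mode attribute `"relative_abundance"`;
#'   * `panel` — mood panel tibble with the 19-factor polarity attribute;
#'   * `metadata` — `sample_id`, `subject_id`, `gender`, `timepoint`;
#'   * `truth` — planted taxon ids with loading signs and effect size, and
#'     the latent state per sample.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_taxa = 30, seed = 7))
#' rowSums(cohort$abundance[-1])[1:3]
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "psy_cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  S <- cfg$n_subjects; Tt <- cfg$timepoints_per_subject
  subjects <- make.unique(rep(LETTERS, length.out = S), sep = "")
  genders <- rep(c("female", "male"), each = ceiling(S / 2))[seq_len(S)]
  md <- tidyr::expand_grid(subject_id = subjects,
                           timepoint = seq_len(Tt)) |>
    dplyr::mutate(
      sample_id = sprintf("%s_t%02d", .data$subject_id, .data$timepoint),
      gender = genders[match(.data$subject_id, subjects)]
    ) |>
    dplyr::select("sample_id", "subject_id", "gender", "timepoint")
  n <- nrow(md)

  # latent per-subject mood state
  state <- unlist(lapply(seq_len(S), function(s) ar1_series(Tt, cfg$ar_phi)))

  # mood panel: polarity-signed readout of the state, rescaled per factor
  pol <- default_mood_factors()
  sd_raw <- sqrt(cfg$lambda^2 / (1 - cfg$ar_phi^2) + cfg$factor_noise_sd^2)
  poms <- c("TMD", "Tension-anxiety", "Anger-hostility", "Fatigue-inertia",
            "Depression-dejection", "Confusion-bewilderment",
            "Vigour-activity", "Self-esteem")
  panel_cols <- lapply(seq_len(nrow(pol)), function(i) {
    s <- if (pol$polarity[i] == "positive") 1 else -1
    raw <- s * cfg$lambda * state + rnorm(n, sd = cfg$factor_noise_sd)
    if (pol$factor[i] %in% poms) 10 + 4 * raw / sd_raw
    else 1.5 + 0.4 * raw / sd_raw
  })
  panel <- tibble::as_tibble(setNames(panel_cols, pol$factor))
  panel <- tibble::add_column(panel, sample_id = md$sample_id, .before = 1)
  attr(panel, "polarity") <- pol

  # taxa: baseline + subject and gender offsets + planted effect + noise
  taxa_ids <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  planted_idx <- sort(sample.int(cfg$n_taxa, cfg$n_planted))
  baseline <- rnorm(cfg$n_taxa, sd = cfg$baseline_sd)
  subj_off <- matrix(rnorm(S * cfg$n_taxa, sd = cfg$subject_offset_sd),
                     S, cfg$n_taxa)
  gender_eff <- rnorm(cfg$n_taxa, sd = cfg$gender_offset_sd)
  s_idx <- match(md$subject_id, subjects)
  is_male <- as.numeric(md$gender == "male")
  log_ab <- matrix(baseline, n, cfg$n_taxa, byrow = TRUE) +
    subj_off[s_idx, , drop = FALSE] +
    outer(is_male, gender_eff) +
    matrix(rnorm(n * cfg$n_taxa, sd = cfg$taxon_noise_sd), n, cfg$n_taxa)
  if (cfg$effect_size != 0) {
    for (k in seq_along(planted_idx)) {
      log_ab[, planted_idx[k]] <- log_ab[, planted_idx[k]] +
        cfg$effect_size * cfg$planted_sign[k] * state
    }
  }
  rel <- exp(log_ab)
  rel <- rel / rowSums(rel)
  dimnames(rel) <- list(md$sample_id, taxa_ids)
  abundance <- matrix_to_df(rel)
  attr(abundance, "mode") <- "relative_abundance"

  planted <- if (cfg$effect_size != 0) {
    tibble::tibble(
      feature_id = taxa_ids[planted_idx],
      loading_sign = cfg$planted_sign,
      effect_size = cfg$effect_size
    )
  } else {
    tibble::tibble(feature_id = character(), loading_sign = numeric(),
                   effect_size = numeric())
  }
  structure(
    list(
      abundance = abundance,
      panel = panel,
      metadata = md,
      truth = list(
        planted = planted,
        latent_state = tibble::tibble(sample_id = md$sample_id,
                                      state = state),
        config = cfg
      )
    ),
    class = "psy_cohort"
  )
}

#' @export
print.psy_cohort <- function(x, ...) {
  cat(sprintf("<psy_cohort> %d samples (%d subjects), %d taxa, %d planted\n",
              nrow(x$metadata), length(unique(x$metadata$subject_id)),
              ncol(x$abundance) - 1, nrow(x$truth$planted)))
  invisible(x)
}

#' Generate a metabolite layer linked to the planted taxa
#'
#' Linked metabolites (one per planted taxon, cycling if there are more
#' links than planted taxa) are log-linear readouts of their source taxon's
#' observed log relative abundance with loading `metabolite_alpha` plus
#' log-normal noise; the remaining metabolites are independent log-normal
#' peaks. With `metabolite_alpha = 0` linked and unlinked metabolites are
#' identically distributed.
#'
#' @param cohort A `psy_cohort` from [generate_cohort()].
#' @param config Defaults to the cohort's own config. Uses the fields
#'   `n_metabolites`, `metabolite_alpha`, `metabolite_noise_sd`, `seed`
#'   (offset so the stream differs from the cohort's).
#' @return A samples-by-metabolites tibble (mode `"metabolite_peak"`) with
#'   the link table attached as attribute `"links"` (`metabolite_id`,
#'   `feature_id`, `alpha`).
#' @export
generate_metabolites <- function(cohort, config = NULL) {
  if (!inherits(cohort, "psy_cohort")) {
    abort("generate_metabolites() needs a cohort from generate_cohort()")
  }
  cfg <- config %||% cohort$truth$config
  withr::with_seed(cfg$seed + 1000003L, {
    n <- nrow(cohort$metadata)
    n_met <- cfg$n_metabolites
    planted <- cohort$truth$planted$feature_id
    n_linked <- min(length(planted), n_met)
    met_ids <- sprintf("met_%03d", seq_len(n_met))
    baseline <- rnorm(n_met, mean = 10, sd = 1)
    logm <- matrix(baseline, n, n_met, byrow = TRUE) +
      matrix(rnorm(n * n_met, sd = cfg$metabolite_noise_sd), n, n_met)
    links <- tibble::tibble(metabolite_id = character(),
                            feature_id = character(), alpha = numeric())
    if (n_linked > 0 && cfg$metabolite_alpha != 0) {
      ra <- df_to_matrix(cohort$abundance)
      for (k in seq_len(n_linked)) {
        src <- log(ra[, planted[k]])
        logm[, k] <- logm[, k] + cfg$metabolite_alpha * (src - mean(src))
      }
      links <- tibble::tibble(metabolite_id = met_ids[seq_len(n_linked)],
                              feature_id = planted[seq_len(n_linked)],
                              alpha = cfg$metabolite_alpha)
    }
    m <- exp(logm)
    dimnames(m) <- list(cohort$metadata$sample_id, met_ids)
    out <- matrix_to_df(m)
    attr(out, "mode") <- "metabolite_peak"
    attr(out, "links") <- links
    out
  })
}

#' Generate a null cohort (no planted effect)
#'
#' Identical to [generate_cohort()] with all planted loadings zeroed: the
#' mood panel keeps its polarity structure but no taxon tracks the latent
#' state. The truth records an empty planted set. Used to calibrate the
#' screen's false-positive rate.
#'
#' @param config A [cohort_config()].
#' @return A `psy_cohort`.
#' @export
make_null_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "psy_cohort_config"))
  config$effect_size <- 0
  generate_cohort(config)
}
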