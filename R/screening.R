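#' Screen features against a mood panel for candidate psychobiotics
#'
#' The two-stage selection rule applied to a normalized feature table
#' (species, KO, or protein-group abundances) and a mood panel:
#'
#' * **Stage 1 (VIP vote).** For every mood factor a PLS1 model predicting
#'   the factor from all features is fitted (component count chosen per
#'   factor by leave-one-out Q2) and VIP scores computed. A feature is *key*
#'   when its VIP is at least `vip_threshold` in more than
#'   `factor_vote_fraction` of the factors (strictly more than 50% by
#'   default, i.e. at least 10 of 19).
#' * **Stage 2 (correlation vote).** For key features only, Spearman
#'   correlation against every factor; a feature is a *candidate* when
#'   `|R| >= r_threshold` with `P < p_threshold` in strictly more than the
#'   same fraction of factors.
#' * **Stage 3 (sign consistency).** Candidates are classified with
#'   [classify_sign()]: positive-mood-associated features correlate
#'   positively with every positive-polarity factor and negatively with a
#'   strict majority of the negative-polarity factors (both at
#'   `sign_alpha`), and mirror-image for negative-mood-associated.
#'
#' Factors with zero variance are excluded from the vote denominator (and
#' logged). Samples must be aligned (same ids, same order) between
#' `features` and `panel`.
#'
#' @param features Normalized samples-by-features tibble (`sample_id`
#'   first). Use [normalize_abundance()] beforehand.
#' @param panel Mood panel tibble (`sample_id` + factor columns) carrying a
#'   polarity attribute ([read_mood_panel()], [generate_cohort()]), or pass
#'   `polarity` explicitly.
#' @param config A [run_config()].
#' @param polarity Optional factor/polarity tibble overriding the panel
#'   attribute.
#' @return A `psy_screen` object: `features` (per-feature votes and flags),
#'   `pairs` (long feature-by-factor table of VIP, R, P), `factors`
#'   (per-factor PLS evaluation: A*, Q2, RMSECV, Spearman R/P of the model),
#'   `config`.
#' @export
screen_features <- function(features, panel, config = run_config(),
                            polarity = NULL) {
  X <- df_to_matrix(features)
  check_aligned(rownames(X), panel$sample_id)
  pol <- polarity %||% attr(panel, "polarity")
  if (is.null(pol)) {
    abort("panel has no polarity attribute; supply `polarity`")
  }
  factor_names <- setdiff(names(panel), "sample_id")
  if (!setequal(factor_names, pol$factor)) {
    abort("polarity table does not match panel factors")
  }
  keep <- factor_names[vapply(factor_names,
                              function(f) var(panel[[f]]) > 0, logical(1))]
  if (length(keep) < length(factor_names)) {
    inform(sprintf("excluding %d zero-variance factor(s) from the vote",
                   length(factor_names) - length(keep)))
  }
  f_total <- length(keep)
  feats <- colnames(X)
  p_feat <- length(feats)

  # Stage 1: per-factor PLS, VIP matrix (features x factors)
  vip_mat <- matrix(NA_real_, p_feat, f_total,
                    dimnames = list(feats, keep))
  factor_eval <- purrr::map_dfr(keep, function(f) {
    y <- panel[[f]]
    ev <- pls_factor_eval(X, y, config)
    fit <- fit_pls(X, y, ncomp = ev$n_components, scale = config$scale)
    vip_mat[, f] <<- vip(fit)
    tibble::tibble(
      factor = f,
      polarity = pol$polarity[match(f, pol$factor)],
      n_components = ev$n_components,
      q2 = ev$q2, rmsecv = ev$rmsecv,
      spearman_r = ev$spearman_r, spearman_p = ev$spearman_p
    )
  })
  vip_votes <- rowSums(vip_mat >= config$vip_threshold)
  key <- strict_majority(vip_votes, f_total, config$factor_vote_fraction)
  inform(sprintf("stage 1 (VIP >= %.3g in > %.0f%% of %d factors): %d -> %d features",
                 config$vip_threshold, 100 * config$factor_vote_fraction,
                 f_total, p_feat, sum(key)))

  # Stage 2: Spearman for key features only
  r_mat <- matrix(NA_real_, p_feat, f_total, dimnames = list(feats, keep))
  p_mat <- r_mat
  for (j in which(key)) {
    for (f in keep) {
      sp <- spearman_cor(X[, j], panel[[f]], p_method = config$p_method)
      r_mat[j, f] <- sp$estimate
      p_mat[j, f] <- sp$p.value
    }
  }
  corr_votes <- ifelse(
    key,
    rowSums(abs(r_mat) >= config$r_threshold & p_mat < config$p_threshold,
            na.rm = TRUE),
    NA_integer_
  )
  candidate <- key &
    strict_majority(dplyr::coalesce(corr_votes, 0), f_total,
                    config$factor_vote_fraction)
  inform(sprintf("stage 2 (|R| >= %.3g, P < %.3g in > %.0f%% of factors): %d -> %d candidates",
                 config$r_threshold, config$p_threshold,
                 100 * config$factor_vote_fraction, sum(key),
                 sum(candidate)))

  # Stage 3: sign consistency for candidates
  sign_class <- rep("none", p_feat)
  pol_keep <- setNames(pol$polarity[match(keep, pol$factor)], keep)
  for (j in which(candidate)) {
    sign_class[j] <- classify_sign(r_mat[j, ], p_mat[j, ], pol_keep,
                                   alpha = config$sign_alpha)
  }

  feature_tbl <- tibble::tibble(
    feature_id = feats,
    vip_votes = as.integer(vip_votes),
    corr_votes = as.integer(corr_votes),
    key = unname(key),
    candidate = unname(candidate),
    sign_class = sign_class
  )
  pairs <- tibble::tibble(
    feature_id = rep(feats, times = f_total),
    factor = rep(keep, each = p_feat),
    vip = as.vector(vip_mat),
    r = as.vector(r_mat),
    p = as.vector(p_mat)
  )
  new_screen_result(feature_tbl, pairs, factor_eval, config)
}

new_screen_result <- function(features, pairs, factors, config) {
  structure(
    list(features = features, pairs = pairs, factors = factors,
         config = config),
    class = "psy_screen"
  )
}

#' @export
print.psy_screen <- function(x, ...) {
  cls <- table(x$features$sign_class[x$features$candidate])
  cat(sprintf("<psy_screen> %d features: %d key, %d candidates",
              nrow(x$features), sum(x$features$key),
              sum(x$features$candidate)))
  if (length(cls) > 0) {
    cat(" (", paste(sprintf("%s: %d", names(cls), cls), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @method tidy psy_screen
#' @export
tidy.psy_screen <- function(x, ...) {
  dplyr::left_join(x$pairs, x$features, by = "feature_id")
}

#' @method glance psy_screen
#' @export
glance.psy_screen <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$features),
    n_key = sum(x$features$key),
    n_candidates = sum(x$features$candidate),
    n_positive = sum(x$features$sign_class == "positive_mood_associated"),
    n_negative = sum(x$features$sign_class == "negative_mood_associated"),
    n_inconsistent = sum(x$features$sign_class == "inconsistent")
  )
}

#' Candidate accessor
#'
#' @param x A `psy_screen` object.
#' @return Tibble of candidate features with votes and sign class.
#' @export
candidates <- function(x) {
  stopifnot(inherits(x, "psy_screen"))
  dplyr::filter(x$features, .data$candidate)
}

#' Sign-consistency classification of a candidate feature
#'
#' A feature is `positive_mood_associated` when it correlates positively
#' (R > 0, P < alpha) with *every* positive-polarity factor and negatively
#' (R < 0, P < alpha) with a strict majority of the negative-polarity
#' factors; `negative_mood_associated` is the mirror image; anything else is
#' `inconsistent`. Unanimity is required over the positive factors (there
#' are only two in the default panel) but only a majority over the 17
#' negative ones, whose significance is rarely uniform.
#'
#' @param r Named numeric vector of Spearman R, one per factor.
#' @param p Matching vector of P-values.
#' @param polarity Named character vector (`"positive"`/`"negative"`), same
#'   factors.
#' @param alpha Significance level. Default 0.05.
#' @return One of `"positive_mood_associated"`,
#'   `"negative_mood_associated"`, `"inconsistent"`.
#' @export
classify_sign <- function(r, p, polarity, alpha = 0.05) {
  stopifnot(length(r) == length(p), length(r) == length(polarity))
  if (!is.null(names(r)) && !is.null(names(polarity))) {
    polarity <- polarity[names(r)]
  }
  pos <- polarity == "positive"
  neg <- !pos
  sig_pos_up <- r > 0 & p < alpha
  sig_neg_dn <- r < 0 & p < alpha
  n_neg <- sum(neg)
  if (all(sig_pos_up[pos]) && sum(sig_neg_dn[neg]) > n_neg / 2) {
    return("positive_mood_associated")
  }
  if (all(sig_neg_dn[pos]) && sum(sig_pos_up[neg]) > n_neg / 2) {
    return("negative_mood_associated")
  }
  "inconsistent"
}

#' Re-apply stricter screening thresholds without refitting
#'
#' Recomputes votes, flags and sign classes of an existing screen result
#' under a new configuration. Valid only for thresholds at least as strict
#' as the original run (Stage-2 correlations were computed for the original
#' key features only).
#'
#' @param result A `psy_screen`.
#' @param config The new [run_config()]; `vip_threshold`, `r_threshold` and
#'   `p_threshold` must not be looser than in `result$config`.
#' @return A new `psy_screen`.
#' @export
rescreen <- function(result, config) {
  stopifnot(inherits(result, "psy_screen"))
  old <- result$config
  if (config$vip_threshold < old$vip_threshold ||
      config$r_threshold < old$r_threshold ||
      config$p_threshold > old$p_threshold) {
    abort("rescreen() only supports thresholds at least as strict")
  }
  pairs <- result$pairs
  f_total <- length(unique(pairs$factor))
  pol <- setNames(result$factors$polarity, result$factors$factor)
  per_feat <- pairs |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      vip_votes = sum(.data$vip >= config$vip_threshold),
      corr_votes = sum(abs(.data$r) >= config$r_threshold &
                         .data$p < config$p_threshold, na.rm = TRUE),
      .groups = "drop"
    )
  per_feat <- per_feat[match(result$features$feature_id,
                             per_feat$feature_id), ]
  key <- strict_majority(per_feat$vip_votes, f_total,
                         config$factor_vote_fraction)
  candidate <- key & strict_majority(per_feat$corr_votes, f_total,
                                     config$factor_vote_fraction)
  sign_class <- rep("none", nrow(per_feat))
  for (j in which(candidate)) {
    rows <- pairs$feature_id == per_feat$feature_id[j]
    sign_class[j] <- classify_sign(
      setNames(pairs$r[rows], pairs$factor[rows]),
      setNames(pairs$p[rows], pairs$factor[rows]),
      pol, alpha = config$sign_alpha
    )
  }
  features <- tibble::tibble(
    feature_id = per_feat$feature_id,
    vip_votes = as.integer(per_feat$vip_votes),
    corr_votes = ifelse(key, as.integer(per_feat$corr_votes), NA_integer_),
    key = key, candidate = candidate, sign_class = sign_class
  )
  new_screen_result(features, pairs, result$factors, config)
}

#' Screen metabolites against candidate taxa
#'
#' The inverted screen linking the metabolite layer to already-identified
#' candidate taxa: one PLS1 model per taxon predicts the taxon's
#' (normalized) abundance from all metabolites, and a metabolite is *key*
#' when its VIP reaches `vip_threshold` in **every** taxon model (a
#' conjunction, not a majority). Spearman R/P between each key metabolite
#' and each taxon are reported. An optional `allowlist` (e.g. a curated set
#' of nervous-system-related metabolites) restricts the reported table only;
#' it does not change the fitting.
#'
#' @param metabolites Normalized samples-by-metabolites tibble (`sample_id`
#'   first).
#' @param taxa Normalized samples-by-taxa tibble holding the candidate
#'   taxa's abundances, aligned with `metabolites`.
#' @param taxa_ids Which taxa columns to use; default all. An id absent from
#'   `taxa` is an error.
#' @param allowlist Optional metabolite ids to which the *report* is
#'   restricted.
#' @param config A [run_config()].
#' @return A list with `metabolites` (per-metabolite VIP-in-all flag),
#'   `pairs` (key-metabolite x taxon long table: VIP, R, P) and `taxa_eval`
#'   (per-taxon PLS evaluation).
#' @export
screen_metabolites <- function(metabolites, taxa, taxa_ids = NULL,
                               allowlist = NULL, config = run_config()) {
  M <- df_to_matrix(metabolites)
  Tx <- df_to_matrix(taxa)
  check_aligned(rownames(M), rownames(Tx), c("metabolites", "taxa"))
  taxa_ids <- taxa_ids %||% colnames(Tx)
  missing <- setdiff(taxa_ids, colnames(Tx))
  if (length(missing) > 0) {
    abort(paste0("taxa absent from abundance table: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(taxa_ids) < 1) abort("need at least one candidate taxon")
  mets <- colnames(M)
  vip_mat <- matrix(NA_real_, length(mets), length(taxa_ids),
                    dimnames = list(mets, taxa_ids))
  taxa_eval <- purrr::map_dfr(taxa_ids, function(tx) {
    y <- Tx[, tx]
    ev <- pls_factor_eval(M, y, config)
    fit <- fit_pls(M, y, ncomp = ev$n_components, scale = config$scale)
    vip_mat[, tx] <<- vip(fit)
    tibble::tibble(taxon = tx, n_components = ev$n_components,
                   q2 = ev$q2, rmsecv = ev$rmsecv,
                   spearman_r = ev$spearman_r, spearman_p = ev$spearman_p)
  })
  key <- apply(vip_mat >= config$vip_threshold, 1, all)
  inform(sprintf("metabolite screen (VIP >= %.3g in all %d taxa): %d -> %d key metabolites",
                 config$vip_threshold, length(taxa_ids), length(mets),
                 sum(key)))
  report_mets <- mets[key]
  if (!is.null(allowlist)) report_mets <- intersect(report_mets, allowlist)
  pairs <- purrr::map_dfr(report_mets, function(mt) {
    purrr::map_dfr(taxa_ids, function(tx) {
      sp <- spearman_cor(M[, mt], Tx[, tx], p_method = config$p_method)
      tibble::tibble(metabolite_id = mt, taxon = tx,
                     vip = vip_mat[mt, tx], r = sp$estimate, p = sp$p.value)
    })
  })
  list(
    metabolites = tibble::tibble(metabolite_id = mets,
                                 min_vip = unname(apply(vip_mat, 1, min)),
                                 key = unname(key)),
    pairs = pairs,
    taxa_eval = taxa_eval
  )
}
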