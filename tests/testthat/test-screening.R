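test_that("the majority vote is strict: 10 of 19 passes, 9 does not", {
  expect_false(psychoscreen:::strict_majority(9, 19, 0.5))
  expect_true(psychoscreen:::strict_majority(10, 19, 0.5))
  # even counts: exactly half is not a majority
  expect_false(psychoscreen:::strict_majority(9, 18, 0.5))
  expect_true(psychoscreen:::strict_majority(10, 18, 0.5))
})

test_that("sign classification follows the polarity rules", {
  pol <- setNames(c("positive", "positive", rep("negative", 17)),
                  paste0("f", 1:19))
  r_good <- setNames(c(0.8, 0.8, rep(-0.7, 17)), names(pol))
  p_good <- setNames(rep(1e-4, 19), names(pol))
  expect_equal(classify_sign(r_good, p_good, pol),
               "positive_mood_associated")
  expect_equal(classify_sign(-r_good, p_good, pol),
               "negative_mood_associated")
  # all positive correlations cannot be sign-consistent
  expect_equal(classify_sign(abs(r_good), p_good, pol), "inconsistent")
  # a majority (not unanimity) of negative factors suffices
  r_maj <- r_good
  r_maj[paste0("f", 3:10)] <- 0.1          # 8 of 17 fail, 9 still agree
  expect_equal(classify_sign(r_maj, p_good, pol),
               "positive_mood_associated")
  r_min <- r_good
  r_min[paste0("f", 3:11)] <- 0.1          # only 8 of 17 agree
  expect_equal(classify_sign(r_min, p_good, pol), "inconsistent")
  # non-significant positive factor breaks the unanimity requirement
  p_bad <- p_good; p_bad["f1"] <- 0.2
  expect_equal(classify_sign(r_good, p_bad, pol), "inconsistent")
})

test_that("a planted taxon is recovered as a positive-mood candidate", {
  co <- tiny_cohort(seed = 61, n_taxa = 60)
  norm <- normalize_abundance(co$abundance)
  scr <- screen_quiet(norm, co$panel)
  cand <- candidates(scr)
  expect_true(all(co$truth$planted$feature_id %in% cand$feature_id))
  expect_true(all(cand$sign_class[cand$feature_id %in%
                                    co$truth$planted$feature_id] ==
                    "positive_mood_associated"))
  # invariants: candidate implies key; votes bounded by the factor count
  expect_true(all(scr$features$key[scr$features$candidate]))
  expect_true(all(scr$features$vip_votes <= 19))
  expect_true(all(scr$features$sign_class[!scr$features$candidate] ==
                    "none"))
})

test_that("an anti-tracking taxon is classified negative_mood_associated", {
  co <- generate_cohort(cohort_config(n_taxa = 60, seed = 62,
                                      planted_sign = c(1, 1, 1, -1, -1)))
  norm <- normalize_abundance(co$abundance)
  scr <- screen_quiet(norm, co$panel)
  cand <- candidates(scr)
  anti <- co$truth$planted$feature_id[co$truth$planted$loading_sign < 0]
  expect_true(all(anti %in% cand$feature_id))
  expect_true(all(cand$sign_class[cand$feature_id %in% anti] ==
                    "negative_mood_associated"))
})

test_that("screening is deterministic and rejects misaligned samples", {
  co <- tiny_cohort(seed = 63, n_taxa = 30)
  norm <- normalize_abundance(co$abundance)
  s1 <- screen_quiet(norm, co$panel)
  s2 <- screen_quiet(norm, co$panel)
  expect_equal(s1$features, s2$features)
  expect_equal(s1$pairs, s2$pairs)
  shuffled <- co$panel[rev(seq_len(nrow(co$panel))), ]
  expect_error(screen_quiet(norm, shuffled), "not aligned")
})

test_that("stage 2 restricted to stage-1 survivors changes nothing", {
  co <- tiny_cohort(seed = 64, n_taxa = 40)
  norm <- normalize_abundance(co$abundance)
  scr <- screen_quiet(norm, co$panel)
  cfg <- scr$config
  # recompute the correlation vote over ALL features
  X <- psychoscreen:::df_to_matrix(norm)
  f_names <- unique(scr$pairs$factor)
  all_votes <- vapply(colnames(X), function(j) {
    sum(vapply(f_names, function(f) {
      sp <- spearman_cor(X[, j], co$panel[[f]])
      abs(sp$estimate) >= cfg$r_threshold && sp$p.value < cfg$p_threshold
    }, logical(1)))
  }, numeric(1))
  unrestricted <- scr$features$feature_id[
    psychoscreen:::strict_majority(scr$features$vip_votes, length(f_names),
                                   cfg$factor_vote_fraction) &
      psychoscreen:::strict_majority(all_votes, length(f_names),
                                     cfg$factor_vote_fraction)
  ]
  expect_setequal(unrestricted, candidates(scr)$feature_id)
})

test_that("raising thresholds never adds a candidate", {
  co <- tiny_cohort(seed = 65, n_taxa = 40)
  norm <- normalize_abundance(co$abundance)
  loose <- screen_quiet(norm, co$panel, run_config(r_threshold = 0.35))
  for (r in c(0.4, 0.5, 0.6)) {
    tight <- rescreen(loose, run_config(r_threshold = r))
    expect_true(all(candidates(tight)$feature_id %in%
                      candidates(loose)$feature_id))
  }
  tight_p <- rescreen(loose, run_config(r_threshold = 0.35,
                                        p_threshold = 1e-5))
  expect_true(all(candidates(tight_p)$feature_id %in%
                    candidates(loose)$feature_id))
  expect_error(rescreen(loose, run_config(r_threshold = 0.1)), "strict")
})

test_that("zero-variance factors are dropped from the vote denominator", {
  co <- tiny_cohort(seed = 66, n_taxa = 25)
  panel <- co$panel
  panel$TMD <- 5
  norm <- normalize_abundance(co$abundance)
  msgs <- capture_messages(scr <- screen_features(norm, panel))
  expect_match(paste(msgs, collapse = " "), "zero-variance factor")
  expect_equal(length(unique(scr$pairs$factor)), 18)
  expect_true(all(scr$features$vip_votes <= 18))
})

test_that("metabolite screen requires VIP >= 1 in every taxon model", {
  co <- tiny_cohort(seed = 67, n_taxa = 50)
  mets <- generate_metabolites(co)
  norm_m <- normalize_abundance(mets)
  norm_t <- normalize_abundance(co$abundance)
  planted <- co$truth$planted$feature_id
  linked <- attr(mets, "links")
  res <- suppressMessages(
    screen_metabolites(norm_m, norm_t[c("sample_id", planted)])
  )
  # linked metabolites out-rank the noise ones
  expect_true(all(linked$metabolite_id %in%
                    res$metabolites$metabolite_id[res$metabolites$key]))
  expect_equal(sort(unique(res$pairs$taxon)), sort(planted))
  # single-taxon degenerate case: conjunction over one model
  res1 <- suppressMessages(
    screen_metabolites(norm_m, norm_t[c("sample_id", planted[1])])
  )
  v1 <- res1$metabolites
  expect_equal(v1$key, v1$min_vip >= 1)
  # unknown taxon id errors
  expect_error(
    suppressMessages(screen_metabolites(norm_m, norm_t[c("sample_id",
                                                         planted)],
                                        taxa_ids = "taxon_999")),
    "absent"
  )
  # allowlist restricts the report, not the fit
  allow <- linked$metabolite_id[1]
  res_allow <- suppressMessages(
    screen_metabolites(norm_m, norm_t[c("sample_id", planted)],
                       allowlist = allow)
  )
  expect_equal(unique(res_allow$pairs$metabolite_id), allow)
  expect_equal(res_allow$metabolites, res$metabolites)
})

test_that("noise metabolites are rarely selected as key", {
  hits <- vapply(1:5, function(s) {
    co <- tiny_cohort(seed = 100 + s, n_taxa = 40)
    mets <- generate_metabolites(co)
    linked <- attr(mets, "links")$metabolite_id
    norm_m <- normalize_abundance(mets)
    norm_t <- normalize_abundance(co$abundance)
    res <- suppressMessages(
      screen_metabolites(norm_m,
                         norm_t[c("sample_id",
                                  co$truth$planted$feature_id)])
    )
    noise_key <- setdiff(res$metabolites$metabolite_id[res$metabolites$key],
                         linked)
    length(noise_key)
  }, numeric(1))
  expect_lte(mean(hits / 45), 0.05)
})
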