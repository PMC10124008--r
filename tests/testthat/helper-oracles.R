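# Independent oracles and small fixture builders used across test files.

# brute-force sample ACF: literal double loop over the defining sum
brute_force_acf <- function(x, max_lag) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  vapply(0:max_lag, function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + (x[t] - xb) * (x[t + k] - xb)
    s / denom
  }, numeric(1))
}

# naive leave-one-out: explicit refit with the public fit/predict interface
naive_loo_predictions <- function(X, y, ncomp, scale = TRUE) {
  vapply(seq_len(nrow(X)), function(i) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp = ncomp,
                   scale = scale)
    predict(fit, X[i, , drop = FALSE])
  }, numeric(1))
}

# small cohort for fast pipeline tests
tiny_cohort <- function(seed = 1, n_taxa = 40, ...) {
  generate_cohort(cohort_config(n_taxa = n_taxa, seed = seed, ...))
}

screen_quiet <- function(...) suppressMessages(screen_features(...))
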