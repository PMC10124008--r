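# NIPALS PLS1 engine: single-response partial least squares with
# leave-one-out Q2/PRESS evaluation and VIP scores.

as_predictor_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) >= 2 && (is.character(x[[1]]) || is.factor(x[[1]]))) {
      return(df_to_matrix(x))
    }
    return(as.matrix(x))
  }
  as.matrix(x)
}

# Core NIPALS recursion on an already centered/scaled X and centered y.
# For PLS1 the response needs no deflation: deflated X stays orthogonal to
# all earlier scores, so X'y is unchanged by removing fitted components
# from y.
nipals_pls1 <- function(X, y, ncomp, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  tt <- numeric(ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break              # no covariance left to model
    w <- w / nw
    t_a <- X %*% w
    tsq <- sum(t_a^2)
    if (tsq < tol) break
    p_a <- crossprod(X, t_a) / tsq
    q_a <- sum(y * t_a) / tsq
    X <- X - tcrossprod(t_a, p_a)
    a <- comp
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a; tt[a] <- tsq
  }
  if (a == 0L) abort("response has no covariance with any predictor")
  keep <- seq_len(a)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Tm = Tm[, keep, drop = FALSE], q = q[keep], tt = tt[keep],
       ncomp = a)
}

center_scale <- function(X, scale) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (scale) {
    sds <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
    dropped <- sds == 0
    sds[dropped] <- 1                # zero-variance column contributes 0
    Xc <- sweep(Xc, 2, sds, "/")
  } else {
    sds <- rep(1, ncol(X))
    dropped <- rep(FALSE, ncol(X))
  }
  list(X = Xc, mu = mu, sds = sds, dropped = dropped)
}

#' Fit a PLS1 regression model by NIPALS
#'
#' Single-response partial least squares: successive components maximize the
#' covariance between the predictor block and the response, deflating the
#' predictors after each component. Predictors are centered (and by default
#' autoscaled to unit variance) internally; the response is centered.
#'
#' @param x Predictors: numeric matrix, or a tibble whose first column is
#'   `sample_id` (dropped) followed by numeric feature columns.
#' @param y Numeric response vector.
#' @param ncomp Number of latent components, at most `min(n - 1, p)`.
#' @param scale Autoscale predictor columns (default `TRUE`). Columns with
#'   zero variance raise an error naming the column.
#' @return A `psy_pls` object with weights `W` (p x A), predictor loadings
#'   `P`, response loadings `q`, scores `T`, regression coefficients
#'   `coefficients` (original predictor scale), `intercept`, and the
#'   centering/scaling constants. `A` may be less than `ncomp` if the
#'   predictor block runs out of covariance with the response.
#' @export
fit_pls <- function(x, y, ncomp, scale = TRUE) {
  X <- as_predictor_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (ncomp > min(n - 1, p)) {
    abort(sprintf("ncomp = %d exceeds min(n - 1, p) = %d",
                  ncomp, min(n - 1, p)))
  }
  cs <- center_scale(X, scale)
  if (scale && any(cs$dropped)) {
    nm <- colnames(X)[cs$dropped]
    abort(paste0("zero-variance column(s) with scale = TRUE: ",
                 paste(head(nm, 5), collapse = ", ")))
  }
  y_mean <- mean(y)
  fit <- nipals_pls1(cs$X, y - y_mean, ncomp)
  # b in the centered/scaled frame, then mapped back to raw predictors
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  b_scaled <- drop(R %*% fit$q)
  b <- b_scaled / cs$sds
  structure(
    list(
      n_components = fit$ncomp,
      W = fit$W, P = fit$P, q = fit$q, T = fit$Tm, tt = fit$tt,
      coefficients = setNames(b, colnames(X)),
      intercept = y_mean - sum(cs$mu * b),
      x_mean = cs$mu, x_scale = cs$sds, y_mean = y_mean,
      scaled = scale, n = n, p = p
    ),
    class = "psy_pls"
  )
}

#' @export
print.psy_pls <- function(x, ...) {
  cat(sprintf("<psy_pls> %d samples, %d predictors, %d component(s)\n",
              x$n, x$p, x$n_components))
  invisible(x)
}

#' @export
predict.psy_pls <- function(object, newdata, ...) {
  X <- as_predictor_matrix(newdata)
  drop(X %*% object$coefficients) + object$intercept
}

#' @method tidy psy_pls
#' @export
tidy.psy_pls <- function(x, ...) {
  vips <- vip(x)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    vip = unname(vips)
  )
}

#' @method glance psy_pls
#' @export
glance.psy_pls <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_samples = x$n,
    n_predictors = x$p
  )
}

#' Variable importance in projection (VIP)
#'
#' Wold's VIP: `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a
#' SS_a )` with the explained response sum of squares `SS_a = q_a^2 (t_a'
#' t_a)`. The squared VIPs average to 1 across predictors, so VIP >= 1 marks
#' a predictor that carries more than its share of the modeled response
#' variance.
#'
#' @param model A fitted `psy_pls` model.
#' @return Named numeric vector of VIP scores, one per predictor.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "psy_pls"))
  ss <- model$q^2 * model$tt
  total <- sum(ss)
  if (total <= 0) abort("degenerate model: no explained response variance")
  wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  v <- sqrt(model$p * drop(wn^2 %*% ss) / total)
  setNames(v, names(model$coefficients))
}

# Cumulative LOO predictions for components 1..max_A in a single pass:
# one NIPALS run per left-out sample, centering/scaling recomputed inside
# the fold to avoid leakage. Returns an n x A matrix of held-out
# predictions (A = smallest component count reached across folds).
pls_loo_path <- function(X, y, max_A, scale = TRUE) {
  n <- nrow(X)
  if (n < max_A + 2) abort("n must be at least max_A + 2 for LOO")
  preds <- matrix(NA_real_, n, max_A)
  reached <- max_A
  any_dropped <- FALSE
  for (i in seq_len(n)) {
    cs <- center_scale(X[-i, , drop = FALSE], scale)
    if (any(cs$dropped)) any_dropped <- TRUE
    y_tr <- y[-i]
    ym <- mean(y_tr)
    fit <- nipals_pls1(cs$X, y_tr - ym, max_A)
    x0 <- (X[i, ] - cs$mu) / cs$sds
    pred <- ym
    for (a in seq_len(fit$ncomp)) {
      t_new <- sum(x0 * fit$W[, a])
      pred <- pred + fit$q[a] * t_new
      preds[i, a] <- pred
      x0 <- x0 - t_new * fit$P[, a]
    }
    if (fit$ncomp < max_A) {        # carry last prediction forward
      preds[i, (fit$ncomp + 1):max_A] <- preds[i, fit$ncomp]
      reached <- min(reached, fit$ncomp)
    }
  }
  if (any_dropped) {
    inform("zero-variance feature(s) inside LOO folds were dropped")
  }
  attr(preds, "reached") <- reached
  preds
}

#' Leave-one-out cross-validation of a PLS1 model
#'
#' Refits the model `n` times, each time holding out one sample and
#' recomputing centering/scaling on the remaining `n - 1` (no leakage), and
#' predicts the held-out response. Reports PRESS, `RMSECV = sqrt(PRESS /
#' n)`, the goodness of prediction `Q2 = 1 - PRESS / sum((y - ybar)^2)`, and
#' the Spearman correlation (R, P) between held-out predictions and the
#' observed response — the per-factor evaluation triplet.
#'
#' @inheritParams fit_pls
#' @param p_method Spearman P-value method, see [spearman_cor()].
#' @return A `psy_pls_cv` object (also a list): `q2`, `rmsecv`, `press`,
#'   `loo_predictions`, `spearman_r`, `spearman_p`, `n_components`.
#' @export
loo_cv <- function(x, y, ncomp, scale = TRUE, p_method = "t_approx") {
  X <- as_predictor_matrix(x)
  y <- as.numeric(y)
  preds <- pls_loo_path(X, y, ncomp, scale)[, ncomp]
  press <- sum((y - preds)^2)
  sp <- spearman_cor(preds, y, p_method = p_method)
  structure(
    list(
      q2 = 1 - press / sum((y - mean(y))^2),
      rmsecv = sqrt(press / length(y)),
      press = press,
      loo_predictions = preds,
      spearman_r = sp$estimate,
      spearman_p = sp$p.value,
      n_components = ncomp
    ),
    class = "psy_pls_cv"
  )
}

#' @export
print.psy_pls_cv <- function(x, ...) {
  cat(sprintf("<psy_pls_cv> A = %d: Q2 = %.4f, RMSECV = %.4f, R = %.4f (P = %.3g)\n",
              x$n_components, x$q2, x$rmsecv, x$spearman_r, x$spearman_p))
  invisible(x)
}

#' @method glance psy_pls_cv
#' @export
glance.psy_pls_cv <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    q2 = x$q2, rmsecv = x$rmsecv, press = x$press,
    spearman_r = x$spearman_r, spearman_p = x$spearman_p
  )
}

#' Select the number of PLS components by leave-one-out Q2
#'
#' Chooses the most parsimonious component count whose Q2 is within `tol`
#' of the best over `1..max_A`. Exact and near ties therefore resolve
#' toward fewer components: on a long flat Q2 plateau a strict argmax would
#' wander into extra components on sampling noise alone.
#'
#' @inheritParams fit_pls
#' @param max_A Largest component count tried; capped at `min(n - 2, p)`.
#' @param tol Q2 slack treated as a tie. Default 0.01.
#' @return Integer `A*`, with the Q2 path attached as attribute `"q2"`.
#' @export
select_components <- function(x, y, max_A = 10, scale = TRUE, tol = 0.01) {
  X <- as_predictor_matrix(x)
  y <- as.numeric(y)
  max_A <- min(max_A, nrow(X) - 2L, ncol(X))
  stopifnot(max_A >= 1)
  preds <- pls_loo_path(X, y, max_A, scale)
  press <- colSums((y - preds)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  a_star <- which(q2 >= max(q2) - tol)[1]
  structure(as.integer(a_star), q2 = q2)
}

#' Spearman rank correlation with a choice of P-value methods
#'
#' R is the Pearson correlation of midranks. The two-sided P-value comes
#' either from the t approximation `t = R sqrt((n - 2) / (1 - R^2))` on
#' `n - 2` degrees of freedom, or from full enumeration of all `n!`
#' orderings (`exact_perm`, n <= 8 only): the fraction of permutations with
#' |R| at least as large as observed.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`. Ties are handled by
#'   midranks.
#' @param p_method `"t_approx"` (default) or `"exact_perm"`.
#' @return List with `estimate` (R) and `p.value`.
#' @export
spearman_cor <- function(x, y, p_method = c("t_approx", "exact_perm")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4) abort("need at least 4 observations")
  if (var(x) == 0 || var(y) == 0) {
    abort("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  r <- cor(rx, ry)
  if (p_method == "t_approx") {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
  } else {
    if (n > 8) abort("exact_perm enumeration only supported for n <= 8")
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    num <- perms_apply(perms, ryc, rxc)
    r_all <- num / (sqrt(sum(rxc^2)) * sqrt(sum(ryc^2)))
    p <- mean(abs(r_all) >= abs(r) - 1e-12)
  }
  list(estimate = r, p.value = p)
}

# all permutations of 1..n as an (n!) x n integer matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- seq(row, row + nrow(sub) - 1L)
    out[block, pos] <- n
    out[block, -pos] <- sub
    row <- row + nrow(sub)
  }
  out
}

# sum over permuted yc times fixed xc, vectorized across permutations
perms_apply <- function(perms, yc, xc) {
  Y <- matrix(yc[perms], nrow = nrow(perms))
  drop(Y %*% xc)
}

# Single LOO pass per response: Q2 path over 1..max_A, A* the smallest
# count within tol of the best Q2, evaluation triplet at A*.
pls_factor_eval <- function(X, y, config, tol = 0.01) {
  max_A <- min(config$max_components, nrow(X) - 2L, ncol(X))
  preds <- pls_loo_path(X, y, max_A, scale = config$scale)
  press <- colSums((y - preds)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  a_star <- which(q2 >= max(q2) - tol)[1]
  loo_pred <- preds[, a_star]
  sp <- spearman_cor(loo_pred, y, p_method = config$p_method)
  list(
    n_components = as.integer(a_star),
    q2 = q2[a_star], q2_path = q2,
    press = press[a_star], rmsecv = sqrt(press[a_star] / length(y)),
    loo_predictions = loo_pred,
    spearman_r = sp$estimate, spearman_p = sp$p.value
  )
}

#' Per-factor PLS evaluation table
#'
#' For each mood factor, selects the component count by LOO Q2, refits, and
#' reports the evaluation triplet (Q2, Spearman R, Spearman P between
#' held-out predictions and observed scores) plus RMSECV and the chosen
#' component count — one row per factor.
#'
#' @param features Normalized samples-by-features tibble (`sample_id`
#'   first).
#' @param panel Mood panel tibble aligned with `features`.
#' @param config A [run_config()].
#' @return Tibble: `factor`, `n_components`, `q2`, `rmsecv`, `spearman_r`,
#'   `spearman_p`.
#' @export
pls_evaluation_table <- function(features, panel, config = run_config()) {
  X <- df_to_matrix(features)
  check_aligned(rownames(X), panel$sample_id)
  factors <- setdiff(names(panel), "sample_id")
  purrr::map_dfr(factors, function(f) {
    ev <- pls_factor_eval(X, panel[[f]], config)
    tibble::tibble(
      factor = f, n_components = ev$n_components,
      q2 = ev$q2, rmsecv = ev$rmsecv,
      spearman_r = ev$spearman_r, spearman_p = ev$spearman_p
    )
  })
}
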