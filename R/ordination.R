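#' PCA ordination of a normalized feature table
#'
#' Principal component analysis (centered, unscaled) of a samples-by-features
#' tibble via the singular value decomposition.
#'
#' @param data Tibble `sample_id` + numeric feature columns (normalize
#'   first with [normalize_abundance()]).
#' @param k Number of components to keep; at most `min(n - 1, p)`.
#' @return A `psy_pca` object: `scores` tibble (`sample_id`, `PC1..PCk`),
#'   `loadings` tibble (`feature_id`, `PC1..PCk`), and
#'   `explained_variance_fraction`.
#' @export
pca_ordination <- function(data, k = 2) {
  m <- df_to_matrix(data)
  k_max <- min(nrow(m) - 1L, ncol(m))
  if (k > k_max) {
    abort(sprintf("k = %d exceeds min(n - 1, p) = %d", k, k_max))
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  scores <- matrix_to_df(fit$x[, seq_len(k), drop = FALSE])
  loadings <- matrix_to_df(fit$rotation[, seq_len(k), drop = FALSE],
                           id_col = "feature_id")
  structure(
    list(
      scores = scores,
      loadings = loadings,
      explained_variance_fraction = ev[seq_len(k)] / sum(ev),
      center = fit$center
    ),
    class = "psy_pca"
  )
}

#' @export
print.psy_pca <- function(x, ...) {
  k <- length(x$explained_variance_fraction)
  cat(sprintf("<psy_pca> %d samples, %d components\n",
              nrow(x$scores), k))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy psy_pca
#' @export
tidy.psy_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample_id",
                      names_to = "component", values_to = "score")
}

#' @method glance psy_pca
#' @export
glance.psy_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$explained_variance_fraction),
    total_explained = sum(x$explained_variance_fraction)
  )
}

#' @method autoplot psy_pca
#' @export
autoplot.psy_pca <- function(object, groups = NULL, ...) {
  df <- object$scores
  ev <- object$explained_variance_fraction
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
}

#' MANOVA on ordination scores with Mahalanobis group distances
#'
#' One-way multivariate analysis of variance on PCA score columns: Wilks'
#' lambda `det(W) / det(W + B)` (W, B the within/between-group SSCP
#' matrices), P-value from Bartlett's chi-square approximation
#' `-(n - 1 - (k + g)/2) log(lambda) ~ chi2(k (g - 1))`. Group separation is
#' summarized by the Mahalanobis distance between group means under the
#' pooled within-group covariance, and the groups are hierarchically
#' clustered on that distance (average linkage; labels sorted
#' lexicographically beforehand so merge order is reproducible).
#'
#' @param scores A `psy_pca` object or a tibble `sample_id` + numeric score
#'   columns.
#' @param groups Character vector of group labels, one per sample in row
#'   order.
#' @param p_approx P-value approximation: `"bartlett"` (chi-square, default)
#'   or `"rao"` (Rao's F transform, exact when k <= 2 or g <= 2; at k = 1
#'   with two groups it reproduces the univariate F test).
#' @return A `psy_manova` object with `wilks_lambda`, `df` (dimension k,
#'   groups g, samples n), `p_value`, `distances` (groups x groups matrix),
#'   `dendrogram` (an `hclust`).
#' @export
manova_groups <- function(scores, groups,
                          p_approx = c("bartlett", "rao")) {
  p_approx <- match.arg(p_approx)
  if (inherits(scores, "psy_pca")) scores <- scores$scores
  m <- df_to_matrix(scores)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least 2 groups")
  if (any(tab < 2)) abort("every group needs at least 2 samples")
  n <- nrow(m); k <- ncol(m); g <- length(tab)
  if (k >= n - g + 1) abort("too many score dimensions for the group sizes")

  grand <- colMeans(m)
  means <- rowsum(m, groups) / as.vector(tab[sort(unique(groups))])
  cm <- m - means[groups, , drop = FALSE]
  W <- crossprod(cm)
  dev <- sweep(means, 2, grand)
  B <- crossprod(dev * sqrt(as.vector(tab[rownames(means)])))
  pooled <- W / (n - g)
  if (rcond_ok(pooled)) {
    pooled_inv <- solve(pooled)
  } else {
    abort("singular pooled within-group covariance; reduce k")
  }
  lambda <- det(W) / det(W + B)
  chi2 <- -(n - 1 - (k + g) / 2) * log(lambda)
  if (p_approx == "bartlett") {
    p <- pchisq(chi2, df = k * (g - 1), lower.tail = FALSE)
  } else {
    q <- g - 1
    tt <- if (k^2 + q^2 - 5 > 0) {
      sqrt((k^2 * q^2 - 4) / (k^2 + q^2 - 5))
    } else 1
    w <- n - 1 - (k + g) / 2
    df1 <- k * q
    df2 <- w * tt - (k * q - 2) / 2
    lam_t <- lambda^(1 / tt)
    fstat <- (1 - lam_t) / lam_t * df2 / df1
    p <- pf(fstat, df1, df2, lower.tail = FALSE)
  }

  labs <- rownames(means)
  D <- matrix(0, g, g, dimnames = list(labs, labs))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      d <- means[i, ] - means[j, ]
      D[i, j] <- D[j, i] <- sqrt(drop(t(d) %*% pooled_inv %*% d))
    }
  }
  ord <- order(labs)
  D <- D[ord, ord]
  dend <- hclust(as.dist(D), method = "average")
  structure(
    list(
      wilks_lambda = lambda,
      chi2 = chi2,
      df = c(k = k, g = g, n = n),
      p_value = p,
      group_means = matrix_to_df(means, id_col = "group"),
      distances = D,
      dendrogram = dend
    ),
    class = "psy_manova"
  )
}

rcond_ok <- function(m, tol = 1e-12) {
  is.finite(rcond(m)) && rcond(m) > tol
}

#' @export
print.psy_manova <- function(x, ...) {
  cat(sprintf(
    "<psy_manova> Wilks' lambda = %.4f, chi2(%d) = %.2f, p = %.3g\n",
    x$wilks_lambda, x$df[["k"]] * (x$df[["g"]] - 1), x$chi2, x$p_value
  ))
  invisible(x)
}

#' @method tidy psy_manova
#' @export
tidy.psy_manova <- function(x, ...) {
  labs <- rownames(x$distances)
  expand.grid(group1 = labs, group2 = labs,
              stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::filter(.data$group1 < .data$group2) |>
    dplyr::mutate(mahalanobis = x$distances[cbind(.data$group1,
                                                  .data$group2)])
}

#' @method glance psy_manova
#' @export
glance.psy_manova <- function(x, ...) {
  tibble::tibble(
    wilks_lambda = x$wilks_lambda,
    chi2 = x$chi2,
    df = x$df[["k"]] * (x$df[["g"]] - 1),
    p_value = x$p_value,
    n_groups = x$df[["g"]],
    n_samples = x$df[["n"]]
  )
}

#' Export the group dendrogram in Newick format
#'
#' @param x A `psy_manova` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(x, path) {
  stopifnot(inherits(x, "psy_manova"))
  phy <- ape::as.phylo(x$dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}
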