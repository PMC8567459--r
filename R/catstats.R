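# Desk-scale category dispersion statistics on feature tables, with Hu
# moment shape descriptors for binary masks and a synthetic feature-table
# generator.

#' Hu moment invariants of a binary mask
#'
#' The seven classic region-based shape descriptors: arithmetic
#' combinations of normalized central image moments that are invariant to
#' translation, scaling, and rotation of the mask.
#'
#' @param mask Numeric/logical matrix; nonzero entries are foreground.
#' @return Numeric vector of the seven invariants.
#' @export
hu_moments <- function(mask) {
  m <- (as.matrix(mask) != 0) * 1
  if (sum(m) == 0) stop("empty mask")
  xs <- row(m); ys <- col(m)
  m00 <- sum(m)
  cx <- sum(xs * m) / m00
  cy <- sum(ys * m) / m00
  mu <- function(p, q) sum((xs - cx)^p * (ys - cy)^q * m)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

#' Column-wise z-scoring of a feature table
#'
#' @param table Data frame with a `category` column and numeric feature
#'   columns.
#' @return The table with each feature column centred to mean zero and
#'   scaled to unit standard deviation.
#' @export
normalize_features <- function(table) {
  feats <- setdiff(names(table), "category")
  for (f in feats) {
    v <- table[[f]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance feature column: ", f)
    table[[f]] <- (v - mean(v)) / s
  }
  table
}

#' Dispersion correlations across categories
#'
#' For each category (with at least `min_per_category` objects; smaller
#' categories are dropped with a warning) computes the per-dimension
#' standard deviations, then the Spearman rank correlation of those
#' standard-deviation vectors across categories for every dimension pair.
#' Positively correlated variability is the signature of integral dimension
#' pairs; near-zero correlation of separable pairs.
#'
#' @param table Feature table (column `category` plus numeric features).
#' @param min_per_category Minimum objects per analyzed category.
#' @param rotate_pca Re-express the features as principal components before
#'   the analysis (robustness check for descriptor axes that may not be the
#'   psychological ones)?
#' @return List with `spearman` (correlation matrix), `sd_by_category`
#'   (matrix), `ellipses` (per-category means and covariances for the first
#'   feature pair), and `dropped` categories.
#' @export
dispersion_correlations <- function(table, min_per_category = 4L,
                                    rotate_pca = FALSE) {
  feats <- setdiff(names(table), "category")
  if (rotate_pca) {
    pc <- stats::prcomp(as.matrix(table[feats]), center = TRUE,
                        scale. = FALSE)
    rotated <- as.data.frame(pc$x)
    names(rotated) <- paste0("pc", seq_along(feats))
    table <- cbind(table["category"], rotated)
    feats <- names(rotated)
  }
  sizes <- table(table$category)
  dropped <- names(sizes)[sizes < min_per_category]
  if (length(dropped) > 0)
    warning("dropping categories with fewer than ", min_per_category,
            " objects: ", paste(dropped, collapse = ", "))
  keep <- setdiff(names(sizes), dropped)
  if (length(keep) < 3L) stop("need at least three analyzable categories")
  sds <- t(vapply(keep, function(cat) {
    sub <- table[table$category == cat, feats, drop = FALSE]
    vapply(sub, stats::sd, numeric(1))
  }, numeric(length(feats))))
  rownames(sds) <- keep
  ellipses <- lapply(keep, function(cat) {
    sub <- as.matrix(table[table$category == cat, feats[1:2], drop = FALSE])
    list(center = colMeans(sub), cov = stats::cov(sub))
  })
  names(ellipses) <- keep
  list(spearman = stats::cor(sds, method = "spearman"),
       sd_by_category = sds, ellipses = ellipses, dropped = dropped)
}

#' Synthetic category feature tables with controlled dispersion structure
#'
#' Emulates the dispersion statistics of natural categories: in the
#' `integral` regime all dimensions of a category share one dispersion
#' scale (positively correlated variability across categories); in the
#' `separable` regime each category is singly narrow, with independent
#' per-dimension dispersions; `mixed` makes the first two dimensions an
#' integral pair and the rest separable.
#'
#' @param n_categories,n_per_category Table size.
#' @param regime `"separable"`, `"integral"`, or `"mixed"`.
#' @param n_dims Number of feature dimensions.
#' @param seed Integer seed.
#' @return Data frame with `category` and feature columns `f1..fD`.
#' @export
synth_category_table <- function(n_categories = 50L, n_per_category = 20L,
                                 regime = c("separable", "integral",
                                            "mixed"),
                                 n_dims = 4L, seed = 1L) {
  regime <- match.arg(regime)
  withr_seed(seed, {
    rows <- list()
    for (cat in seq_len(n_categories)) {
      center <- stats::runif(n_dims, -3, 3)
      sds <- switch(regime,
        integral = {
          scale <- stats::rlnorm(1L, 0, 0.6)
          scale * stats::rlnorm(n_dims, 0, 0.15)
        },
        separable = {
          narrow <- sample.int(n_dims, 1L)
          s <- stats::rlnorm(n_dims, 0, 0.3)
          s[narrow] <- 0.1 * s[narrow]
          s
        },
        mixed = {
          scale <- stats::rlnorm(1L, 0, 0.6)
          s <- numeric(n_dims)
          s[1:2] <- scale * stats::rlnorm(2L, 0, 0.15)
          rest <- seq_len(n_dims)[-(1:2)]
          sr <- stats::rlnorm(length(rest), 0, 0.3)
          if (length(rest) > 0 && stats::runif(1) < 0.5)
            sr[sample.int(length(rest), 1L)] <-
              0.1 * sr[sample.int(length(rest), 1L)]
          s[rest] <- sr
          s
        })
      pts <- sweep(matrix(stats::rnorm(n_per_category * n_dims),
                          n_per_category) %*% diag(sds, n_dims),
                   2L, center, `+`)
      rows[[cat]] <- data.frame(category = sprintf("cat%03d", cat), pts)
    }
    out <- do.call(rbind, rows)
    names(out) <- c("category", paste0("f", seq_len(n_dims)))
    out
  })
}

#' Median off-diagonal dispersion correlation
#'
#' Convenience summary of [dispersion_correlations()]: the median Spearman
#' correlation over distinct dimension pairs.
#'
#' @param table Feature table.
#' @param ... Passed to [dispersion_correlations()].
#' @return A single number.
#' @export
median_dispersion_correlation <- function(table, ...) {
  sp <- dispersion_correlations(table, ...)$spearman
  stats::median(sp[upper.tri(sp)])
}
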