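# Probability primitives: CRP and hierarchical-CRP priors, inverse-Wishart,
# multivariate normal, truncated normal, and exact partition combinatorics.

#' Chinese restaurant process parameters
#'
#' Bundle of the three dispersion parameters used by the two-level clustering
#' prior: `alpha` governs the item-to-cluster partition within a context,
#' `alpha_c` the probability of bringing an existing covariance component into
#' the current context, and `alpha_g` the probability of creating a brand-new
#' component. `alpha_c = Inf` removes the contextual prior (clusters draw
#' components directly from the global distribution); `alpha_g = 0` is only
#' legal when a finite fixed component set is supplied.
#'
#' @param alpha Positive dispersion for the item-level partition.
#' @param alpha_c Positive dispersion (or `Inf`) for reusing components within
#'   a context.
#' @param alpha_g Nonnegative dispersion for creating new components.
#' @return An object of class `crp_params`.
#' @export
crp_params <- function(alpha = 10, alpha_c = 0.001, alpha_g = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive finite number")
  if (!is.numeric(alpha_c) || length(alpha_c) != 1L || alpha_c <= 0)
    stop("`alpha_c` must be positive (possibly Inf)")
  if (!is.numeric(alpha_g) || length(alpha_g) != 1L || !is.finite(alpha_g) || alpha_g < 0)
    stop("`alpha_g` must be a nonnegative finite number")
  structure(list(alpha = alpha, alpha_c = alpha_c, alpha_g = alpha_g),
            class = "crp_params")
}

#' Canonicalize a partition to restricted-growth form
#'
#' Cluster ids are relabelled 1, 2, ... in order of first appearance so that
#' two assignment vectors describing the same set partition compare equal.
#'
#' @param z Integer vector of cluster assignments.
#' @return Integer vector in restricted-growth form.
#' @export
canonical_partition <- function(z) {
  z <- as.integer(z)
  if (length(z) == 0L) return(integer(0))
  match(z, unique(z))
}

partition_counts <- function(z) {
  z <- canonical_partition(z)
  as.integer(tabulate(z))
}

validate_partition <- function(z) {
  z <- as.integer(z)
  if (length(z) > 0L && !identical(z, canonical_partition(z)))
    stop("partition is not in canonical (restricted-growth) form")
  z
}

#' CRP assignment probabilities for the next item
#'
#' Given the current partition of `n - 1` items, returns the prior probability
#' that item `n` joins each existing cluster (proportional to cluster size)
#' or starts a new one (proportional to `alpha`).
#'
#' @param counts Integer vector of existing cluster sizes (may be empty).
#' @param alpha Positive dispersion parameter.
#' @return Numeric vector of length `length(counts) + 1`; the last entry is
#'   the new-cluster probability. Sums to one.
#' @export
crp_assignment_probs <- function(counts, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number")
  counts <- as.numeric(counts)
  if (any(counts < 1)) stop("cluster counts must all be >= 1")
  w <- c(counts, alpha)
  w / sum(w)
}

#' Joint log probability of a partition under the CRP
#'
#' Computed as the product of sequential seating probabilities; by
#' exchangeability the result depends only on the multiset of cluster sizes.
#'
#' @param z Integer assignment vector (any labelling; canonicalized
#'   internally).
#' @param alpha Positive dispersion parameter.
#' @return Log probability of the partition.
#' @export
crp_joint_logprob <- function(z, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number")
  z <- canonical_partition(z)
  n <- length(z)
  if (n == 0L) return(0)
  counts <- partition_counts(z)
  k <- length(counts)
  # exchangeable product form: alpha^K * prod (M_k - 1)! / prod_i (i - 1 + alpha)
  k * log(alpha) + sum(lgamma(counts)) - sum(log(seq_len(n) - 1 + alpha))
}

#' Component choice probabilities under the hierarchical CRP
#'
#' A new cluster in a context picks component `j` with probability
#' proportional to (number of clusters in this context already using `j`) +
#' `alpha_c` times the global weight of `j`. When `alpha_g > 0` the global
#' distribution reserves mass `alpha_g` for a brand-new component and an
#' extra slot is appended for it; with `alpha_g = 0` a finite fixed component
#' set with the supplied (by default equal) global weights is assumed.
#'
#' @param context_counts Nonnegative per-component cluster counts in the
#'   current context.
#' @param params A [crp_params()] object.
#' @param global_usage Per-component global usage (cluster counts across all
#'   contexts). Defaults to equal weights, which is the fixed-set convention.
#' @return Probability vector over components (plus one trailing
#'   new-component slot when `alpha_g > 0`).
#' @export
hcrp_component_probs <- function(context_counts, params,
                                 global_usage = NULL) {
  stopifnot(inherits(params, "crp_params"))
  m <- as.numeric(context_counts)
  if (any(m < 0)) stop("context counts must be nonnegative")
  j <- length(m)
  if (is.null(global_usage)) {
    if (params$alpha_g > 0)
      global_usage <- rep(0, j)
    else
      global_usage <- rep(1, j)
  }
  g <- as.numeric(global_usage)
  if (length(g) != j) stop("global usage length must match context counts")
  if (params$alpha_g > 0) {
    gw <- c(g, params$alpha_g)
    gw <- gw / sum(gw)
    if (is.infinite(params$alpha_c)) return(gw)
    score <- c(m, 0) + params$alpha_c * gw
    return(score / sum(score))
  }
  if (j == 0L)
    stop("alpha_g = 0 requires a fixed, nonempty component set")
  if (sum(g) <= 0) stop("global weights must have positive mass")
  gw <- g / sum(g)
  if (is.infinite(params$alpha_c)) return(gw)
  score <- m + params$alpha_c * gw
  score / sum(score)
}

## ---- multivariate normal -------------------------------------------------

#' Log density of a multivariate normal
#'
#' @param x Numeric matrix (rows are points) or a single vector.
#' @param mean Mean vector.
#' @param sigma Covariance matrix (symmetric positive definite).
#' @return Numeric vector of log densities.
#' @export
dmvnorm_log <- function(x, mean, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  ch <- chol_spd(sigma)
  logdet <- 2 * sum(log(diag(ch)))
  centred <- sweep(x, 2L, mean)
  z <- backsolve(ch, t(centred), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
}

# Cholesky with a tiny jitter retry for near-singular matrices.
chol_spd <- function(sigma, jitter = 1e-10) {
  sigma <- (sigma + t(sigma)) / 2
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(sigma + diag(jitter, nrow(sigma))),
                   error = function(e) NULL)
    if (is.null(ch)) stop("matrix is not positive definite")
  }
  ch
}

#' Test whether a matrix is symmetric positive definite
#'
#' @param x Square numeric matrix.
#' @param tol Symmetry tolerance.
#' @return Logical.
#' @export
is_spd <- function(x, tol = 1e-8) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) return(FALSE)
  if (max(abs(x - t(x))) > tol * max(1, max(abs(x)))) return(FALSE)
  !is.null(tryCatch(chol((x + t(x)) / 2), error = function(e) NULL))
}

## ---- inverse-Wishart -----------------------------------------------------

lmvgamma <- function(a, d) {
  (d * (d - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

#' Inverse-Wishart log density
#'
#' Parameterized so that the mode of the distribution is
#' `scale / (dof + d + 1)` and, for `dof > d + 1`, the mean is
#' `scale / (dof - d - 1)`.
#'
#' @param x Symmetric positive-definite matrix.
#' @param scale Symmetric positive-definite scale matrix.
#' @param dof Degrees of freedom, `dof > d - 1`.
#' @return Log density.
#' @export
iw_logpdf <- function(x, scale, dof) {
  d <- nrow(scale)
  if (dof <= d - 1) stop("`dof` must exceed dim - 1")
  if (!is_spd(x)) stop("`x` must be symmetric positive definite")
  chx <- chol_spd(x)
  chs <- chol_spd(scale)
  logdet_x <- 2 * sum(log(diag(chx)))
  logdet_s <- 2 * sum(log(diag(chs)))
  xinv <- chol2inv(chx)
  (dof / 2) * logdet_s - (dof * d / 2) * log(2) - lmvgamma(dof / 2, d) -
    ((dof + d + 1) / 2) * logdet_x - 0.5 * sum(diag(scale %*% xinv))
}

#' Sample from an inverse-Wishart distribution
#'
#' Draws `Sigma` with `Sigma^{-1} ~ Wishart(dof, scale^{-1})`, so that
#' `E[Sigma] = scale / (dof - d - 1)` when that mean exists.
#'
#' @param n Number of draws.
#' @param scale SPD scale matrix.
#' @param dof Degrees of freedom.
#' @return A `d x d x n` array (or a single matrix when `n = 1`).
#' @export
iw_sample <- function(n, scale, dof) {
  d <- nrow(scale)
  if (dof <= d - 1) stop("`dof` must exceed dim - 1")
  sinv <- chol2inv(chol_spd(scale))
  w <- stats::rWishart(n, df = dof, Sigma = (sinv + t(sinv)) / 2)
  out <- array(apply(w, 3L, function(m) chol2inv(chol_spd(m))), dim = dim(w))
  if (n == 1L) out[, , 1L] else out
}

#' Mode of an inverse-Wishart distribution
#'
#' @param scale SPD scale matrix.
#' @param dof Degrees of freedom.
#' @return `scale / (dof + d + 1)`.
#' @export
iw_mode <- function(scale, dof) scale / (dof + nrow(scale) + 1)

## ---- truncated normal ----------------------------------------------------

#' Truncated normal density (truncated from below)
#'
#' @param x Evaluation points.
#' @param mean,sd Location and scale of the parent normal.
#' @param lower Lower truncation point (support is `[lower, Inf)`).
#' @param log Return log density?
#' @return (Log) density, zero (`-Inf`) below `lower`.
#' @export
dtruncnorm <- function(x, mean, sd, lower = -Inf, log = FALSE) {
  if (sd <= 0) stop("`sd` must be positive")
  lz <- stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
  ld <- stats::dnorm(x, mean, sd, log = TRUE) - lz
  ld[x < lower] <- -Inf
  if (log) ld else exp(ld)
}

#' Draw from a lower-truncated normal by inversion
#'
#' @inheritParams dtruncnorm
#' @param n Number of draws.
#' @return Numeric vector of draws, all `>= lower`.
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf) {
  if (sd <= 0) stop("`sd` must be positive")
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  pmax(stats::qnorm(u, mean, sd), lower)
}

## ---- partition combinatorics ---------------------------------------------

#' Enumerate all set partitions of n items
#'
#' Partitions are generated as restricted-growth strings in lexicographic
#' order, so the list is exhaustive, duplicate-free, and canonical.
#'
#' @param n Number of items.
#' @param cap Refuse above this size (Bell numbers grow super-exponentially).
#' @return A list of integer assignment vectors; length equals `Bell(n)`.
#' @export
enumerate_partitions <- function(n, cap = 10L) {
  if (n < 1) stop("`n` must be a positive integer")
  if (n > cap)
    stop("refusing to enumerate partitions of ", n,
         " items (Bell numbers explode); raise `cap` deliberately if needed")
  out <- vector("list", 0L)
  rec <- function(prefix, maxid) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (k in seq_len(maxid + 1L))
      rec(c(prefix, k), max(maxid, k))
  }
  rec(integer(0), 0L)
  out
}

## Exact big-integer arithmetic (nonnegative, base 1e9 little-endian digit
## vectors) -- only addition is needed for the Bell triangle.

big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  base <- 1e9
  digits <- numeric(0)
  while (x > 0) {
    digits <- c(digits, x %% base)
    x <- x %/% base
  }
  digits
}

big_add <- function(a, b) {
  base <- 1e9
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- ifelse(s[i] >= base, 1, 0)
    s[i] <- s[i] - carry * base
  }
  if (carry > 0) s <- c(s, carry)
  s
}

big_to_character <- function(x) {
  parts <- sprintf("%09.0f", rev(x))
  parts[1] <- sub("^0+(?=\\d)", "", parts[1], perl = TRUE)
  paste0(parts, collapse = "")
}

#' Exact Bell numbers via the Bell triangle
#'
#' Computed with exact big-integer addition, so the result is correct to the
#' last digit for any `n` (the count of set partitions of 100 items has 116
#' digits).
#'
#' @param n Nonnegative integer.
#' @param as_character Return the exact decimal string instead of a (possibly
#'   rounded) double?
#' @return Bell number of `n`.
#' @export
bell_number <- function(n, as_character = FALSE) {
  if (n < 0) stop("`n` must be nonnegative")
  if (n <= 1) return(if (as_character) "1" else 1)
  row <- list(big_from_int(1))
  for (i in seq_len(n - 1L)) {
    nxt <- vector("list", length(row) + 1L)
    nxt[[1L]] <- row[[length(row)]]
    for (j in seq_along(row))
      nxt[[j + 1L]] <- big_add(nxt[[j]], row[[j]])
    row <- nxt
  }
  ans <- big_to_character(row[[length(row)]])
  if (as_character) return(ans)
  as.numeric(ans)
}

#' Scientific-notation string for an exact decimal integer
#'
#' The mantissa is truncated (not rounded) to the requested number of
#' significant digits — the usual convention when quoting astronomically
#' large counts as a lower bound.
#'
#' @param x Decimal integer string (as from `bell_number(..., as_character =
#'   TRUE)`).
#' @param digits Significant digits to keep.
#' @return String like `"4.7e115"`.
#' @export
big_scientific <- function(x, digits = 2) {
  x <- as.character(x)
  expo <- nchar(x) - 1L
  digs <- substr(x, 1, min(nchar(x), digits))
  mant <- as.numeric(paste0(substr(digs, 1, 1), ".", substring(digs, 2)))
  paste0(format(mant), "e", expo)
}
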