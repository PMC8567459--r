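# Similarity between stimuli under the posterior over cluster hypotheses,
# iso-similarity fields, Minkowski-metric fitting, convexity and
# triangle-inequality diagnostics, and d-prime.

# Draw the "hypothesis kit" for one posterior snapshot: one covariance per
# available component (existing components sampled from their
# inverse-Wishart, plus one fresh top-level draw for the new-component
# slot), with hierarchical-CRP global weights.
sample_hypothesis_kit <- function(snapshot, hyper) {
  crp <- hyper$crp
  g <- snapshot$gusage
  total <- sum(g) + crp$alpha_g
  covs <- list(); wts <- numeric(0)
  for (j in seq_along(snapshot$comps)) {
    covs[[length(covs) + 1L]] <-
      iw_sample(1L, snapshot$comps[[j]]$scale, snapshot$comps[[j]]$dof)
    wts <- c(wts, g[[j]] / total)
  }
  if (crp$alpha_g > 0) {
    fresh <- draw_component_prior(hyper)
    covs[[length(covs) + 1L]] <- iw_sample(1L, fresh$scale, fresh$dof)
    wts <- c(wts, crp$alpha_g / total)
  }
  list(covs = covs, weights = wts / sum(wts))
}

# Fixed-kit variant for trained component sets (no sampling involved).
fixed_hypothesis_kit <- function(components) {
  j <- length(components$matrices)
  list(covs = components$matrices, weights = rep(1 / j, j))
}

kit_similarity <- function(kit, x, xstar_mat, hyper) {
  d <- length(x)
  n_h <- length(kit$covs)
  # p(h | x): component weight times marginal density of x under an empty
  # cluster of that component
  lph <- vapply(seq_len(n_h), function(h)
    log(kit$weights[[h]]) +
      cluster_predictive_fixed_cov(x, NULL, kit$covs[[h]], hyper),
    numeric(1))
  ph <- exp(lph - max(lph)); ph <- ph / sum(ph)
  # p(x* in C | x, h): graded-region membership of x* in x's cluster, the
  # posterior-predictive Gaussian normalized to one at its center
  s <- numeric(nrow(xstar_mat))
  prior_prec <- diag(d) / hyper$sigma_r2
  for (h in seq_len(n_h)) {
    if (ph[[h]] <= 0) next
    sig_inv <- chol2inv(chol_spd(kit$covs[[h]]))
    v1 <- chol2inv(chol_spd(prior_prec + sig_inv))
    m1 <- drop(v1 %*% (prior_prec %*% hyper$omega + sig_inv %*% x))
    pred_prec <- chol2inv(chol_spd(kit$covs[[h]] + v1))
    dev <- sweep(xstar_mat, 2L, m1)
    quad <- rowSums((dev %*% pred_prec) * dev)
    s <- s + ph[[h]] * exp(-quad / 2)
  }
  s
}

#' Similarity between stimuli under a posterior
#'
#' Similarity is the probability that `x_star` belongs to the same (graded)
#' cluster as `x`: hypotheses are the cluster types (covariance components)
#' that could host `x` in a fresh context, weighted by their posterior
#' probability given `x`; under each hypothesis the membership of `x_star`
#' in `x`'s cluster is the posterior-predictive Gaussian normalized to one
#' at its center, the graded generalization of an all-or-none consequential
#' region. Averaged over posterior snapshots (and optionally over the two
#' role assignments of the pair).
#'
#' @param x,x_star Stimulus vectors.
#' @param posterior An `fr_posterior` (from [run_gibbs()] or
#'   [prior_sample_set()]), or a [component_set()] for the trained model.
#' @param hyper An [fr_hyper()].
#' @param symmetrize Average over the two assignments of the stimuli to the
#'   reference and query roles?
#' @param seed Integer seed for the per-snapshot covariance draws.
#' @return Similarity in `[0, 1]`.
#' @export
similarity <- function(x, x_star, posterior, hyper, symmetrize = FALSE,
                       seed = 1L) {
  f <- similarity_fun(posterior, hyper, seed = seed)
  s <- f(x, matrix(x_star, 1L))
  if (symmetrize) s <- (s + f(x_star, matrix(x, 1L))) / 2
  drop(s)
}

#' Build a reusable similarity evaluator
#'
#' Returns a function `(x, xstar_mat) -> similarity vector` with the
#' per-snapshot covariance draws fixed by `seed`, so different query points
#' share one hypothesis sample.
#'
#' @inheritParams similarity
#' @return A function of a reference point and a query matrix.
#' @export
similarity_fun <- function(posterior, hyper, seed = 1L) {
  kits <- if (inherits(posterior, "component_set")) {
    list(fixed_hypothesis_kit(posterior))
  } else {
    stopifnot(inherits(posterior, "fr_posterior"))
    withr_seed(seed, lapply(posterior$samples, sample_hypothesis_kit,
                            hyper = hyper))
  }
  function(x, xstar_mat) {
    xstar_mat <- if (is.null(dim(xstar_mat))) matrix(xstar_mat, 1L) else
      as.matrix(xstar_mat)
    s <- numeric(nrow(xstar_mat))
    for (kit in kits) s <- s + kit_similarity(kit, x, xstar_mat, hyper)
    s / length(kits)
  }
}

#' Iso-similarity field around a reference stimulus
#'
#' Evaluates [similarity()] on a regular two-dimensional grid slice through
#' the reference, with any unplotted dimensions clamped to fixed values.
#'
#' @param posterior An `fr_posterior` or [component_set()].
#' @param hyper An [fr_hyper()].
#' @param reference Reference stimulus (field center).
#' @param pair Indices of the two plotted dimensions.
#' @param half_width Grid half-extent per plotted dimension.
#' @param n_grid Grid points per axis.
#' @param fixed_values Values of unplotted dimensions (default: the
#'   reference's).
#' @param seed Integer seed for the hypothesis draws.
#' @return An object of class `similarity_field`: list with `reference`,
#'   `ax1`, `ax2`, `pair`, and `values` (an `n_grid` by `n_grid` matrix in
#'   `[0, 1]`).
#' @export
iso_similarity_field <- function(posterior, hyper, reference,
                                 pair = c(1L, 2L), half_width = 2,
                                 n_grid = 17L, fixed_values = NULL,
                                 seed = 1L) {
  reference <- as.numeric(reference)
  d <- hyper$dim
  if (is.null(fixed_values)) fixed_values <- reference
  ax1 <- reference[pair[1]] + seq(-half_width, half_width,
                                  length.out = n_grid)
  ax2 <- reference[pair[2]] + seq(-half_width, half_width,
                                  length.out = n_grid)
  grid2 <- as.matrix(expand.grid(a = ax1, b = ax2))
  pts <- matrix(rep(fixed_values, each = nrow(grid2)), nrow(grid2), d)
  pts[, pair[1]] <- grid2[, 1]
  pts[, pair[2]] <- grid2[, 2]
  f <- similarity_fun(posterior, hyper, seed = seed)
  vals <- f(reference, pts)
  structure(list(reference = reference, ax1 = ax1, ax2 = ax2, pair = pair,
                 values = matrix(vals, n_grid, n_grid)),
            class = "similarity_field")
}

#' Forward-generate a similarity field from a Minkowski metric
#'
#' Useful as an oracle for metric-recovery checks: similarity is
#' `exp(-decay * d)` with `d` the weighted Minkowski distance of order `r`
#' (optionally in axes rotated by `theta`).
#'
#' @param r Minkowski exponent.
#' @param weights Two positive weights (normalized internally).
#' @param decay Positive decay rate of the exponential link.
#' @param theta Axis rotation in radians.
#' @param half_width,n_grid Grid geometry as in [iso_similarity_field()].
#' @return A `similarity_field`.
#' @export
minkowski_field <- function(r, weights = c(0.5, 0.5), decay = 1,
                            theta = 0, half_width = 2, n_grid = 17L) {
  w <- weights / sum(weights)
  ax <- seq(-half_width, half_width, length.out = n_grid)
  grid2 <- as.matrix(expand.grid(a = ax, b = ax))
  rot <- rotation2(-theta)
  delta <- abs(grid2 %*% t(rot))
  dist <- (delta^r %*% w)^(1 / r)
  structure(list(reference = c(0, 0), ax1 = ax, ax2 = ax, pair = c(1L, 2L),
                 values = matrix(exp(-decay * dist), n_grid, n_grid)),
            class = "similarity_field")
}

#' Fit a Minkowski metric to an iso-similarity field
#'
#' Grid search over the exponent `r` (with refinement), axis rotation, and
#' dimension weights, with an exponential-decay link `a * exp(-b * d)`
#' fitted by least squares at each candidate.
#'
#' @param field A `similarity_field`.
#' @param r_range Search range for the exponent.
#' @param thetas Candidate axis rotations (radians).
#' @param weights_grid Candidate weights for the first plotted dimension.
#' @return An object of class `minkowski_fit`: list with `r`, `theta`,
#'   `weights`, `decay`, `scale`, `rss`.
#' @export
fit_minkowski <- function(field, r_range = c(0.25, 4),
                          thetas = seq(0, pi / 2, length.out = 13L),
                          weights_grid = seq(0.3, 0.7, by = 0.1)) {
  vals <- as.vector(field$values)
  if (max(vals) - min(vals) < 1e-10)
    stop("degenerate flat field: cannot fit a metric")
  grid2 <- as.matrix(expand.grid(a = field$ax1 - field$reference[field$pair[1]],
                                 b = field$ax2 - field$reference[field$pair[2]]))
  eval_cand <- function(r, theta, w) {
    delta <- abs(grid2 %*% t(rotation2(-theta)))
    dist <- drop((delta^r %*% c(w, 1 - w))^(1 / r))
    obj <- function(b) {
      e <- exp(-b * dist)
      a <- sum(vals * e) / sum(e * e)
      sum((vals - a * e)^2)
    }
    op <- stats::optimize(obj, c(1e-3, 60))
    e <- exp(-op$minimum * dist)
    a <- sum(vals * e) / sum(e * e)
    list(rss = op$objective, decay = op$minimum, scale = a)
  }
  best <- NULL
  search_r <- function(rs) {
    for (r in rs) for (theta in thetas) for (w in weights_grid) {
      cand <- eval_cand(r, theta, w)
      if (is.null(best) || cand$rss < best$rss)
        best <<- c(cand, list(r = r, theta = theta, w = w))
    }
  }
  search_r(seq(r_range[1], r_range[2], by = 0.25))
  r0 <- best$r
  search_r(setdiff(seq(max(r_range[1], r0 - 0.25),
                       min(r_range[2], r0 + 0.25), by = 0.05), r0))
  r0 <- best$r
  search_r(setdiff(seq(max(r_range[1], r0 - 0.05),
                       min(r_range[2], r0 + 0.05), by = 0.01), r0))
  structure(list(r = best$r, theta = best$theta,
                 weights = c(best$w, 1 - best$w), decay = best$decay,
                 scale = best$scale, rss = best$rss),
            class = "minkowski_fit")
}

#' Convexity and triangle-inequality diagnostics for a similarity field
#'
#' Extracts the super-level region at a fraction of the field maximum and
#' tests whether it is convex on the grid: a witness is a pair of
#' grid points inside the region whose segment midpoint falls strictly
#' below the level (the reference plays the role of the off-segment
#' matching stimulus: both endpoints are at least as similar to it as the
#' level, yet the direct path between them leaves the region, which is
#' impossible for any metric-induced, convex iso-similarity contour).
#'
#' @param field A `similarity_field`.
#' @param level_frac Level as a fraction of the field maximum.
#' @param tol Margin below the level required to count as a violation.
#' @param max_witnesses Stop after this many witnesses.
#' @return List with `convex` (flag), `n_witnesses`, and `witnesses`
#'   (data frame of grid indices).
#' @export
convexity_and_triangle_check <- function(field, level_frac = 0.5,
                                         tol = 1e-3,
                                         max_witnesses = 100L) {
  v <- field$values
  level <- level_frac * max(v)
  inside <- which(v >= level, arr.ind = TRUE)
  if (nrow(inside) < 3L)
    return(list(convex = TRUE, n_witnesses = 0L,
                witnesses = data.frame()))
  wit <- list()
  np <- nrow(inside)
  for (i in seq_len(np - 1L)) {
    for (j in seq.int(i + 1L, np)) {
      mid <- (inside[i, ] + inside[j, ]) / 2
      mi <- floor(mid); ma <- ceiling(mid)
      # the midpoint must clear the level for some adjacent grid rounding
      mvals <- c(v[mi[1], mi[2]], v[ma[1], ma[2]],
                 v[mi[1], ma[2]], v[ma[1], mi[2]])
      if (max(mvals) < level - tol) {
        wit[[length(wit) + 1L]] <- c(inside[i, ], inside[j, ])
        if (length(wit) >= max_witnesses) break
      }
    }
    if (length(wit) >= max_witnesses) break
  }
  witnesses <- if (length(wit) > 0) {
    out <- as.data.frame(do.call(rbind, wit))
    names(out) <- c("row_a", "col_a", "row_b", "col_b")
    out
  } else data.frame()
  list(convex = length(wit) == 0L, n_witnesses = length(wit),
       witnesses = witnesses)
}

#' Signal-detection sensitivity from hit and false-alarm rates
#'
#' @param hit Hit rate (probability of responding "different" to a
#'   different pair).
#' @param fa False-alarm rate (responding "different" to a same pair).
#' @param n Number of observations used for rate clipping (rates are clipped
#'   to `[1/(2n), 1 - 1/(2n)]`; `Inf` disables clipping).
#' @return `qnorm(hit) - qnorm(fa)`.
#' @export
dprime <- function(hit, fa, n = Inf) {
  if (is.finite(n)) {
    lo <- 1 / (2 * n); hi <- 1 - lo
    hit <- pmin(pmax(hit, lo), hi)
    fa <- pmin(pmax(fa, lo), hi)
  }
  stats::qnorm(hit) - stats::qnorm(fa)
}

#' Per-dimension discrimination sensitivity for neighbor pairs
#'
#' The response model treats one minus the (symmetrized) similarity of a
#' pair as the probability of responding "different". Hits are "different"
#' responses to neighboring pairs that differ along a dimension; false
#' alarms are "different" responses to identical pairs.
#'
#' @param posterior An `fr_posterior` or [component_set()].
#' @param hyper An [fr_hyper()].
#' @param stimuli Stimulus coordinate matrix.
#' @param pairs Data frame with columns `i`, `j`, `dim` (as from
#'   [discrimination_grid()]).
#' @param seed Integer seed.
#' @return List with `dprime` (named per dimension), `hit`, `fa`, and the
#'   per-pair similarity table.
#' @export
discrimination_dprime <- function(posterior, hyper, stimuli, pairs,
                                  seed = 1L) {
  f <- similarity_fun(posterior, hyper, seed = seed)
  sim_pair <- function(i, j) {
    (f(stimuli[i, ], matrix(stimuli[j, ], 1L)) +
       f(stimuli[j, ], matrix(stimuli[i, ], 1L))) / 2
  }
  pairs$similarity <- mapply(sim_pair, pairs$i, pairs$j)
  same_sim <- vapply(seq_len(nrow(stimuli)), function(i)
    drop(f(stimuli[i, ], matrix(stimuli[i, ], 1L))), numeric(1))
  fa <- mean(1 - same_sim)
  dims <- sort(unique(pairs$dim))
  hit <- vapply(dims, function(dd)
    mean(1 - pairs$similarity[pairs$dim == dd]), numeric(1))
  n_clip <- max(nrow(pairs), nrow(stimuli))
  dp <- dprime(hit, rep(fa, length(dims)), n = n_clip)
  list(dprime = stats::setNames(dp, paste0("dim", dims)),
       hit = stats::setNames(hit, paste0("dim", dims)), fa = fa,
       pairs = pairs)
}
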