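# Inference engines for the trained fixed-component approximation: particle
# filter, collapsed Gibbs, and exact posterior by partition enumeration.

label_levels <- function(labels) sort(unique(labels[!is.na(labels)]))

components_cube <- function(components) {
  d <- components$dim
  j <- length(components$matrices)
  cube <- array(0, c(d, d, j))
  for (i in seq_len(j)) cube[, , i] <- components$matrices[[i]]
  cube
}

#' Particle filter for the trained approximation
#'
#' Each particle stores only the discrete item-to-cluster and
#' cluster-to-component assignments; cluster means are integrated out
#' analytically. Per trial the filter (1) reports the mixture predictive
#' over labels before feedback, (2) propagates each particle through the
#' exact conditional posterior over (cluster, component) for the new item
#' (the optimal proposal), (3) reweights by the particle's marginal
#' predictive, and (4) resamples systematically when the effective sample
#' size drops below `resample_threshold * n_particles`.
#'
#' @param X Trial stimuli (matrix, one row per trial, in presentation
#'   order).
#' @param labels Character labels per trial (`NA` for unsupervised trials).
#' @param components A [component_set()].
#' @param hyper An [fr_hyper()] object (`alpha_g` must be 0: the component
#'   set is fixed).
#' @param label_set Label vocabulary (defaults to the labels present).
#' @param n_particles Number of particles.
#' @param resample_threshold ESS fraction triggering resampling.
#' @param seed Integer seed.
#' @return List with `responses` (trial-by-label probability matrix),
#'   `p_correct` (pre-feedback probability of the true label), `z`
#'   (particle-by-trial cluster assignments), `cluster_components`, and
#'   `weights`.
#' @export
run_particle_filter <- function(X, labels, components, hyper,
                                label_set = NULL, n_particles = 100L,
                                resample_threshold = 0.5, seed = 1L) {
  stopifnot(inherits(components, "component_set"),
            inherits(hyper, "fr_hyper"))
  X <- as.matrix(X)
  if (is.null(label_set)) label_set <- label_levels(labels)
  lab_int <- ifelse(is.na(labels), -1L,
                    match(labels, label_set) - 1L)
  res <- .pf_run_cpp(X, as.integer(lab_int), components_cube(components),
                     hyper$omega, hyper$sigma_r2, hyper$crp$alpha,
                     hyper$crp$alpha_c, length(label_set),
                     as.integer(n_particles), resample_threshold,
                     as.integer(seed))
  responses <- res$responses
  if (length(label_set) > 0) colnames(responses) <- label_set
  p_correct <- rep(NA_real_, nrow(X))
  ok <- !is.na(labels)
  if (any(ok))
    p_correct[ok] <- responses[cbind(which(ok), match(labels[ok],
                                                      label_set))]
  list(responses = responses, p_correct = p_correct, z = res$z,
       cluster_components = res$cluster_components, weights = res$weights)
}

#' Collapsed Gibbs sampler with fixed components
#'
#' Alternates item-level cluster reassignment and cluster-level component
#' reassignment, with cluster means collapsed. Intended for small stimulus
#' sets where the partition posterior itself is of interest.
#'
#' @inheritParams run_particle_filter
#' @param n_sweeps Total sweeps.
#' @param burn_in Discarded initial sweeps.
#' @return List with `z` (sweep-by-item assignments, post burn-in) and
#'   `partition_probs` (named relative frequencies of canonical partitions).
#' @export
run_gibbs_fixed <- function(X, components, hyper, labels = NULL,
                            label_set = NULL, n_sweeps = 1050L,
                            burn_in = 50L, seed = 1L) {
  stopifnot(burn_in < n_sweeps)
  X <- as.matrix(X)
  if (is.null(labels)) labels <- rep(NA_character_, nrow(X))
  if (is.null(label_set)) label_set <- label_levels(labels)
  lab_int <- ifelse(is.na(labels), -1L, match(labels, label_set) - 1L)
  res <- .gibbs_fixed_cpp(X, as.integer(lab_int),
                          components_cube(components), hyper$omega,
                          hyper$sigma_r2, hyper$crp$alpha,
                          hyper$crp$alpha_c, length(label_set),
                          as.integer(n_sweeps), as.integer(burn_in),
                          as.integer(seed))
  keys <- apply(res$z, 1L, function(z)
    paste(canonical_partition(z), collapse = "-"))
  tab <- table(keys)
  list(z = res$z,
       partition_probs = stats::setNames(as.numeric(tab) / sum(tab),
                                         names(tab)))
}

#' Aggregate particle weights into a partition posterior
#'
#' @param pf Result of [run_particle_filter()].
#' @return Named vector of posterior partition probabilities.
#' @export
partition_probs_from_particles <- function(pf) {
  keys <- apply(pf$z, 1L, function(z)
    paste(canonical_partition(z), collapse = "-"))
  out <- tapply(pf$weights, keys, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Total-variation distance between two partition distributions
#'
#' @param p,q Named probability vectors keyed by canonical partition string.
#' @return Total variation distance in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  sum(abs(pv - qv)) / 2
}

## ---- exact posterior ------------------------------------------------------

cluster_marginal_loglik <- function(members, cov, hyper) {
  ll <- 0
  for (i in seq_len(nrow(members)))
    ll <- ll + cluster_predictive_fixed_cov(
      members[i, ], members[seq_len(i - 1L), , drop = FALSE], cov, hyper)
  ll
}

# Sum over all cluster->component assignment sequences of the product of
# hierarchical-CRP factors and per-cluster marginal likelihoods.
hcrp_likelihood_sum <- function(mlik, params) {
  k <- nrow(mlik); j <- ncol(mlik)
  rec <- function(ki, ccount) {
    if (ki > k) return(0)
    pr <- hcrp_component_probs(ccount, params)
    terms <- vapply(seq_len(j), function(jj) {
      if (pr[[jj]] <= 0) return(-Inf)
      e <- ccount; e[[jj]] <- e[[jj]] + 1
      log(pr[[jj]]) + mlik[ki, jj] + rec(ki + 1L, e)
    }, numeric(1))
    mx <- max(terms)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(terms - mx)))
  }
  rec(1L, numeric(j))
}

#' Exact posterior over partitions for a small stimulus set
#'
#' Enumerates every set partition of the stimuli (single-category clusters
#' only, when labels are given) and, for each, sums over all
#' cluster-to-component assignments: CRP prior times hierarchical-CRP prior
#' times the product of per-cluster marginal likelihoods with cluster means
#' integrated out.
#'
#' @inheritParams run_particle_filter
#' @param cap Refuse above this many stimuli.
#' @return Data frame with `partition` (canonical string), `logprob`
#'   (unnormalized), and `prob` (normalized); plus attribute `probs`, the
#'   named probability vector.
#' @export
exact_posterior <- function(X, components, hyper, labels = NULL,
                            label_set = NULL, cap = 8L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > cap) stop("refusing exact enumeration beyond ", cap, " stimuli")
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(label_set)) label_set <- label_levels(labels)
  parts <- enumerate_partitions(n)
  lp <- vapply(parts, function(z) {
    k <- max(z)
    for (kk in seq_len(k)) {
      labs <- unique(labels[z == kk])
      labs <- labs[!is.na(labs)]
      if (length(labs) > 1L) return(-Inf)
    }
    mlik <- matrix(0, k, length(components$matrices))
    for (kk in seq_len(k))
      for (jj in seq_along(components$matrices))
        mlik[kk, jj] <- cluster_marginal_loglik(
          X[z == kk, , drop = FALSE], components$matrices[[jj]], hyper)
    lab_term <- if (length(label_set) > 0 && any(!is.na(labels)))
      -k * log(length(label_set)) else 0
    crp_joint_logprob(z, hyper$crp$alpha) + lab_term +
      hcrp_likelihood_sum(mlik, hyper$crp)
  }, numeric(1))
  mx <- max(lp)
  pr <- exp(lp - mx)
  pr <- pr / sum(pr)
  keys <- vapply(parts, function(z) paste(z, collapse = "-"), character(1))
  out <- data.frame(partition = keys, logprob = lp, prob = pr,
                    stringsAsFactors = FALSE)
  attr(out, "probs") <- stats::setNames(pr, keys)
  out
}

## ---- learning curves ------------------------------------------------------

#' Simulated learning curves for a category structure
#'
#' Runs independent seeded particle-filter learners through the structure's
#' randomized trial protocol and records the expected error (one minus the
#' pre-feedback probability of the correct label) per block.
#'
#' @param struct A [category_structure()].
#' @param regime A [regime()] with a fixed component set, or a list with
#'   `components` and `crp`/`sigma_r2` fields.
#' @param n_learners Number of independent simulated learners.
#' @param n_blocks Number of training blocks (defaults to the structure's).
#' @param n_particles Particles per learner.
#' @param seed Integer seed; learner `i` uses `seed + i`.
#' @return List with `per_block` (data frame: block, error, se),
#'   `mean_error` (grand mean across trials and learners), and
#'   `per_learner` (learner-by-block matrix).
#' @export
learning_curve <- function(struct, regime, n_learners = 50L,
                           n_blocks = NULL, n_particles = 100L, seed = 1L) {
  if (is.null(n_blocks)) n_blocks <- struct$n_blocks
  comps <- regime$components
  omega <- colMeans(struct$stimuli)
  hyper <- fr_hyper(regime$crp, sigma_r2 = regime$sigma_r2, omega = omega,
                    dim = ncol(struct$stimuli))
  label_set <- label_levels(struct$labels)
  per_learner <- matrix(NA_real_, n_learners, n_blocks)
  for (i in seq_len(n_learners)) {
    tr <- trial_stream(struct, n_blocks, seed = seed + i)
    pf <- run_particle_filter(tr$X, tr$label, comps, hyper,
                              label_set = label_set,
                              n_particles = n_particles, seed = seed + i)
    err <- 1 - pf$p_correct
    per_learner[i, ] <- tapply(err, tr$block, mean)
  }
  per_block <- data.frame(
    block = seq_len(n_blocks),
    error = colMeans(per_learner),
    se = apply(per_learner, 2L, stats::sd) / sqrt(n_learners))
  list(per_block = per_block, mean_error = mean(per_learner),
       per_learner = per_learner)
}
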