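# The original rational model of categorization with the local
# maximum-a-posteriori approximation, used as a baseline.

#' Parameters of the rational model of categorization
#'
#' Per-dimension normal likelihoods with conjugate normal-inverse-chi-square
#' priors on the mean and variance, a beta-binomial likelihood for category
#' labels, and a CRP prior over clusters.
#'
#' @param alpha CRP dispersion.
#' @param sigma0_2 Prior variance.
#' @param a0 Confidence in the prior variance (degrees of freedom).
#' @param lambda0 Confidence in the prior mean.
#' @param beta Label smoothing of the beta-binomial label likelihood.
#' @param omega Per-dimension prior means.
#' @return An object of class `rmc_params`.
#' @export
rmc_params <- function(alpha = 1, sigma0_2 = 2.25, a0 = 1, lambda0 = 1,
                       beta = 0.1, omega = c(0, 0)) {
  vals <- c(alpha, sigma0_2, a0, lambda0, beta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rational-model parameters must be positive")
  structure(list(alpha = alpha, sigma0_2 = sigma0_2, a0 = a0,
                 lambda0 = lambda0, beta = beta,
                 omega = as.numeric(omega)),
            class = "rmc_params")
}

#' Cluster feature predictive of the rational model
#'
#' Product over dimensions of the posterior-predictive scaled, shifted t
#' density implied by the conjugate normal-inverse-chi-square updates. An
#' empty cluster gives the prior predictive with `a0` degrees of freedom.
#'
#' @param x Query stimulus (vector) or matrix of queries.
#' @param members Matrix of cluster members (possibly 0 rows).
#' @param params An [rmc_params()].
#' @param log Return log density?
#' @return (Log) predictive density.
#' @export
rmc_cluster_predictive <- function(x, members, params, log = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  if (is.null(members)) members <- matrix(numeric(0), 0L, d)
  if (is.null(dim(members))) members <- matrix(members, ncol = d)
  m <- nrow(members)
  ll <- numeric(nrow(x))
  for (dd in seq_len(d)) {
    xs <- members[, dd]
    lam_m <- params$lambda0 + m
    a_m <- params$a0 + m
    xbar <- if (m > 0) mean(xs) else 0
    om <- params$omega[dd]
    om_m <- (params$lambda0 * om + m * xbar) / lam_m
    ss <- if (m > 0) sum((xs - xbar)^2) else 0
    a_sig2 <- params$a0 * params$sigma0_2 + ss +
      (params$lambda0 * m / lam_m) * (xbar - om)^2
    sig2_m <- a_sig2 / a_m
    scale <- sqrt(sig2_m * (1 + 1 / lam_m))
    ll <- ll + stats::dt((x[, dd] - om_m) / scale, df = a_m, log = TRUE) -
      log(scale)
  }
  if (log) ll else exp(ll)
}

#' Beta-binomial label likelihood of a cluster
#'
#' @param label_counts Named counts of labels among the cluster's members.
#' @param label Queried label.
#' @param beta Smoothing parameter.
#' @param label_set Full label vocabulary.
#' @return `(count + beta) / (size + |labels| * beta)`.
#' @export
rmc_label_likelihood <- function(label_counts, label, beta, label_set) {
  size <- sum(label_counts)
  cnt <- if (label %in% names(label_counts)) label_counts[[label]] else 0
  (cnt + beta) / (size + length(label_set) * beta)
}

#' Run the rational model with the local-MAP approximation
#'
#' Each trial the model responds with the weighted sum of cluster label
#' likelihoods, weighted by the feature-only assignment probabilities; the
#' item (with its label) is then committed to the single a-posteriori most
#' probable cluster, ties broken toward the lowest cluster index.
#'
#' @param X Trial stimuli in presentation order.
#' @param labels Trial labels.
#' @param params An [rmc_params()].
#' @param label_set Label vocabulary (defaults to labels present).
#' @return List with `p_correct` (pre-feedback probability of the true
#'   label per trial), `z` (final cluster assignments).
#' @export
rmc_run <- function(X, labels, params, label_set = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(label_set)) label_set <- label_levels(labels)
  z <- integer(n)
  p_correct <- numeric(n)
  for (t in seq_len(n)) {
    k_n <- max(z)
    prior <- crp_assignment_probs(tabulate(z[seq_len(t - 1L)], k_n),
                                  params$alpha)
    feat <- vapply(seq_len(k_n + 1L), function(k) {
      members <- if (k <= k_n) X[which(z == k), , drop = FALSE] else NULL
      rmc_cluster_predictive(X[t, ], members, params)
    }, numeric(1))
    lw <- log(prior) + feat
    w <- exp(lw - max(lw)); w <- w / sum(w)
    lab_lik <- vapply(seq_len(k_n + 1L), function(k) {
      cnts <- if (k <= k_n)
        table(factor(labels[which(z == k)], levels = label_set))
      else table(factor(character(0), levels = label_set))
      rmc_label_likelihood(cnts, labels[t], params$beta, label_set)
    }, numeric(1))
    # response: weighted sum over clusters, before seeing the label
    p_correct[t] <- sum(w * lab_lik)
    # local-MAP commitment, label included as a feature
    score <- lw + log(lab_lik)
    z[t] <- which.max(score)  # which.max takes the lowest index on ties
  }
  list(p_correct = p_correct, z = z)
}

#' Learning curve for the rational model, averaged over trial orders
#'
#' @param struct A [category_structure()].
#' @param params An [rmc_params()] (with `omega` replaced by the mean
#'   stimulus if `auto_omega`).
#' @param n_orders Number of random trial orders to average.
#' @param n_blocks Training blocks.
#' @param seed Integer seed.
#' @param auto_omega Center the prior mean on the mean stimulus?
#' @return List with `per_block` (block, error, se) and `mean_error`.
#' @export
rmc_learning_curve <- function(struct, params = rmc_params(),
                               n_orders = 50L, n_blocks = NULL, seed = 1L,
                               auto_omega = TRUE) {
  if (is.null(n_blocks)) n_blocks <- struct$n_blocks
  if (auto_omega)
    params$omega <- rep_len(colMeans(struct$stimuli),
                            ncol(struct$stimuli))
  label_set <- label_levels(struct$labels)
  per_order <- matrix(NA_real_, n_orders, n_blocks)
  for (i in seq_len(n_orders)) {
    tr <- trial_stream(struct, n_blocks, seed = seed + i)
    run <- rmc_run(tr$X, tr$label, params, label_set)
    per_order[i, ] <- tapply(1 - run$p_correct, tr$block, mean)
  }
  list(per_block = data.frame(block = seq_len(n_blocks),
                              error = colMeans(per_order),
                              se = apply(per_order, 2L, stats::sd) /
                                sqrt(n_orders)),
       mean_error = mean(per_order))
}
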