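# The hierarchical family-resemblance model: generative state, predictive
# densities, assignment posterior, category decision rule, and joint density.

#' Model hyperparameters
#'
#' @param crp A [crp_params()] bundle of dispersion parameters.
#' @param sigma_r2 Prior variance of cluster means (the mean prior is
#'   `N(omega, sigma_r2 * I)`, deliberately independent of the cluster
#'   covariance).
#' @param omega Prior mean of cluster means; conventionally the mean
#'   stimulus of the task.
#' @param v_t Top-level degrees of freedom: prior scale certainty, and the
#'   mean and standard deviation of the truncated-normal prior on each
#'   component's degrees of freedom.
#' @param top_scale Top-level inverse-Wishart scale matrix (isotropic
#'   identity by default, so the prior prefers no direction of the space).
#' @param dim Stimulus dimensionality.
#' @return An object of class `fr_hyper`.
#' @export
fr_hyper <- function(crp = crp_params(), sigma_r2 = 1, omega = NULL,
                     v_t = 30, top_scale = NULL, dim = 2L) {
  stopifnot(inherits(crp, "crp_params"))
  if (sigma_r2 <= 0) stop("`sigma_r2` must be positive")
  dim <- as.integer(dim)
  if (is.null(omega)) omega <- rep(0, dim)
  if (length(omega) != dim) stop("`omega` must have length `dim`")
  if (is.null(top_scale)) top_scale <- diag(dim)
  if (!is_spd(top_scale)) stop("`top_scale` must be SPD")
  if (v_t <= dim - 1) stop("`v_t` must exceed dim - 1")
  structure(list(crp = crp, sigma_r2 = sigma_r2, omega = as.numeric(omega),
                 v_t = v_t, top_scale = top_scale, dim = dim),
            class = "fr_hyper")
}

#' Posterior-predictive density of a cluster with fixed covariance
#'
#' With the cluster mean integrated out analytically: given `m` members with
#' sum `s`, the mean posterior has covariance
#' `V = (sigma_r^{-2} I + m Sigma^{-1})^{-1}` and mean
#' `V (sigma_r^{-2} omega + Sigma^{-1} s)`; the predictive for a new item is
#' Gaussian with that mean and covariance `Sigma + V`. An empty cluster gives
#' `N(omega, Sigma + sigma_r2 I)`.
#'
#' @param x Query point(s): vector or matrix with points in rows.
#' @param members Matrix of member coordinates (0-row matrix or `NULL` for an
#'   empty cluster).
#' @param cov SPD cluster covariance.
#' @param hyper An [fr_hyper()] object.
#' @param log Return log density?
#' @return Numeric vector of (log) predictive densities.
#' @export
cluster_predictive_fixed_cov <- function(x, members, cov, hyper, log = TRUE) {
  if (!is_spd(cov)) stop("`cov` must be SPD")
  d <- nrow(cov)
  if (is.null(members)) members <- matrix(numeric(0), 0L, d)
  if (is.null(dim(members))) members <- matrix(members, ncol = d)
  m <- nrow(members)
  prior_prec <- diag(d) / hyper$sigma_r2
  if (m == 0L) {
    mu_hat <- hyper$omega
    v_post <- diag(hyper$sigma_r2, d)
  } else {
    sig_inv <- chol2inv(chol_spd(cov))
    v_post <- chol2inv(chol_spd(prior_prec + m * sig_inv))
    mu_hat <- drop(v_post %*% (prior_prec %*% hyper$omega +
                                 sig_inv %*% colSums(members)))
  }
  ld <- dmvnorm_log(x, mu_hat, cov + v_post)
  if (log) ld else exp(ld)
}

## ---- hierarchy state -----------------------------------------------------

#' Create an empty hierarchy state
#'
#' A state holds the observed items, their cluster assignments, each
#' cluster's label/context/component, and the component set. With a fixed
#' [component_set()] the model is the trained approximation (cluster
#' covariances are the component matrices and cluster means are collapsed).
#'
#' @param hyper An [fr_hyper()] object.
#' @param components A [component_set()] (fixed-covariance trained model) —
#'   required when `alpha_g = 0`.
#' @param label_set Character vector of possible category labels (used as
#'   the uniform base rate of the new-cluster slot).
#' @return An object of class `hier_state`.
#' @export
hier_state <- function(hyper, components = NULL, label_set = character(0)) {
  stopifnot(inherits(hyper, "fr_hyper"))
  if (is.null(components) && hyper$crp$alpha_g == 0)
    stop("alpha_g = 0 requires a fixed component set")
  if (!is.null(components)) {
    stopifnot(inherits(components, "component_set"))
    if (components$dim != hyper$dim)
      stop("component set dimensionality does not match `hyper$dim`")
  }
  structure(list(
    X = matrix(numeric(0), 0L, hyper$dim),
    label = character(0), context = character(0),
    z = integer(0),
    cl_component = integer(0), cl_label = character(0),
    cl_context = character(0),
    components = components,
    hyper = hyper, label_set = as.character(label_set)
  ), class = "hier_state")
}

state_check <- function(state) {
  stopifnot(inherits(state, "hier_state"))
  n <- nrow(state$X)
  k <- length(state$cl_component)
  if (length(state$z) != n) stop("inconsistent state: z length")
  if (n > 0L && (any(state$z < 1L) || any(state$z > k)))
    stop("inconsistent state: cluster index out of range")
  if (k > 0L && any(tabulate(state$z, k) < 1L))
    stop("inconsistent state: empty cluster (counts must all be >= 1)")
  for (kk in seq_len(k)) {
    idx <- which(state$z == kk)
    if (length(unique(state$label[idx])) > 1L)
      stop("inconsistent state: cluster ", kk, " mixes category labels")
    if (length(unique(state$context[idx])) > 1L)
      stop("inconsistent state: cluster ", kk, " mixes contexts")
  }
  invisible(state)
}

cluster_cov <- function(state, k) {
  state$components$matrices[[state$cl_component[[k]]]]
}

# Context-level component usage counts (clusters per component).
context_component_counts <- function(state, context) {
  j <- length(state$components$matrices)
  counts <- numeric(j)
  sel <- state$cl_context == context
  if (any(sel)) {
    tab <- table(factor(state$cl_component[sel], levels = seq_len(j)))
    counts <- as.numeric(tab)
  }
  counts
}

#' Posterior over cluster assignments for a new item
#'
#' Combines the context-level partition prior with the marginal predictive
#' density of each candidate cluster. The new-cluster slot is expanded into
#' one option per component, weighted by the hierarchical-CRP component
#' probabilities for the context. When `label` is given, clusters with a
#' different label receive zero mass (clusters are single-category) and the
#' new-cluster options carry the uniform label base rate.
#'
#' @param state A `hier_state`.
#' @param x Query stimulus (numeric vector).
#' @param context Context id of the query.
#' @param label Optional category label to condition on.
#' @return A data frame with columns `cluster` (NA for new), `component`,
#'   `label`, `prob`, and attribute `log_marginal` (the log of the summed
#'   unnormalized mass, useful as a particle weight increment).
#' @export
assignment_posterior <- function(state, x, context, label = NULL) {
  state_check(state)
  if (is.null(state$components))
    stop("assignment_posterior requires a fixed component set; use the Gibbs",
         " sampler for the full hierarchy")
  in_ctx <- which(state$cl_context == context)
  n_ctx <- sum(state$context == context)
  alpha <- state$hyper$crp$alpha
  counts <- tabulate(state$z, length(state$cl_component))
  opts_cluster <- integer(0); opts_comp <- integer(0)
  opts_label <- character(0); logw <- numeric(0)
  for (k in in_ctx) {
    lw <- log(counts[[k]]) - log(n_ctx + alpha)
    if (!is.null(label)) {
      if (!identical(state$cl_label[[k]], label)) next
    }
    members <- state$X[state$z == k, , drop = FALSE]
    lw <- lw + cluster_predictive_fixed_cov(x, members, cluster_cov(state, k),
                                            state$hyper)
    opts_cluster <- c(opts_cluster, k)
    opts_comp <- c(opts_comp, state$cl_component[[k]])
    opts_label <- c(opts_label, state$cl_label[[k]])
    logw <- c(logw, lw)
  }
  comp_probs <- hcrp_component_probs(context_component_counts(state, context),
                                     state$hyper$crp)
  label_base <- if (!is.null(label) && length(state$label_set) > 0)
    1 / length(state$label_set) else 1
  for (j in seq_along(comp_probs)) {
    if (comp_probs[[j]] <= 0) next
    lw <- log(alpha) - log(n_ctx + alpha) + log(comp_probs[[j]]) +
      log(label_base) +
      cluster_predictive_fixed_cov(x, NULL,
                                   state$components$matrices[[j]],
                                   state$hyper)
    opts_cluster <- c(opts_cluster, NA_integer_)
    opts_comp <- c(opts_comp, j)
    opts_label <- c(opts_label, if (is.null(label)) NA_character_ else label)
    logw <- c(logw, lw)
  }
  if (length(logw) == 0L)
    stop("no candidate clusters or components available in this context")
  mx <- max(logw)
  w <- exp(logw - mx)
  out <- data.frame(cluster = opts_cluster, component = opts_comp,
                    label = opts_label, prob = w / sum(w),
                    stringsAsFactors = FALSE)
  attr(out, "log_marginal") <- mx + log(sum(w))
  out
}

#' Category decision rule
#'
#' The probability of each label is the assignment-posterior mass of the
#' clusters carrying that label, plus the new-cluster mass spread uniformly
#' over the task's label set.
#'
#' @param state A `hier_state` with at least one labeled cluster or a
#'   nonempty `label_set`.
#' @param x Query stimulus.
#' @param context Context id.
#' @return Named probability vector over labels.
#' @export
classify <- function(state, x, context) {
  labels <- state$label_set
  if (length(labels) == 0L)
    labels <- sort(unique(stats::na.omit(state$cl_label)))
  if (length(labels) == 0L)
    stop("no labels known: supply `label_set` or observe labeled items")
  post <- assignment_posterior(state, x, context, label = NULL)
  p <- stats::setNames(numeric(length(labels)), labels)
  for (i in seq_len(nrow(post))) {
    if (is.na(post$cluster[[i]]))
      p <- p + post$prob[[i]] / length(labels)
    else if (post$label[[i]] %in% labels)
      p[[post$label[[i]]]] <- p[[post$label[[i]]]] + post$prob[[i]]
  }
  p / sum(p)
}

#' Observe one labeled stimulus and update the state
#'
#' The item is assigned to a label-consistent cluster (or to a new cluster
#' under some component): the maximum-posterior choice in `"map"` mode, or a
#' draw from the assignment posterior in `"sample"` mode.
#'
#' @param state A `hier_state`.
#' @param x Stimulus vector.
#' @param label Category label (may be `NA` for unsupervised observation).
#' @param context Context id.
#' @param mode `"map"` or `"sample"`.
#' @return The updated `hier_state`, with attribute `log_marginal`.
#' @export
observe <- function(state, x, label, context, mode = c("map", "sample")) {
  mode <- match.arg(mode)
  lab <- if (is.na(label)) NULL else label
  post <- assignment_posterior(state, x, context, label = lab)
  pick <- if (mode == "map") which.max(post$prob)
  else sample.int(nrow(post), 1L, prob = post$prob)
  n <- nrow(state$X)
  state$X <- rbind(state$X, matrix(as.numeric(x), 1L))
  state$label <- c(state$label, as.character(label))
  state$context <- c(state$context, context)
  if (is.na(post$cluster[[pick]])) {
    state$cl_component <- c(state$cl_component, post$component[[pick]])
    state$cl_label <- c(state$cl_label, as.character(label))
    state$cl_context <- c(state$cl_context, context)
    state$z <- c(state$z, length(state$cl_component))
  } else {
    state$z <- c(state$z, post$cluster[[pick]])
  }
  attr(state, "log_marginal") <- attr(post, "log_marginal")
  state
}

## ---- joint density -------------------------------------------------------

# Sequential log prior of cluster->component assignments under the collapsed
# hierarchical CRP (fixed finite component set, equal global weights).
hcrp_joint_logprob <- function(u, cl_context, params, n_components) {
  lp <- 0
  for (ctx in unique(cl_context)) {
    idx <- which(cl_context == ctx)
    ctx_counts <- numeric(n_components)
    for (k in idx) {
      pr <- hcrp_component_probs(ctx_counts, params)
      lp <- lp + log(pr[[u[[k]]]])
      ctx_counts[[u[[k]]]] <- ctx_counts[[u[[k]]]] + 1
    }
  }
  lp
}

#' Joint log probability of a fixed-component hierarchy state
#'
#' Sums the CRP log prior on the item partition (per context), the
#' hierarchical-CRP log prior on the cluster-to-component assignments, the
#' uniform label term for each labeled cluster, and the marginal Gaussian
#' likelihood of each cluster's members (means integrated out).
#'
#' @param state A `hier_state` with a fixed component set.
#' @return Log joint probability (up to the stimulus-order constant shared
#'   by all states over the same data).
#' @export
state_joint_logprob <- function(state) {
  state_check(state)
  lp <- 0
  for (ctx in unique(state$context)) {
    sel <- state$context == ctx
    lp <- lp + crp_joint_logprob(canonical_partition(state$z[sel]),
                                 state$hyper$crp$alpha)
  }
  lp <- lp + hcrp_joint_logprob(state$cl_component, state$cl_context,
                                state$hyper$crp,
                                length(state$components$matrices))
  if (length(state$label_set) > 0) {
    labeled <- !is.na(state$cl_label)
    lp <- lp - sum(labeled) * log(length(state$label_set))
  }
  for (k in seq_along(state$cl_component)) {
    members <- state$X[state$z == k, , drop = FALSE]
    cov <- cluster_cov(state, k)
    for (i in seq_len(nrow(members)))
      lp <- lp + cluster_predictive_fixed_cov(
        members[i, ], members[seq_len(i - 1L), , drop = FALSE], cov,
        state$hyper)
  }
  lp
}
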