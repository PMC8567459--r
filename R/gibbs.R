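# Gibbs sampling for the full hierarchy: clusters carry instantiated means
# and covariances, components carry inverse-Wishart scale matrices and
# degrees of freedom, and both levels of the Chinese-restaurant hierarchy
# are resampled.

#' Gibbs sampler configuration
#'
#' @param n_samples Total sweeps (default 1050).
#' @param burn_in Initial sweeps to discard (default 50).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param n_aux Auxiliary (cluster, component) candidates for the
#'   non-conjugate new-cluster move.
#' @param phi_proposal_dof Degrees of freedom of the Wishart
#'   Metropolis-Hastings proposal for component scale matrices (larger =
#'   smaller steps).
#' @param v_step Random-walk step (on `log(v - D)`) for component degrees of
#'   freedom.
#' @param seed Integer seed.
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_samples = 1050L, burn_in = 50L, thin = 1L,
                         n_aux = 3L, phi_proposal_dof = 100,
                         v_step = 0.25, seed = 1L) {
  stopifnot(burn_in < n_samples, n_aux >= 1L, thin >= 1L)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_aux = as.integer(n_aux),
                 phi_proposal_dof = phi_proposal_dof, v_step = v_step,
                 seed = as.integer(seed)),
            class = "gibbs_config")
}

draw_component_prior <- function(hyper) {
  list(scale = iw_sample(1L, hyper$top_scale, hyper$v_t),
       dof = rtruncnorm(1L, hyper$v_t, hyper$v_t, lower = hyper$dim))
}

# Component-choice probabilities for a new cluster: existing components
# scored by context usage plus alpha_c times their global weight; a trailing
# slot carries the new-component mass alpha_g.
comp_choice_probs <- function(ctx_counts, gusage, crp) {
  g <- sum(gusage)
  gw <- c(gusage, crp$alpha_g) / (g + crp$alpha_g)
  if (is.infinite(crp$alpha_c)) return(gw)
  score <- c(ctx_counts, 0) + crp$alpha_c * gw
  score / sum(score)
}

wishart_logpdf <- function(x, scale, dof) {
  d <- nrow(scale)
  chx <- chol_spd(x); chs <- chol_spd(scale)
  sinv <- chol2inv(chs)
  ((dof - d - 1) / 2) * 2 * sum(log(diag(chx))) -
    0.5 * sum(diag(sinv %*% x)) - (dof * d / 2) * log(2) -
    (dof / 2) * 2 * sum(log(diag(chs))) - lmvgamma(dof / 2, d)
}

#' Gibbs sampling for the full hierarchy
#'
#' Sweeps update, in order: item-to-cluster assignments (with an
#' auxiliary-candidate scheme for the non-conjugate new-cluster case),
#' cluster means (conjugate Gaussian), cluster covariances (conjugate
#' inverse-Wishart), cluster-to-component assignments (hierarchical-CRP
#' prior times inverse-Wishart likelihood), component scale matrices
#' (Metropolis-Hastings with a shape-matched Wishart proposal), and
#' component degrees of freedom (random-walk Metropolis-Hastings on
#' `log(v - D)` under the truncated-normal prior). The chain is initialized
#' with each item in its own cluster and own component.
#'
#' @param X Stimulus matrix (one row per item).
#' @param context Character context id per item (clusters never cross
#'   contexts).
#' @param hyper An [fr_hyper()] with `alpha_g > 0`.
#' @param labels Optional per-item labels (clusters never mix labels).
#' @param cfg A [gibbs_config()].
#' @return An object of class `fr_posterior`: list with `samples` (state
#'   snapshots), `hyper`, `accept` (MH acceptance rates), and
#'   `joint_logprob` trace.
#' @export
run_gibbs <- function(X, context, hyper, labels = NULL,
                      cfg = gibbs_config()) {
  stopifnot(inherits(hyper, "fr_hyper"), inherits(cfg, "gibbs_config"))
  if (hyper$crp$alpha_g <= 0)
    stop("the full hierarchy requires alpha_g > 0 (components are learned)")
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  context <- as.character(context)
  crp <- hyper$crp

  withr_seed(cfg$seed, {
    # init: one cluster and one fresh component per item
    z <- seq_len(n)
    comps <- lapply(seq_len(n), function(i) draw_component_prior(hyper))
    u <- seq_len(n)
    cl_ctx <- context; cl_lab <- labels
    Sigma <- lapply(seq_len(n), function(i)
      iw_sample(1L, comps[[i]]$scale, comps[[i]]$dof))
    mu <- lapply(seq_len(n), function(i) X[i, ])
    gusage <- rep(1, n)

    samples <- list()
    lp_trace <- numeric(0)
    acc_phi <- c(0, 0); acc_v <- c(0, 0)

    ctx_counts_for <- function(ctx) {
      sel <- cl_ctx == ctx
      if (!any(sel)) return(numeric(length(comps)))
      tabulate(u[sel], length(comps))
    }

    drop_cluster <- function(k) {
      gusage[u[k]] <<- gusage[u[k]] - 1
      keep <- setdiff(seq_along(mu), k)
      mu <<- mu[keep]; Sigma <<- Sigma[keep]
      u <<- u[keep]; cl_ctx <<- cl_ctx[keep]; cl_lab <<- cl_lab[keep]
      z <<- ifelse(z > k, z - 1L, z)
      # retire unused components
      dead <- which(gusage == 0)
      if (length(dead) > 0) {
        keepc <- setdiff(seq_along(comps), dead)
        comps <<- comps[keepc]; gusage <<- gusage[keepc]
        u <<- match(u, keepc)
      }
    }

    n_labels <- length(label_levels(labels))
    lab_base <- if (n_labels > 0) -log(n_labels) else 0

    for (sweep in seq_len(cfg$n_samples)) {
      ## --- z updates (auxiliary-candidate scheme)
      for (i in seq_len(n)) {
        k_old <- z[i]
        singleton <- sum(z == k_old) == 1L
        aux <- vector("list", cfg$n_aux)
        if (singleton) {
          comp_dies <- gusage[u[[k_old]]] == 1
          aux[[1L]] <- if (comp_dies) {
            # keep the retiring component's parameters with the auxiliary
            list(mu = mu[[k_old]], Sigma = Sigma[[k_old]],
                 comp = NA_integer_, fresh = comps[[u[[k_old]]]])
          } else {
            list(mu = mu[[k_old]], Sigma = Sigma[[k_old]],
                 comp = u[[k_old]], fresh = NULL)
          }
          drop_cluster(k_old)
          z[i] <- NA_integer_
        } else {
          z[i] <- NA_integer_
        }
        ctxc <- ctx_counts_for(context[i])
        for (a in seq_len(cfg$n_aux)) {
          if (!is.null(aux[[a]])) next
          pr <- comp_choice_probs(ctxc, gusage, crp)
          jj <- sample.int(length(pr), 1L, prob = pr)
          if (jj > length(comps)) {
            fresh <- draw_component_prior(hyper)
            sig <- iw_sample(1L, fresh$scale, fresh$dof)
            aux[[a]] <- list(mu = hyper$omega +
                               stats::rnorm(d, 0, sqrt(hyper$sigma_r2)),
                             Sigma = sig, comp = NA_integer_, fresh = fresh)
          } else {
            sig <- iw_sample(1L, comps[[jj]]$scale, comps[[jj]]$dof)
            aux[[a]] <- list(mu = hyper$omega +
                               stats::rnorm(d, 0, sqrt(hyper$sigma_r2)),
                             Sigma = sig, comp = jj, fresh = NULL)
          }
        }
        cand <- which(cl_ctx == context[i])
        if (!is.na(labels[i]))
          cand <- cand[is.na(cl_lab[cand]) | cl_lab[cand] == labels[i]]
        sizes <- tabulate(z[!is.na(z)], length(mu))
        lw <- c(
          vapply(cand, function(k)
            log(sizes[[k]]) + dmvnorm_log(X[i, ], mu[[k]], Sigma[[k]]),
            numeric(1)),
          vapply(aux, function(a)
            log(crp$alpha / cfg$n_aux) + lab_base +
              dmvnorm_log(X[i, ], a$mu, a$Sigma), numeric(1)))
        pick <- sample.int(length(lw), 1L, prob = exp(lw - max(lw)))
        if (pick <= length(cand)) {
          z[i] <- cand[[pick]]
        } else {
          a <- aux[[pick - length(cand)]]
          if (is.na(a$comp)) {
            comps[[length(comps) + 1L]] <- a$fresh
            gusage <- c(gusage, 0)
            a$comp <- length(comps)
          }
          mu[[length(mu) + 1L]] <- a$mu
          Sigma[[length(Sigma) + 1L]] <- a$Sigma
          u <- c(u, a$comp)
          cl_ctx <- c(cl_ctx, context[i])
          cl_lab <- c(cl_lab, labels[i])
          gusage[a$comp] <- gusage[a$comp] + 1
          z[i] <- length(mu)
        }
      }

      ## --- cluster parameter updates
      for (k in seq_along(mu)) {
        idx <- which(z == k)
        m <- length(idx)
        xs <- X[idx, , drop = FALSE]
        sig_inv <- chol2inv(chol_spd(Sigma[[k]]))
        v_post <- chol2inv(chol_spd(diag(d) / hyper$sigma_r2 + m * sig_inv))
        mu_post <- drop(v_post %*% (hyper$omega / hyper$sigma_r2 +
                                      sig_inv %*% colSums(xs)))
        mu[[k]] <- drop(mu_post + t(chol_spd(v_post)) %*% stats::rnorm(d))
        dev <- sweep(xs, 2L, mu[[k]])
        scatter <- crossprod(dev)
        cc <- comps[[u[[k]]]]
        Sigma[[k]] <- iw_sample(1L, cc$scale + scatter, cc$dof + m)
      }

      ## --- component assignment updates
      for (k in seq_along(mu)) {
        gusage[u[[k]]] <- gusage[u[[k]]] - 1
        ctxc <- ctx_counts_for(cl_ctx[[k]])
        ctxc[u[[k]]] <- ctxc[u[[k]]] - 1  # exclude this cluster
        pr <- comp_choice_probs(ctxc, gusage, crp)
        fresh <- draw_component_prior(hyper)
        lw <- c(
          vapply(seq_along(comps), function(j)
            log(pr[[j]]) + iw_logpdf(Sigma[[k]], comps[[j]]$scale,
                                     comps[[j]]$dof), numeric(1)),
          log(pr[[length(pr)]]) + iw_logpdf(Sigma[[k]], fresh$scale,
                                            fresh$dof))
        lw[!is.finite(lw)] <- -Inf
        pick <- sample.int(length(lw), 1L, prob = exp(lw - max(lw)))
        if (pick > length(comps)) {
          comps[[length(comps) + 1L]] <- fresh
          gusage <- c(gusage, 0)
          pick <- length(comps)
        }
        u[[k]] <- pick
        gusage[pick] <- gusage[pick] + 1
        dead <- which(gusage == 0)
        if (length(dead) > 0) {
          keepc <- setdiff(seq_along(comps), dead)
          comps <- comps[keepc]; gusage <- gusage[keepc]
          u <- match(u, keepc)
        }
      }

      ## --- component parameter updates (Metropolis-Hastings)
      for (j in seq_along(comps)) {
        members <- which(u == j)
        phi <- comps[[j]]$scale; v <- comps[[j]]$dof
        dfp <- cfg$phi_proposal_dof
        phi_star <- stats::rWishart(1L, dfp, phi / dfp)[, , 1L]
        if (is_spd(phi_star)) {
          logr <- iw_logpdf(phi_star, hyper$top_scale, hyper$v_t) -
            iw_logpdf(phi, hyper$top_scale, hyper$v_t) +
            sum(vapply(members, function(k)
              iw_logpdf(Sigma[[k]], phi_star, v), numeric(1))) -
            sum(vapply(members, function(k)
              iw_logpdf(Sigma[[k]], phi, v), numeric(1))) +
            wishart_logpdf(phi, phi_star / dfp, dfp) -
            wishart_logpdf(phi_star, phi / dfp, dfp)
          acc_phi[2] <- acc_phi[2] + 1
          if (is.finite(logr) && log(stats::runif(1)) < logr) {
            comps[[j]]$scale <- phi_star
            acc_phi[1] <- acc_phi[1] + 1
          }
        }
        ## degrees of freedom
        phi <- comps[[j]]$scale
        t_cur <- log(v - d)
        t_star <- t_cur + stats::rnorm(1L, 0, cfg$v_step)
        v_star <- d + exp(t_star)
        logr <- dtruncnorm(v_star, hyper$v_t, hyper$v_t, lower = d,
                           log = TRUE) -
          dtruncnorm(v, hyper$v_t, hyper$v_t, lower = d, log = TRUE) +
          sum(vapply(members, function(k)
            iw_logpdf(Sigma[[k]], phi, v_star), numeric(1))) -
          sum(vapply(members, function(k)
            iw_logpdf(Sigma[[k]], phi, v), numeric(1))) +
          (t_star - t_cur)  # Jacobian of v = d + exp(t)
        acc_v[2] <- acc_v[2] + 1
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          comps[[j]]$dof <- v_star
          acc_v[1] <- acc_v[1] + 1
        }
      }

      if (sweep > cfg$burn_in &&
          (sweep - cfg$burn_in) %% cfg$thin == 0L) {
        samples[[length(samples) + 1L]] <- list(
          z = z, u = u, mu = mu, Sigma = Sigma, comps = comps,
          gusage = gusage, cl_ctx = cl_ctx, cl_lab = cl_lab)
        lp_trace <- c(lp_trace,
                      gibbs_joint_logprob(X, context, labels, z, u, mu,
                                          Sigma, comps, cl_ctx, hyper))
      }
    }

    structure(list(samples = samples, hyper = hyper,
                   accept = c(phi = acc_phi[1] / max(acc_phi[2], 1),
                              v = acc_v[1] / max(acc_v[2], 1)),
                   joint_logprob = lp_trace),
              class = "fr_posterior")
  })
}

# Full joint log density of an instantiated hierarchy state.
gibbs_joint_logprob <- function(X, context, labels, z, u, mu, Sigma, comps,
                                cl_ctx, hyper) {
  crp <- hyper$crp
  lp <- 0
  for (ctx in unique(context)) {
    sel <- context == ctx
    lp <- lp + crp_joint_logprob(canonical_partition(z[sel]), crp$alpha)
  }
  # sequential hierarchical-CRP prior over cluster -> component assignments
  # (components relabelled in order of first appearance)
  uc <- canonical_partition(u)
  n_comp <- max(uc, 0L)
  gus <- numeric(n_comp)
  ctx_counts <- list()
  seen <- 0L
  for (k in seq_along(uc)) {
    ctx <- cl_ctx[[k]]
    if (is.null(ctx_counts[[ctx]])) ctx_counts[[ctx]] <- numeric(n_comp)
    cc <- ctx_counts[[ctx]]
    pr <- comp_choice_probs(cc[seq_len(seen)], gus[seq_len(seen)], crp)
    jj <- uc[[k]]
    lp <- lp + if (jj > seen) log(pr[[length(pr)]]) else log(pr[[jj]])
    if (jj > seen) seen <- seen + 1L
    gus[jj] <- gus[jj] + 1
    cc[jj] <- cc[jj] + 1
    ctx_counts[[ctx]] <- cc
  }
  for (j in seq_along(comps)) {
    lp <- lp + iw_logpdf(comps[[j]]$scale, hyper$top_scale, hyper$v_t) +
      dtruncnorm(comps[[j]]$dof, hyper$v_t, hyper$v_t, lower = hyper$dim,
                 log = TRUE)
  }
  for (k in seq_along(mu)) {
    lp <- lp + iw_logpdf(Sigma[[k]], comps[[u[[k]]]]$scale,
                         comps[[u[[k]]]]$dof) +
      dmvnorm_log(mu[[k]], hyper$omega,
                  diag(hyper$sigma_r2, hyper$dim)) +
      sum(dmvnorm_log(X[z == k, , drop = FALSE], mu[[k]], Sigma[[k]]))
  }
  lp
}

#' Prior sample set for the untrained model
#'
#' Snapshots with no observed clusters; similarity computations seeded from
#' these reflect the isotropic top-level prior only.
#'
#' @param hyper An [fr_hyper()].
#' @param n_samples Number of snapshots.
#' @param seed Integer seed.
#' @return An `fr_posterior` object with empty cluster structure.
#' @export
prior_sample_set <- function(hyper, n_samples = 1000L, seed = 1L) {
  samples <- replicate(n_samples, list(
    z = integer(0), u = integer(0), mu = list(), Sigma = list(),
    comps = list(), gusage = numeric(0), cl_ctx = character(0),
    cl_lab = character(0)), simplify = FALSE)
  structure(list(samples = samples, hyper = hyper,
                 accept = c(phi = NA, v = NA),
                 joint_logprob = numeric(0)),
            class = "fr_posterior")
}

#' Modal component covariances of posterior samples
#'
#' For selected posterior snapshots, returns each component's most probable
#' covariance matrix `scale / (dof + D + 1)`, the summary used to hand a
#' Gibbs-trained component structure to the particle filter.
#'
#' @param posterior An `fr_posterior`.
#' @param which_samples Indices of snapshots to summarize (default: ten
#'   evenly spaced).
#' @return List (per snapshot) of lists of modal covariance matrices with
#'   their global usage weights.
#' @export
posterior_modal_components <- function(posterior, which_samples = NULL) {
  ns <- length(posterior$samples)
  if (is.null(which_samples))
    which_samples <- unique(round(seq(1, ns, length.out = min(10, ns))))
  lapply(which_samples, function(i) {
    s <- posterior$samples[[i]]
    list(covs = lapply(s$comps, function(cc) iw_mode(cc$scale, cc$dof)),
         weights = if (length(s$gusage) > 0) s$gusage / sum(s$gusage)
                   else numeric(0))
  })
}
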