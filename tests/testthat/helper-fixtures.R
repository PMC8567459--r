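# Shared test fixtures and small independent oracles.

# Trained two-component hyperparameter bundle for small-fixture tests.
toy_hyper <- function(alpha = 10, alpha_c = 0.001, sigma_r2 = 0.1,
                      omega = c(0, 0), dim = 2L) {
  fr_hyper(crp_params(alpha, alpha_c, 0), sigma_r2 = sigma_r2,
           omega = omega, dim = dim)
}

# Independent marginal likelihood of one cluster: joint multivariate normal
# over the stacked member vector with covariance
# blockdiag(Sigma) + sigma_r2 * (J x J ones kron I_D).
brute_cluster_loglik <- function(members, cov, hyper) {
  m <- nrow(members)
  if (m == 0L) return(0)
  d <- ncol(members)
  big <- kronecker(diag(m), cov) +
    hyper$sigma_r2 * kronecker(matrix(1, m, m), diag(d))
  x <- as.vector(t(members))
  mu <- rep(hyper$omega, m)
  dmvnorm_log(matrix(x, 1L), mu, big)
}

# Independent brute-force posterior over partitions: plain loops, joint
# normal likelihoods, explicit enumeration of component assignments.
brute_exact_posterior <- function(X, components, hyper, labels = NULL) {
  n <- nrow(X)
  parts <- enumerate_partitions(n)
  J <- length(components$matrices)
  L <- if (is.null(labels)) 0L else length(unique(labels[!is.na(labels)]))
  lp <- vapply(parts, function(z) {
    k <- max(z)
    if (!is.null(labels)) {
      for (kk in seq_len(k))
        if (length(unique(stats::na.omit(labels[z == kk]))) > 1L)
          return(-Inf)
    }
    assignments <- as.matrix(expand.grid(rep(list(seq_len(J)), k)))
    terms <- apply(assignments, 1L, function(u) {
      lpu <- 0
      cc <- numeric(J)
      for (kk in seq_len(k)) {
        pr <- (cc + hyper$crp$alpha_c / J) / (sum(cc) + hyper$crp$alpha_c)
        lpu <- lpu + log(pr[u[kk]])
        cc[u[kk]] <- cc[u[kk]] + 1
        lpu <- lpu + brute_cluster_loglik(X[z == kk, , drop = FALSE],
                                          components$matrices[[u[kk]]],
                                          hyper)
      }
      lpu
    })
    mx <- max(terms)
    lab_term <- if (L > 0) -k * log(L) else 0
    crp_joint_logprob(z, hyper$crp$alpha) + lab_term +
      mx + log(sum(exp(terms - mx)))
  }, numeric(1))
  keys <- vapply(parts, function(z) paste(z, collapse = "-"), character(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  stats::setNames(pr, keys)
}

# Small labeled 2-D fixture: two tight pairs with different labels.
toy_labeled_fixture <- function() {
  list(X = rbind(c(-1, 0), c(-0.9, 0.1), c(1, 0), c(0.9, -0.1)),
       labels = c("A", "A", "B", "B"))
}

# All permutations of 1:n (tiny n only).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}
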