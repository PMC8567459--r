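test_that("the collapsed-mean cluster predictive matches closed forms and
           quadrature", {
  hyper <- toy_hyper(sigma_r2 = 1, omega = c(0, 0))
  x <- c(0.3, -0.2)
  # empty cluster: N(omega, Sigma + sigma_r2 I)
  expect_equal(cluster_predictive_fixed_cov(x, NULL, diag(2), hyper),
               dmvnorm_log(matrix(x, 1), c(0, 0), 2 * diag(2)))
  # posterior concentration: many members at a common mean
  members <- matrix(rep(c(1, 1), 500), ncol = 2, byrow = TRUE)
  expect_equal(cluster_predictive_fixed_cov(x, members, diag(2), hyper),
               dmvnorm_log(matrix(x, 1), c(1, 1), diag(2)),
               tolerance = 1e-2)
  # 1-D quadrature oracle: integral over mu of N(x; mu, s2) N(mu; w, r2)
  h1 <- fr_hyper(crp_params(1, 1, 0), sigma_r2 = 0.7, omega = 0.5,
                 dim = 1L)
  mem <- matrix(c(0.1, 0.9, 0.4))
  s2 <- 0.6
  f <- function(mu) vapply(mu, function(m)
    exp(sum(dnorm(c(mem), m, sqrt(s2), log = TRUE)) +
          dnorm(m, 0.5, sqrt(0.7), log = TRUE) +
          dnorm(1.2, m, sqrt(s2), log = TRUE)), numeric(1))
  num <- integrate(f, -10, 10, rel.tol = 1e-12)$value
  den <- integrate(function(mu) vapply(mu, function(m)
    exp(sum(dnorm(c(mem), m, sqrt(s2), log = TRUE)) +
          dnorm(m, 0.5, sqrt(0.7), log = TRUE)), numeric(1)),
    -10, 10, rel.tol = 1e-12)$value
  expect_equal(
    cluster_predictive_fixed_cov(1.2, mem, matrix(s2), h1, log = FALSE),
    num / den, tolerance = 1e-8)
  expect_error(cluster_predictive_fixed_cov(x, NULL,
                                            matrix(c(1, 2, 2, 1), 2),
                                            hyper), "SPD")
})

make_sym_state <- function(alpha = 10, alpha_c = 0.001, c_d = 1,
                           sigma_r2 = 0.5) {
  comps <- component_set(c("nw", "wn"), c_d = c_d)
  hyper <- fr_hyper(crp_params(alpha, alpha_c, 0), sigma_r2 = sigma_r2,
                    omega = c(0, 0), dim = 2L)
  st <- hier_state(hyper, comps, label_set = c("A", "B"))
  for (i in 1:3) st <- observe(st, c(-1, 0) + 0.01 * i, "A", "ctx")
  for (i in 1:3) st <- observe(st, c(1, 0) - 0.01 * i, "B", "ctx")
  st
}

test_that("assignment posterior is symmetric, normalized, and vanishes for
           new clusters as alpha -> 0", {
  st <- make_sym_state()
  post <- assignment_posterior(st, c(0, 0), "ctx")
  expect_equal(sum(post$prob), 1, tolerance = 1e-12)
  pa <- sum(post$prob[which(post$label == "A")])
  pb <- sum(post$prob[which(post$label == "B")])
  expect_equal(pa, pb, tolerance = 1e-2)
  st_small <- make_sym_state(alpha = 1e-8)
  post_small <- assignment_posterior(st_small, c(0, 0), "ctx")
  expect_lt(sum(post_small$prob[is.na(post_small$cluster)]), 1e-6)
})

test_that("classification is a proper distribution with sensible limits", {
  st <- make_sym_state()
  p <- classify(st, c(0, 0), "ctx")
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p["A"]), 0.5, tolerance = 1e-2)
  # query at the heart of the A cluster, tiny alpha and well-separated
  # clusters -> P(A) ~ 1
  st2 <- make_sym_state(alpha = 1e-6, c_d = 2, sigma_r2 = 5)
  p2 <- classify(st2, c(-0.98, 0), "ctx")
  expect_gt(p2[["A"]], 0.99)
  # a distant unrelated cluster barely changes the answer
  st3 <- make_sym_state()
  st3 <- observe(st3, c(60, 60), "B", "ctx")
  p3 <- classify(st3, c(0, 0), "ctx")
  expect_lt(abs(p3[["A"]] - p[["A"]]), 1e-6)
})

test_that("classification matches a hand-built Bayes computation", {
  comps <- component_set(c("nw", "wn"), c_d = 1)
  hyper <- fr_hyper(crp_params(2, 0.001, 0), sigma_r2 = 0.5,
                    omega = c(0, 0), dim = 2L)
  st <- hier_state(hyper, comps, label_set = c("A", "B"))
  st <- observe(st, c(-0.5, 0.2), "A", "c1")
  st <- observe(st, c(0.6, -0.1), "B", "c1")
  x <- c(0.15, 0.05)
  post <- assignment_posterior(st, x, "c1")
  # manual: cluster priors 1/(2+2) each, new 2/(2+2) split over components
  k1 <- st$X[st$z == 1, , drop = FALSE]
  k2 <- st$X[st$z == 2, , drop = FALSE]
  cov1 <- comps$matrices[[st$cl_component[1]]]
  cov2 <- comps$matrices[[st$cl_component[2]]]
  w1 <- (1 / 4) * cluster_predictive_fixed_cov(x, k1, cov1, hyper,
                                               log = FALSE)
  w2 <- (1 / 4) * cluster_predictive_fixed_cov(x, k2, cov2, hyper,
                                               log = FALSE)
  ctx_counts <- tabulate(factor(st$cl_component, levels = 1:2))
  cp <- hcrp_component_probs(ctx_counts, hyper$crp)
  wn <- (2 / 4) * cp * c(
    cluster_predictive_fixed_cov(x, NULL, comps$matrices[[1]], hyper,
                                 log = FALSE),
    cluster_predictive_fixed_cov(x, NULL, comps$matrices[[2]], hyper,
                                 log = FALSE))
  manual <- c(w1, w2, wn) / sum(c(w1, w2, wn))
  expect_equal(post$prob, manual, tolerance = 1e-10)
  p <- classify(st, x, "c1")
  expect_equal(unname(p["A"]),
               manual[1] + sum(manual[3:4]) / 2, tolerance = 1e-10)
})

test_that("observe keeps clusters label-pure and is reproducible", {
  comps <- component_set(c("nw", "wn"), c_d = 1)
  hyper <- fr_hyper(crp_params(5, 0.001, 0), sigma_r2 = 0.5,
                    omega = c(0, 0), dim = 2L)
  set.seed(42)
  st <- hier_state(hyper, comps, label_set = c("A", "B"))
  for (t in 1:30) {
    x <- rnorm(2, 0, 0.5)
    lab <- sample(c("A", "B"), 1)
    st <- observe(st, x, lab, "c1", mode = "sample")
  }
  for (k in seq_along(st$cl_component))
    expect_length(unique(st$label[st$z == k]), 1L)
  # map mode is deterministic
  a <- observe(st, c(0.2, 0.2), "A", "c1", mode = "map")
  b <- observe(st, c(0.2, 0.2), "A", "c1", mode = "map")
  expect_identical(a$z, b$z)
  # sample mode reproducible under a fixed seed
  set.seed(7); s1 <- observe(st, c(0.2, 0.2), "A", "c1", mode = "sample")
  set.seed(7); s2 <- observe(st, c(0.2, 0.2), "A", "c1", mode = "sample")
  expect_identical(s1$z, s2$z)
})

test_that("classification with isotropic components is rotation invariant", {
  comps <- component_set("ww", c_d = 1)
  hyper <- fr_hyper(crp_params(5, 0.001, 0), sigma_r2 = 0.5,
                    omega = c(0, 0), dim = 2L)
  base_pts <- rbind(c(-0.6, 0.3), c(0.5, 0.4), c(0.1, -0.7))
  labs <- c("A", "B", "B")
  theta <- pi / 5
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  build <- function(pts) {
    st <- hier_state(hyper, comps, label_set = c("A", "B"))
    for (i in seq_len(nrow(pts)))
      st <- observe(st, pts[i, ], labs[i], "c1", mode = "map")
    st
  }
  q <- c(0.2, 0.1)
  p1 <- classify(build(base_pts), q, "c1")
  p2 <- classify(build(base_pts %*% t(rot)), drop(rot %*% q), "c1")
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("the state joint density rejects inconsistent states and matches
           its named terms on a one-item state", {
  comps <- component_set(c("nw", "wn"), c_d = 1)
  hyper <- fr_hyper(crp_params(3, 0.01, 0), sigma_r2 = 0.5,
                    omega = c(0, 0), dim = 2L)
  st <- hier_state(hyper, comps, label_set = c("A", "B"))
  st <- observe(st, c(0.4, -0.3), "A", "c1", mode = "map")
  jj <- st$cl_component[1]
  manual <- log(1) +                       # CRP: first item, forced
    log(0.5) +                             # component choice, symmetric
    log(1 / 2) +                           # uniform label base rate
    cluster_predictive_fixed_cov(c(0.4, -0.3), NULL,
                                 comps$matrices[[jj]], hyper)
  expect_equal(state_joint_logprob(st), manual, tolerance = 1e-12)
  # empty clusters are structurally impossible
  broken <- st
  broken$cl_component <- c(broken$cl_component, 2L)
  broken$cl_label <- c(broken$cl_label, "B")
  broken$cl_context <- c(broken$cl_context, "c1")
  expect_error(state_joint_logprob(broken), "empty cluster")
})
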