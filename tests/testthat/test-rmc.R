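test_that("the beta-binomial label likelihood matches direct evaluation", {
  ls <- c("A", "B")
  expect_equal(rmc_label_likelihood(c(A = 3, B = 0), "A", 0.1, ls),
               3.1 / 3.2)
  expect_equal(rmc_label_likelihood(c(A = 0, B = 0), "A", 0.1, ls), 0.5)
  # sums to one over labels
  cnts <- c(A = 2, B = 5)
  expect_equal(rmc_label_likelihood(cnts, "A", 0.3, ls) +
                 rmc_label_likelihood(cnts, "B", 0.3, ls), 1)
})

test_that("the cluster feature predictive is a per-dimension t density", {
  p <- rmc_params(omega = c(0, 0))
  # empty cluster: prior predictive t with a0 dof per dimension
  x <- c(0.4, -1.1)
  scale <- sqrt(p$sigma0_2 * (1 + 1 / p$lambda0))
  manual <- sum(dt(x / scale, df = p$a0, log = TRUE) - log(scale))
  expect_equal(rmc_cluster_predictive(x, NULL, p), manual)
  # factorizes across dimensions
  members <- rbind(c(0.2, 1), c(-0.3, 0.5), c(0.1, 0.7))
  p1 <- rmc_params(omega = 0)
  joint <- rmc_cluster_predictive(x, members, p)
  marg <- rmc_cluster_predictive(x[1], members[, 1, drop = FALSE], p1) +
    rmc_cluster_predictive(x[2], members[, 2, drop = FALSE], p1)
  expect_equal(joint, marg, tolerance = 1e-12)
  # matches 1-D numerical integration over the conjugate posterior
  mem <- matrix(c(0.3, 0.8, -0.1))
  f <- function(mu, s2) exp(sum(dnorm(c(mem), mu, sqrt(s2), log = TRUE)) +
                              dnorm(mu, 0, sqrt(s2 / 1), log = TRUE) +
                              # inverse-chi-square(a0=1, s0=2.25) density
                              log(2.25 / 2) * 0.5 - lgamma(0.5) -
                              (0.5 + 1) * log(s2) - 2.25 / (2 * s2) +
                              dnorm(0.9, mu, sqrt(s2), log = TRUE))
  num <- integrate(function(s2v) vapply(s2v, function(s2)
    integrate(function(muv) vapply(muv, f, numeric(1), s2 = s2),
              -8, 8)$value, numeric(1)), 1e-4, 200)$value
  den <- integrate(function(s2v) vapply(s2v, function(s2)
    integrate(function(muv) vapply(muv, function(mu)
      exp(sum(dnorm(c(mem), mu, sqrt(s2), log = TRUE)) +
            dnorm(mu, 0, sqrt(s2), log = TRUE) +
            log(2.25 / 2) * 0.5 - lgamma(0.5) -
            (0.5 + 1) * log(s2) - 2.25 / (2 * s2)), numeric(1)),
      -8, 8)$value, numeric(1)), 1e-4, 200)$value
  expect_equal(rmc_cluster_predictive(0.9, mem, rmc_params(omega = 0),
                                      log = FALSE),
               num / den, tolerance = 1e-3)
})

test_that("the local-MAP run is deterministic and starts with one cluster", {
  fx <- toy_labeled_fixture()
  p <- rmc_params(omega = colMeans(fx$X))
  a <- rmc_run(fx$X, fx$labels, p)
  b <- rmc_run(fx$X, fx$labels, p)
  expect_identical(a$z, b$z)
  expect_identical(a$z[1], 1L)
  expect_equal(a$p_correct[1], 0.5)
})

test_that("the mixture interpolates between prototype and exemplar
           limits", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  labs <- rep(c("A", "B"), 5)
  # alpha -> 0: a single cluster for everything (prototype limit)
  proto <- rmc_run(X, labs, rmc_params(alpha = 1e-10,
                                       omega = colMeans(X)))
  expect_identical(max(proto$z), 1L)
  # huge alpha and tiny prior variance: one cluster per item (exemplars)
  exem <- rmc_run(X, labs, rmc_params(alpha = 1e8, sigma0_2 = 1e-4,
                                      omega = colMeans(X)))
  expect_identical(max(exem$z), 10L)
})

test_that("learning-curve aggregation averages orders reproducibly", {
  struct <- condensation_filtration_structure("filtration_dim1",
                                              n_blocks = 3)
  a <- rmc_learning_curve(struct, n_orders = 5, seed = 2)
  b <- rmc_learning_curve(struct, n_orders = 5, seed = 2)
  expect_equal(a$per_block$error, b$per_block$error)
  expect_true(all(a$per_block$error >= 0 & a$per_block$error <= 1))
})
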