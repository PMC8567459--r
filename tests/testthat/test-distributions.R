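test_that("CRP assignment probabilities follow the rich-get-richer form", {
  expect_equal(crp_assignment_probs(c(2, 1), 10), c(2, 1, 10) / 13)
  expect_equal(crp_assignment_probs(integer(0), 5), 1)
  expect_equal(crp_assignment_probs(5, 1), c(5 / 6, 1 / 6))
  expect_error(crp_assignment_probs(c(2, 1), -1), "positive")
  # normalization across a spread of partitions and alphas
  for (alpha in c(0.1, 1, 10)) {
    for (counts in list(1, c(3, 2), c(5, 1, 1, 1))) {
      expect_equal(sum(crp_assignment_probs(counts, alpha)), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("CRP joint log probability matches sequential products and is
           exchangeable", {
  # all items together: prod (i-1)/(i-1+1) for alpha = 1 -> 1/n
  for (n in 2:6)
    expect_equal(crp_joint_logprob(rep(1, n), 1), -log(n))
  # all singletons, alpha = 1: prod 1/(i - 1 + 1) = 1/n!
  expect_equal(crp_joint_logprob(1:3, 1), log(1 / 6))
  # exchangeability: every permutation of items gives identical values
  z <- c(1, 1, 2, 3, 2, 1)
  base <- crp_joint_logprob(z, 2.5)
  perms <- replicate(50, sample(length(z)), simplify = FALSE)
  for (p in perms)
    expect_identical(crp_joint_logprob(z[p], 2.5), base)
  # full enumeration at n = 4 sums to one
  total <- sum(vapply(enumerate_partitions(4),
                      function(z) exp(crp_joint_logprob(z, 1.7)),
                      numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("hierarchical CRP component probabilities interpolate between
           context counts and global weights", {
  p <- crp_params(10, 0.001, 0)
  expect_equal(hcrp_component_probs(c(0, 0), p), c(0.5, 0.5))
  probs <- hcrp_component_probs(c(3, 0), p)
  expect_equal(probs, c(3.0005, 0.0005) / 3.001, tolerance = 1e-12)
  # alpha_c -> Inf recovers the global distribution
  pinf <- crp_params(10, Inf, 0)
  expect_equal(hcrp_component_probs(c(7, 0, 1), pinf), rep(1 / 3, 3))
  # alpha_c -> 0 with nonzero counts recovers the context frequencies
  p0 <- crp_params(10, 1e-12, 0)
  expect_equal(hcrp_component_probs(c(3, 1), p0), c(0.75, 0.25),
               tolerance = 1e-9)
  # new-component slot appears with alpha_g > 0 and everything normalizes
  pg <- crp_params(10, 0.5, 1)
  pr <- hcrp_component_probs(c(2, 0), pg, global_usage = c(1, 1))
  expect_length(pr, 3L)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_error(hcrp_component_probs(numeric(0), p), "fixed")
})

test_that("inverse-Wishart density has the right mode and normalizes in 1-D", {
  # argmax over diagonal 2x2 SPD matrices at scale/(dof + d + 1)
  v <- 30; scale <- diag(2)
  mode <- iw_mode(scale, v)
  expect_equal(mode, diag(2) / 33)
  f <- function(a, b) iw_logpdf(diag(c(a, b)), scale, v)
  opt <- optim(c(0.05, 0.05), function(p) -f(p[1], p[2]),
               lower = c(1e-4, 1e-4), method = "L-BFGS-B")
  expect_equal(opt$par, diag(mode), tolerance = 1e-2)
  # 1-D case integrates to one (inverse-gamma reduction) by quadrature
  q <- integrate(function(x)
    vapply(x, function(xx) exp(iw_logpdf(matrix(xx), matrix(2), 5)),
           numeric(1)), 1e-4, Inf, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-5)
  # invariance under joint orthogonal rotation
  r <- rotation_matrix <- matrix(c(cos(0.7), sin(0.7),
                                   -sin(0.7), cos(0.7)), 2)
  x <- matrix(c(2, 0.5, 0.5, 1), 2)
  phi <- matrix(c(1.5, -0.2, -0.2, 0.8), 2)
  expect_equal(iw_logpdf(r %*% x %*% t(r), r %*% phi %*% t(r), 12),
               iw_logpdf(x, phi, 12), tolerance = 1e-10)
  expect_error(iw_logpdf(matrix(c(1, 2, 2, 1), 2), diag(2), 10), "positive")
})

test_that("inverse-Wishart sampling matches its mean and is reproducible", {
  set.seed(4)
  draws <- iw_sample(40000, diag(2), 30)
  expect_equal(apply(draws, c(1, 2), mean), diag(2) / 27, tolerance = 0.02)
  # every draw SPD
  ok <- apply(draws[, , 1:200], 3L, is_spd)
  expect_true(all(ok))
  set.seed(99); a <- iw_sample(1, diag(3), 10)
  set.seed(99); b <- iw_sample(1, diag(3), 10)
  expect_identical(a, b)
})

test_that("sampled inverse-Wishart marginals match the density", {
  set.seed(8)
  draws <- drop(iw_sample(5000, matrix(1.5), 6))
  dens <- function(x) vapply(x, function(xx)
    exp(iw_logpdf(matrix(xx), matrix(1.5), 6)), numeric(1))
  grid <- seq(1e-4, max(draws) * 1.05, length.out = 4000)
  cdf_vals <- cumsum(dens(grid)) * diff(grid[1:2])
  cdf <- stats::approxfun(grid, cdf_vals / max(cdf_vals), rule = 2)
  ks <- suppressWarnings(stats::ks.test(draws, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("truncated normal respects its support and normalizes", {
  set.seed(2)
  draws <- rtruncnorm(10000, 30, 30, lower = 3)
  expect_true(all(draws >= 3))
  q <- integrate(function(x) dtruncnorm(x, 30, 30, lower = 3), 3, Inf)
  expect_equal(q$value, 1, tolerance = 1e-6)
  # lower -> -Inf recovers the untruncated density
  expect_equal(dtruncnorm(1.3, 0, 1, lower = -Inf), dnorm(1.3))
  expect_identical(dtruncnorm(2, 30, 30, lower = 3), 0 * 1)
})

test_that("partition enumeration is exhaustive, canonical, and matches Bell
           numbers", {
  p3 <- enumerate_partitions(3)
  expect_length(p3, 5L)
  expect_length(enumerate_partitions(4), 15L)
  # canonical restricted-growth form, duplicate-free
  keys <- vapply(p3, paste, character(1), collapse = "-")
  expect_identical(anyDuplicated(keys), 0L)
  for (z in p3) expect_identical(z, canonical_partition(z))
  for (n in 1:8)
    expect_identical(length(enumerate_partitions(n, cap = 8)),
                     as.integer(bell_number(n)))
  expect_error(enumerate_partitions(11), "refus")
})

test_that("Bell numbers are exact", {
  expect_identical(bell_number(0), 1)
  expect_identical(bell_number(1), 1)
  expect_identical(bell_number(6), 203)
  expect_identical(bell_number(10), 115975)
  # exact decimal string agrees with the double value where both exist
  expect_identical(bell_number(20, as_character = TRUE), "51724158235372")
})
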