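test_that("forward-generated Minkowski fields are recovered by the fit", {
  for (r_true in c(0.5, 1, 2)) {
    f <- minkowski_field(r_true, decay = 1.2, half_width = 2, n_grid = 17)
    fit <- fit_minkowski(f)
    expect_lt(abs(fit$r - r_true), 0.1)
  }
  # axis rotation is recovered (modulo the 90-degree ball symmetry)
  f45 <- minkowski_field(1, decay = 1.2, theta = pi / 4)
  fit45 <- fit_minkowski(f45)
  expect_lt(abs(fit45$r - 1), 0.15)
  expect_lt(min(abs(fit45$theta - pi / 4), abs(fit45$theta + pi / 4 -
                                                 pi / 2)), 0.1)
  # unequal weights
  fw <- minkowski_field(2, weights = c(0.7, 0.3), decay = 1)
  fitw <- fit_minkowski(fw)
  expect_lt(abs(fitw$r - 2), 0.1)
  expect_error(fit_minkowski(structure(list(
    reference = c(0, 0), ax1 = -2:2, ax2 = -2:2, pair = c(1L, 2L),
    values = matrix(0.5, 5, 5)), class = "similarity_field")),
    "flat field")
})

test_that("convexity witnesses appear exactly for sub-metric exponents", {
  # any true metric (r >= 1) has convex level sets: no witnesses
  for (r_true in c(1, 1.5, 2)) {
    f <- minkowski_field(r_true, decay = 1, half_width = 2, n_grid = 21)
    chk <- convexity_and_triangle_check(f, level_frac = 0.5)
    expect_true(chk$convex)
    expect_identical(chk$n_witnesses, 0L)
  }
  # r = 1/2 level sets are star-shaped: witnesses exist
  f05 <- minkowski_field(0.5, decay = 1, half_width = 2, n_grid = 21)
  chk05 <- convexity_and_triangle_check(f05, level_frac = 0.5)
  expect_false(chk05$convex)
  expect_gt(chk05$n_witnesses, 0L)
})

test_that("d-prime follows the standard normal-quantile form", {
  expect_equal(dprime(0.84, 0.16), qnorm(0.84) - qnorm(0.16))
  expect_equal(dprime(0.84, 0.16), 1.989, tolerance = 1e-3)
  expect_equal(dprime(0.3, 0.3), 0)
  # antisymmetry under swapping hit and false-alarm roles
  expect_equal(dprime(0.9, 0.2), -dprime(0.2, 0.9))
  # perfect separation is clipped to a finite value
  expect_true(is.finite(dprime(1, 0, n = 20)))
  expect_equal(dprime(1, 0, n = 20), qnorm(39 / 40) - qnorm(1 / 40))
})

test_that("similarity under a fixed component set is unimodal, bounded, and
           matches a hand-built mixture", {
  comps <- component_set(c("nw", "wn"), c_d = 1)
  hyper <- fr_hyper(crp_params(10, 0.001, 0), sigma_r2 = 1,
                    omega = c(0, 0), dim = 2L)
  x <- c(0.1, -0.05)
  # hand computation: hypothesis weights prop to density of x under an
  # empty cluster; membership is the normalized posterior predictive
  wts <- vapply(1:2, function(j)
    0.5 * cluster_predictive_fixed_cov(x, NULL, comps$matrices[[j]],
                                       hyper, log = FALSE), numeric(1))
  wts <- wts / sum(wts)
  member <- function(xs, j) {
    sig_inv <- solve(comps$matrices[[j]])
    v1 <- solve(diag(2) + sig_inv)
    m1 <- drop(v1 %*% (sig_inv %*% x))
    p <- solve(comps$matrices[[j]] + v1)
    exp(-0.5 * drop(t(xs - m1) %*% p %*% (xs - m1)))
  }
  xs <- c(0.3, 0.2)
  manual <- wts[1] * member(xs, 1) + wts[2] * member(xs, 2)
  expect_equal(similarity(x, xs, comps, hyper), manual, tolerance = 1e-10)
  # bounded and (near-)maximal at the reference
  f <- iso_similarity_field(comps, hyper, reference = x,
                            half_width = 1, n_grid = 15)
  expect_true(all(f$values >= 0 & f$values <= 1))
  expect_gte(max(f$values) + 1e-9, f$values[8, 8])
  center_idx <- which(f$values == max(f$values), arr.ind = TRUE)[1, ]
  expect_true(all(abs(center_idx - c(8, 8)) <= 1))
})

test_that("similarity with one isotropic component depends only on
           distance", {
  comps <- component_set("ww", c_d = 1)
  hyper <- fr_hyper(crp_params(10, 0.001, 0), sigma_r2 = 1,
                    omega = c(0, 0), dim = 2L)
  d0 <- 0.8
  angles <- seq(0, 2 * pi, length.out = 9)
  vals <- vapply(angles, function(a)
    similarity(c(0, 0), d0 * c(cos(a), sin(a)), comps, hyper), numeric(1))
  expect_lt(max(vals) - min(vals), 1e-10)
})

test_that("axis-mirror symmetry of fields built from axis-aligned
           component sets", {
  comps <- component_set(c("nw", "wn"), c_d = 1)
  hyper <- fr_hyper(crp_params(10, 0.001, 0), sigma_r2 = 1,
                    omega = c(0, 0), dim = 2L)
  f <- iso_similarity_field(comps, hyper, reference = c(0, 0),
                            half_width = 1.5, n_grid = 15)
  expect_equal(f$values, f$values[15:1, ], tolerance = 1e-9)
  expect_equal(f$values, f$values[, 15:1], tolerance = 1e-9)
})

test_that("per-dimension discrimination d-prime reflects component
           narrowness", {
  grid <- discrimination_grid("1d_dim1", spacing = 0.5)
  hyper <- fr_hyper(crp_params(10, 0.001, 0), sigma_r2 = 1,
                    omega = c(0, 0), dim = 2L)
  # a component narrow on dimension 1 makes dimension-1 neighbors easy to
  # tell apart
  comps <- component_set("nw", c_d = 1)
  res <- discrimination_dprime(comps, hyper, grid$stimuli, grid$pairs)
  expect_gt(res$dprime[["dim1"]], res$dprime[["dim2"]])
  expect_true(all(is.finite(res$dprime)))
})
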