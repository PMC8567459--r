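test_that("exact partition posteriors match an independent brute-force
           enumeration", {
  # unlabeled six-stimulus fixture, two components
  task <- free_classification_structure()
  X <- task$structure$stimuli
  reg <- regime("dimensional_development", narrow_sd = 0.6)
  hyper <- fr_hyper(reg$crp, sigma_r2 = reg$sigma_r2,
                    omega = colMeans(X), dim = 2L)
  ex <- exact_posterior(X, reg$components, hyper)
  brute <- brute_exact_posterior(X, reg$components, hyper)
  expect_equal(attr(ex, "probs")[names(brute)], brute, tolerance = 1e-10)
  lp <- ex$logprob[is.finite(ex$logprob)]
  expect_equal(sum(ex$prob), 1, tolerance = 1e-12)

  # labeled four-stimulus fixture
  fx <- toy_labeled_fixture()
  comps <- component_set(c("nw", "wn"), c_d = 1)
  h2 <- toy_hyper(sigma_r2 = 0.5)
  ex2 <- exact_posterior(fx$X, comps, h2, labels = fx$labels)
  brute2 <- brute_exact_posterior(fx$X, comps, h2, labels = fx$labels)
  keep <- names(brute2)[brute2 > 0]
  expect_equal(attr(ex2, "probs")[keep], brute2[keep], tolerance = 1e-10)
  # partitions mixing labels carry zero mass
  mixed <- ex2$prob[ex2$partition == "1-1-1-1"]
  expect_identical(mixed, 0)
})

test_that("two coincident points prefer sharing a cluster", {
  # likelihood dominance requires clusters tighter than the mean prior
  comps <- component_set("ww", c_d = 5)
  hyper <- toy_hyper(alpha = 5, sigma_r2 = 1)
  X <- rbind(c(0.2, 0.2), c(0.2, 0.2))
  probs <- attr(exact_posterior(X, comps, hyper), "probs")
  expect_gt(probs[["1-1"]], probs[["1-2"]])
})

test_that("Gibbs with fixed components recovers the exact posterior", {
  task <- free_classification_structure()
  X <- task$structure$stimuli
  reg <- regime("dimensional_development", narrow_sd = 0.6)
  hyper <- fr_hyper(reg$crp, sigma_r2 = reg$sigma_r2,
                    omega = colMeans(X), dim = 2L)
  probs <- attr(exact_posterior(X, reg$components, hyper), "probs")
  # pool several chains: the three-mode posterior mixes slowly within one
  pool <- lapply(1:6, function(seed)
    run_gibbs_fixed(X, reg$components, hyper, n_sweeps = 5050,
                    burn_in = 50, seed = seed)$partition_probs)
  keys <- unique(unlist(lapply(pool, names)))
  avg <- vapply(keys, function(k)
    mean(vapply(pool, function(p)
      if (k %in% names(p)) p[[k]] else 0, numeric(1))), numeric(1))
  expect_lt(tv_distance(probs, avg), 0.05)
  # identical seeds give identical chains
  g2 <- run_gibbs_fixed(X, reg$components, hyper, n_sweeps = 200,
                        burn_in = 0, seed = 11)
  g3 <- run_gibbs_fixed(X, reg$components, hyper, n_sweeps = 200,
                        burn_in = 0, seed = 11)
  expect_identical(g2$z, g3$z)
})

test_that("the particle filter tracks the exact sequential posterior", {
  fx <- toy_labeled_fixture()
  comps <- component_set(c("nw", "wn"), c_d = 1)
  hyper <- toy_hyper(sigma_r2 = 0.5)
  pf <- run_particle_filter(fx$X, fx$labels, comps, hyper,
                            n_particles = 4000L, seed = 5)
  probs <- attr(exact_posterior(fx$X, comps, hyper, labels = fx$labels),
                "probs")
  expect_lt(tv_distance(probs, partition_probs_from_particles(pf)), 0.05)
  # label probabilities are proper and start at the uniform base rate
  expect_equal(rowSums(pf$responses), rep(1, 4), tolerance = 1e-10)
  expect_equal(unname(pf$responses[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  # a single particle still runs and stays normalized
  pf1 <- run_particle_filter(fx$X, fx$labels, comps, hyper,
                             n_particles = 1L, seed = 5)
  expect_equal(rowSums(pf1$responses), rep(1, 4), tolerance = 1e-10)
  # seeded reproducibility
  pfa <- run_particle_filter(fx$X, fx$labels, comps, hyper,
                             n_particles = 50L, seed = 9)
  pfb <- run_particle_filter(fx$X, fx$labels, comps, hyper,
                             n_particles = 50L, seed = 9)
  expect_identical(pfa$responses, pfb$responses)
  expect_identical(pfa$z, pfb$z)
})

test_that("particle-filter predictions are stable across seeds", {
  fx <- toy_labeled_fixture()
  comps <- component_set(c("nw", "wn"), c_d = 1)
  hyper <- toy_hyper(sigma_r2 = 0.5)
  means <- vapply(1:25, function(s) {
    pf <- run_particle_filter(fx$X, fx$labels, comps, hyper,
                              n_particles = 400L, seed = s)
    mean(pf$p_correct)
  }, numeric(1))
  expect_lt(stats::sd(means), 0.01)
})

test_that("learning curves start at chance and shrink their error bars with
           more learners", {
  struct <- condensation_filtration_structure("filtration_dim1",
                                              n_blocks = 2)
  reg <- regime("condensation_filtration")
  lc <- learning_curve(struct, reg, n_learners = 8L, n_particles = 30L,
                       seed = 2)
  # first trial of block 1 is at the uniform base rate for every learner
  tr <- trial_stream(struct, 2, seed = 2 + 1)
  pf <- run_particle_filter(tr$X, tr$label, reg$components,
                            fr_hyper(reg$crp, sigma_r2 = reg$sigma_r2,
                                     omega = colMeans(struct$stimuli),
                                     dim = 2L),
                            n_particles = 30L, seed = 2 + 1)
  expect_equal(pf$p_correct[1], 0.5, tolerance = 1e-12)
  lc_big <- learning_curve(struct, reg, n_learners = 32L,
                           n_particles = 30L, seed = 2)
  expect_lt(mean(lc_big$per_block$se), mean(lc$per_block$se))
})
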