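# Reproduction harness: named experiments with deterministic seeding and
# reduced default Monte-Carlo budgets.

#' Mean-error comparison of condensation and filtration learning
#'
#' Runs particle-filter learners through the four boundary conditions under
#' a named regime and reports the mean expected error per condition and the
#' filtration/condensation aggregates.
#'
#' @param regime_name Registry regime (e.g. `"condensation_filtration"`,
#'   `"condensation_filtration_integral"`, `"filtration_unequal"`).
#' @param n_learners Simulated learners per condition.
#' @param n_blocks Training blocks.
#' @param n_particles Particles per learner.
#' @param seed Integer seed.
#' @return List with `per_condition`, `filtration`, `condensation`.
#' @export
experiment_condensation_filtration <- function(
    regime_name = "condensation_filtration", n_learners = 200L,
    n_blocks = 15L, n_particles = 100L, seed = 1L) {
  reg <- regime(regime_name)
  conds <- c("filtration_dim1", "filtration_dim2",
             "condensation_A", "condensation_B")
  errs <- vapply(seq_along(conds), function(i) {
    struct <- condensation_filtration_structure(conds[[i]], n_blocks)
    learning_curve(struct, reg, n_learners = n_learners,
                   n_particles = n_particles,
                   seed = seed + 1000L * i)$mean_error
  }, numeric(1))
  names(errs) <- conds
  list(per_condition = errs,
       filtration = mean(errs[1:2]),
       condensation = mean(errs[3:4]))
}

#' Mean error per problem type for the six classic structures
#'
#' @param regime_name Registry regime (or a `simulation_regime` object).
#' @param types Which problem types to run.
#' @param n_learners,n_blocks,n_particles,seed Simulation budget.
#' @param alpha_c Optional override of the contextual dispersion (e.g.
#'   `Inf` removes the contextual prior).
#' @param narrow_sd Optional developmental widening of the narrow
#'   standard deviations.
#' @return Named vector of mean expected errors (plus attribute `curves`).
#' @export
experiment_shj <- function(regime_name = "shj_separable",
                           types = c("I", "II", "III", "IV", "V", "VI"),
                           n_learners = 200L, n_blocks = 8L,
                           n_particles = 100L, seed = 1L,
                           alpha_c = NULL, narrow_sd = NULL) {
  reg <- if (inherits(regime_name, "simulation_regime")) regime_name
  else regime(regime_name, narrow_sd = narrow_sd)
  if (!is.null(alpha_c))
    reg$crp <- crp_params(reg$crp$alpha, alpha_c, reg$crp$alpha_g)
  curves <- list()
  errs <- vapply(seq_along(types), function(i) {
    struct <- shj_structure(types[[i]], n_blocks = n_blocks)
    lc <- learning_curve(struct, reg, n_learners = n_learners,
                         n_particles = n_particles,
                         seed = seed + 1000L * i)
    curves[[types[[i]]]] <<- lc$per_block
    lc$mean_error
  }, numeric(1))
  names(errs) <- types
  attr(errs, "curves") <- curves
  errs
}

#' Biconditional discrimination with separable versus integral pairings
#'
#' @inheritParams experiment_condensation_filtration
#' @return Named mean errors for the two pairings.
#' @export
experiment_biconditional <- function(n_learners = 200L, n_blocks = 15L,
                                     n_particles = 100L, seed = 1L) {
  reg <- regime("biconditional")
  vapply(stats::setNames(c("separable_pairing", "integral_pairing"),
                         c("separable", "integral")), function(kind) {
    struct <- biconditional_structure(kind, n_blocks)
    learning_curve(struct, reg, n_learners = n_learners,
                   n_particles = n_particles, seed = seed)$mean_error
  }, numeric(1))
}

#' Problem-type ordering as a function of inferential resources
#'
#' Compares Type II and Type IV learning at different particle counts: with
#' many particles the exclusive-or problem is learned faster, with a single
#' particle the ordering reverses (the particle count plays the role of a
#' working-memory capacity analog).
#'
#' @param particle_counts Particle counts to compare.
#' @inheritParams experiment_shj
#' @return Data frame with `n_particles`, `type`, `error`.
#' @export
experiment_particle_count <- function(particle_counts = c(1L, 100L),
                                      types = c("II", "IV"),
                                      n_learners = 200L, n_blocks = 8L,
                                      seed = 1L) {
  out <- NULL
  for (np in particle_counts) {
    errs <- experiment_shj("shj_separable", types = types,
                           n_learners = n_learners, n_blocks = n_blocks,
                           n_particles = np, seed = seed + np)
    out <- rbind(out, data.frame(n_particles = np, type = types,
                                 error = as.numeric(errs)))
  }
  out
}

#' Exact development sweep for the free-classification task
#'
#' For each narrow standard deviation (wider for younger ages), computes the
#' exact partition posterior over the six stimuli and reports the mass on
#' the three critical partitions.
#'
#' @param narrow_sds Narrow standard deviations, oldest last (adults 0.1).
#' @param stimuli Optional coordinate override.
#' @return Data frame with one row per age step: the masses on the critical
#'   partitions, the `other` mass, and the modal critical type.
#' @export
experiment_free_classification_development <- function(
    narrow_sds = c(0.8, 0.6, 0.5, 0.1), stimuli = NULL) {
  task <- free_classification_structure(stimuli)
  X <- task$structure$stimuli
  out <- NULL
  for (nsd in narrow_sds) {
    reg <- regime("dimensional_development", narrow_sd = nsd)
    hyper <- fr_hyper(reg$crp, sigma_r2 = reg$sigma_r2,
                      omega = colMeans(X), dim = ncol(X))
    post <- exact_posterior(X, reg$components, hyper)
    probs <- attr(post, "probs")
    mass <- vapply(task$critical, function(z)
      unname(probs[paste(z, collapse = "-")]), numeric(1))
    mass[is.na(mass)] <- 0
    modal <- names(task$critical)[which.max(mass)]
    out <- rbind(out, data.frame(narrow_sd = nsd, t(mass),
                                 other = 1 - sum(mass),
                                 modal_critical = modal))
  }
  out
}

#' Developmental comparison on the six problem types
#'
#' Children use only the singly narrow components with widened narrow
#' standard deviations; adults the full set.
#'
#' @param groups Named list mapping group name to `list(regime, narrow_sd)`.
#' @inheritParams experiment_shj
#' @return Data frame of mean errors by group and type.
#' @export
experiment_shj_development <- function(
    groups = list(
      adult = list(regime = "shj_development_adults", narrow_sd = NULL),
      child3 = list(regime = "shj_development_children", narrow_sd = 0.8),
      child8 = list(regime = "shj_development_children", narrow_sd = 0.4)),
    types = c("I", "II", "III", "IV"), n_learners = 100L, n_blocks = 3L,
    n_particles = 100L, seed = 1L) {
  out <- NULL
  for (g in names(groups)) {
    errs <- experiment_shj(groups[[g]]$regime, types = types,
                           n_learners = n_learners, n_blocks = n_blocks,
                           n_particles = n_particles, seed = seed,
                           narrow_sd = groups[[g]]$narrow_sd)
    out <- rbind(out, data.frame(group = g, type = types,
                                 error = as.numeric(errs)))
  }
  out
}

#' Rational-model condensation/filtration baseline
#'
#' @param n_orders Random trial orders to average.
#' @param n_blocks Training blocks.
#' @param seed Integer seed.
#' @return List with per-condition mean errors and the
#'   filtration/condensation aggregates.
#' @export
experiment_rmc_filtration <- function(n_orders = 50L, n_blocks = 15L,
                                      seed = 1L) {
  conds <- c("filtration_dim1", "filtration_dim2",
             "condensation_A", "condensation_B")
  errs <- vapply(seq_along(conds), function(i) {
    struct <- condensation_filtration_structure(conds[[i]], n_blocks)
    rmc_learning_curve(struct, rmc_params(), n_orders = n_orders,
                       seed = seed + 100L * i)$mean_error
  }, numeric(1))
  names(errs) <- conds
  list(per_condition = errs, filtration = mean(errs[1:2]),
       condensation = mean(errs[3:4]))
}

#' Train the full hierarchy on a synthetic cluster preset
#'
#' @param preset Preset name from [training_preset()].
#' @param n_per_cluster Points per generating cluster.
#' @param cfg A [gibbs_config()].
#' @param seed Data seed.
#' @return List with the posterior (`fr_posterior`), the training data, and
#'   the hyperparameters used.
#' @export
train_on_preset <- function(preset = "six_axis_aligned",
                            n_per_cluster = 30L,
                            cfg = gibbs_config(), seed = 1L) {
  data <- training_preset(preset, n_per_cluster = n_per_cluster,
                          seed = seed)
  hyper <- fr_hyper(crp_params(10, 0.001, 1), sigma_r2 = 1,
                    omega = colMeans(data$X), v_t = 30, dim = ncol(data$X))
  posterior <- run_gibbs(data$X, data$context, hyper, cfg = cfg)
  list(posterior = posterior, data = data, hyper = hyper)
}

#' Garner filtering experiment with Gibbs-then-filter pipeline
#'
#' Trains the full hierarchy on the categorization square (or skips training
#' for the untrained condition), summarizes posterior snapshots by their
#' modal component covariances, and runs the particle filter on the
#' filtering and baseline test tasks. Interference is baseline accuracy
#' minus filtering accuracy.
#'
#' @param trained Use categorization training before test?
#' @param cfg Gibbs configuration for the training stage.
#' @param n_learners,n_particles Test-stage budget.
#' @param n_snapshots Posterior snapshots summarized into component sets.
#' @param train_spacing Training-square spacing in model units (small, at
#'   the scale of prior-predictive cluster sizes, so that untrained test
#'   stimuli are genuinely confusable).
#' @param seed Integer seed.
#' @return List with `filtering`, `baseline` accuracies and `interference`.
#' @export
experiment_garner <- function(trained = TRUE,
                              cfg = gibbs_config(n_samples = 150L,
                                                 burn_in = 50L),
                              n_learners = 50L, n_particles = 100L,
                              n_snapshots = 10L, train_spacing = 0.05,
                              seed = 1L) {
  tasks <- garner_tasks(train_spacing = train_spacing)
  d <- 3L
  hyper_train <- fr_hyper(crp_params(10, 0.001, 1), sigma_r2 = 1,
                          omega = colMeans(tasks$training$stimuli),
                          v_t = 30, dim = d)
  if (trained) {
    tr <- trial_stream(tasks$training, seed = seed)
    posterior <- run_gibbs(tr$X, rep("train", nrow(tr$X)), hyper_train,
                           labels = tr$label, cfg = cfg)
    kits <- posterior_modal_components(
      posterior, unique(round(seq(1, length(posterior$samples),
                                  length.out = n_snapshots))))
  } else {
    # untrained: component sets drawn from the top-level prior
    kits <- withr_seed(seed, replicate(n_snapshots, {
      cc <- draw_component_prior(hyper_train)
      list(covs = list(iw_mode(cc$scale, cc$dof)), weights = 1)
    }, simplify = FALSE))
  }
  # per-block accuracies; the interference summary keeps only blocks with
  # accuracy above 75%, mirroring the empirical analysis
  run_task <- function(struct, n_blocks) {
    blocks <- NULL
    for (si in seq_along(kits)) {
      covs <- kits[[si]]$covs
      if (length(covs) == 0) next
      comp <- structure(list(
        names = paste0("m", seq_along(covs)), matrices = covs, dim = d,
        c_d = rep(1, d), narrow_single = NA, narrow_double = NA),
        class = "component_set")
      hyper_test <- fr_hyper(crp_params(10, 0.001, 0), sigma_r2 = 0.1,
                             omega = colMeans(struct$stimuli), dim = d)
      for (l in seq_len(max(1L, n_learners %/% length(kits)))) {
        tr <- trial_stream(struct, n_blocks = n_blocks,
                           seed = seed + 37L * si + l)
        pf <- run_particle_filter(tr$X, tr$label, comp, hyper_test,
                                  n_particles = n_particles,
                                  seed = seed + 37L * si + l)
        blocks <- c(blocks, tapply(pf$p_correct, tr$block, mean))
      }
    }
    blocks
  }
  above <- function(b) mean(b[b > 0.75])
  filt_blocks <- run_task(tasks$filtering, 8L)
  base_blocks <- unlist(lapply(tasks$baselines, run_task, n_blocks = 4L))
  filtering <- above(filt_blocks)
  baseline <- above(base_blocks)
  list(filtering = filtering, baseline = baseline,
       interference = baseline - filtering)
}

#' Discrimination-training experiment
#'
#' Trains the full hierarchy on the labeled four-by-four grid, then
#' compares per-dimension discrimination d-prime against the untrained
#' prior baseline.
#'
#' @param training Training labeling (see [discrimination_grid()]).
#' @param spacing Grid spacing in model units (small, at the scale of
#'   prior-predictive cluster sizes, so that untrained neighbors are
#'   genuinely confusable).
#' @param n_copies Presentations of each stimulus during training.
#' @param cfg Gibbs configuration.
#' @param n_reps Independent training repetitions averaged into the
#'   reported sensitivities.
#' @param n_prior_samples Prior snapshots for the baseline.
#' @param seed Integer seed.
#' @return List with `trained` and `baseline` d-prime vectors (averaged
#'   over repetitions) and the per-repetition values.
#' @export
experiment_discrimination <- function(training = "1d_dim1",
                                      spacing = 0.04, n_copies = 12L,
                                      cfg = gibbs_config(n_samples = 300L,
                                                         burn_in = 50L,
                                                         thin = 3L),
                                      n_reps = 2L,
                                      n_prior_samples = 100L, seed = 1L) {
  grid <- discrimination_grid(training, spacing = spacing)
  struct <- grid$structure
  hyper <- fr_hyper(crp_params(10, 0.001, 1), sigma_r2 = 1,
                    omega = colMeans(struct$stimuli), v_t = 30,
                    dim = ncol(struct$stimuli))
  reps <- lapply(seq_len(n_reps), function(r) {
    idx <- withr_seed(seed + 13L * r, {
      unlist(lapply(seq_len(n_copies), function(b) sample(seq_len(16L))))
    })
    X <- struct$stimuli[idx, , drop = FALSE]
    labs <- struct$labels[idx]
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    posterior <- run_gibbs(X, rep("train", nrow(X)), hyper, labels = labs,
                           cfg = cfg_r)
    discrimination_dprime(posterior, hyper, grid$stimuli, grid$pairs,
                          seed = seed + r)$dprime
  })
  trained <- colMeans(do.call(rbind, reps))
  prior <- prior_sample_set(hyper, n_samples = n_prior_samples,
                            seed = seed + 1L)
  baseline <- discrimination_dprime(prior, hyper, grid$stimuli,
                                    grid$pairs, seed = seed + 2L)$dprime
  list(trained = trained, baseline = baseline, reps = reps)
}

## ---- registry -------------------------------------------------------------

.experiment_registry <- function() list(
  filtration_condensation = function(overrides)
    do.call(experiment_condensation_filtration, overrides),
  filtration_condensation_integral = function(overrides)
    do.call(experiment_condensation_filtration,
            utils::modifyList(list(
              regime_name = "condensation_filtration_integral"),
              overrides)),
  filtration_condensation_unequal = function(overrides)
    do.call(experiment_condensation_filtration,
            utils::modifyList(list(regime_name = "filtration_unequal"),
                              overrides)),
  shj_separable = function(overrides)
    do.call(experiment_shj,
            utils::modifyList(list(regime_name = "shj_separable"),
                              overrides)),
  shj_integral = function(overrides)
    do.call(experiment_shj,
            utils::modifyList(list(regime_name = "shj_integral"),
                              overrides)),
  shj_singly_narrow = function(overrides)
    do.call(experiment_shj,
            utils::modifyList(list(regime_name = "shj_singly_narrow"),
                              overrides)),
  shj_no_context_prior = function(overrides)
    do.call(experiment_shj,
            utils::modifyList(list(regime_name = "shj_separable",
                                   alpha_c = Inf,
                                   types = c("II", "III")), overrides)),
  shj_particles = function(overrides)
    do.call(experiment_particle_count, overrides),
  shj_development = function(overrides)
    do.call(experiment_shj_development, overrides),
  biconditional = function(overrides)
    do.call(experiment_biconditional, overrides),
  free_classification_development = function(overrides)
    do.call(experiment_free_classification_development, overrides),
  discrimination_training = function(overrides)
    do.call(experiment_discrimination, overrides),
  garner_untrained = function(overrides)
    do.call(experiment_garner,
            utils::modifyList(list(trained = FALSE), overrides)),
  garner_trained = function(overrides)
    do.call(experiment_garner, overrides),
  rmc_filtration = function(overrides)
    do.call(experiment_rmc_filtration, overrides)
)

#' Fast self-verification report
#'
#' Runs the package's quick analytic sanity checks — exact combinatorics,
#' component-table construction, probability normalization, and
#' exact-enumeration agreement on a two-point fixture — and reports each
#' outcome. The full scientific validation lives in the test suite.
#'
#' @return Data frame with columns `check` and `pass`.
#' @export
verify <- function() {
  checks <- list(
    bell_numbers = function() {
      bell_number(6) == 203 &&
        big_scientific(bell_number(100, as_character = TRUE)) == "4.7e115"
    },
    partition_enumeration = function() {
      all(vapply(4:6, function(n)
        length(enumerate_partitions(n)) == bell_number(n), logical(1)))
    },
    component_table = function() {
      isTRUE(all.equal(component_set("nw", c(1, 1))$matrices$nw,
                       diag(c(0.01, 1)))) &&
        isTRUE(all.equal(component_set("nnw", c(1, 1, 1))$matrices$nnw,
                         diag(c(0.09, 0.09, 1))))
    },
    crp_normalization = function() {
      abs(sum(crp_assignment_probs(c(3, 2, 1), 7)) - 1) < 1e-12 &&
        abs(sum(vapply(enumerate_partitions(5), function(z)
          exp(crp_joint_logprob(z, 1.3)), numeric(1))) - 1) < 1e-10
    },
    exact_posterior_fixture = function() {
      comps <- component_set("ww", c_d = 5)
      hyper <- fr_hyper(crp_params(5, 0.001, 0), sigma_r2 = 1,
                        omega = c(0, 0), dim = 2L)
      probs <- attr(exact_posterior(rbind(c(0.2, 0.2), c(0.2, 0.2)),
                                    comps, hyper), "probs")
      abs(sum(probs) - 1) < 1e-12 && probs[["1-1"]] > probs[["1-2"]]
    },
    iw_mode = function() {
      isTRUE(all.equal(iw_mode(diag(2), 30), diag(2) / 33))
    })
  pass <- vapply(checks, function(f)
    isTRUE(tryCatch(f(), error = function(e) FALSE)), logical(1))
  data.frame(check = names(checks), pass = pass, row.names = NULL)
}

#' Run a named experiment
#'
#' @param name Experiment name; unknown names list the registry.
#' @param overrides Named list of argument overrides (budgets, seeds).
#' @param out_dir Optional directory for result files (a JSON summary and a
#'   CSV where the result is tabular).
#' @return The experiment result object (invisibly when writing files).
#' @export
run_experiment <- function(name, overrides = list(), out_dir = NULL) {
  reg <- .experiment_registry()
  if (!name %in% names(reg))
    stop("unknown experiment '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  result <- reg[[name]](overrides)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      manifest <- list(experiment = name, overrides = overrides,
                       timestamp = format(Sys.time()))
      jsonlite::write_json(manifest,
                           file.path(out_dir, paste0(name,
                                                     "_manifest.json")),
                           auto_unbox = TRUE)
      jsonlite::write_json(result,
                           file.path(out_dir, paste0(name,
                                                     "_result.json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    if (is.data.frame(result))
      utils::write.csv(result, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    return(invisible(result))
  }
  result
}
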