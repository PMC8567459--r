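# Fixed covariance components for the trained approximation, and the named
# per-simulation parameter regimes.

.component_vocab <- c("ww", "nw", "wn",
                      "www", "nww", "wnw", "wwn",
                      "wnn", "nwn", "nnw")

component_rho <- function(name, narrow_single = 0.1, narrow_double = 0.3) {
  letters_ <- strsplit(name, "")[[1]]
  n_narrow <- sum(letters_ == "n")
  rho_n <- if (n_narrow >= 2) narrow_double else narrow_single
  ifelse(letters_ == "n", rho_n, 1)
}

#' Build a named set of fixed covariance components
#'
#' Components are diagonal covariance matrices named by their per-dimension
#' variability pattern: `w` marks a wide dimension (standard deviation 1
#' before scaling) and `n` a narrow one. In singly narrow components the
#' narrow standard deviation is 10% of the wide one; in doubly narrow
#' components the two narrow standard deviations are 30% of the wide one
#' (narrower values would let the doubly narrow components dominate, since
#' the density at a cluster center scales with the inverse volume). Every
#' standard deviation along dimension `d` is divided by the discriminability
#' scale `c[d]`, so entry `d` of component `x` is `(rho_d / c_d)^2`.
#'
#' @param names Character vector drawn from the recognized vocabulary
#'   (`"ww"`, `"nw"`, `"wn"` in two dimensions; `"www"`, `"nww"`, `"wnw"`,
#'   `"wwn"`, `"wnn"`, `"nwn"`, `"nnw"` in three).
#' @param c_d Per-dimension positive scale parameters (recycled to the
#'   component dimensionality).
#' @param narrow_single Narrow-to-wide standard-deviation ratio for singly
#'   narrow components (default 0.1).
#' @param narrow_double Ratio for doubly narrow components (default 0.3).
#' @return An object of class `component_set`: list with `names`, `matrices`
#'   (list of diagonal SPD matrices), `dim`, `c_d`, and the two ratios.
#' @export
component_set <- function(names, c_d = 1, narrow_single = 0.1,
                          narrow_double = 0.3) {
  unknown <- setdiff(names, .component_vocab)
  if (length(unknown) > 0)
    stop("unknown component name(s): ", paste(unknown, collapse = ", "),
         "; vocabulary is: ", paste(.component_vocab, collapse = ", "))
  dims <- nchar(names)
  if (length(unique(dims)) != 1L)
    stop("all components in a set must share one dimensionality")
  d <- dims[[1]]
  c_d <- rep_len(as.numeric(c_d), d)
  if (any(c_d <= 0)) stop("`c_d` must be positive")
  mats <- lapply(names, function(nm) {
    rho <- component_rho(nm, narrow_single, narrow_double)
    diag((rho / c_d)^2, d)
  })
  names(mats) <- names
  structure(list(names = names, matrices = mats, dim = d, c_d = c_d,
                 narrow_single = narrow_single,
                 narrow_double = narrow_double),
            class = "component_set")
}

#' Widen the narrow dimensions of a component set
#'
#' Developmental variants replace the adult narrow standard deviation (0.1
#' before scaling) of singly narrow components with a wider value, modeling
#' less category-learning experience (0.8 for 3-year-olds, 0.6 for
#' 4-year-olds, 0.5 for 5-year-olds, 0.4 for 8-year-olds). The replacement
#' happens on the unit scale, before division by `c_d`.
#'
#' @param set A [component_set()].
#' @param narrow_sd Replacement narrow standard deviation in (0, 1].
#' @return A new `component_set`.
#' @export
developmental_variant <- function(set, narrow_sd) {
  stopifnot(inherits(set, "component_set"))
  if (!is.numeric(narrow_sd) || narrow_sd <= 0 || narrow_sd > 1)
    stop("`narrow_sd` must be in (0, 1]")
  component_set(set$names, set$c_d, narrow_single = narrow_sd,
                narrow_double = set$narrow_double)
}

#' @export
print.component_set <- function(x, ...) {
  cat("Fixed component set (", x$dim, "-D), c = (",
      paste(format(x$c_d), collapse = ", "), ")\n", sep = "")
  for (nm in x$names)
    cat("  ", nm, ": diag(", paste(format(diag(x$matrices[[nm]]), digits = 4),
                                   collapse = ", "), ")\n", sep = "")
  invisible(x)
}

.singly3 <- c("nww", "wnw", "wwn")
.all3 <- c("nww", "wnw", "wwn", "nnw", "nwn", "wnn")

.regime_table <- list(
  condensation_filtration = list(
    components = c("nw", "wn"), c_d = c(0.5, 0.5), alpha = 10,
    alpha_c = 0.001, alpha_g = 0, sigma_r2 = 0.1,
    approximation = "particle_filter"),
  filtration_unequal = list(
    components = c("nw", "wn"), c_d = c(0.5, 1), alpha = 10,
    alpha_c = 0.001, alpha_g = 0, sigma_r2 = 0.1,
    approximation = "particle_filter"),
  condensation_filtration_integral = list(
    components = "ww", c_d = c(2, 2), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  shj_separable = list(
    components = .all3, c_d = rep(2.1, 3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  shj_integral = list(
    components = "www", c_d = rep(2.5, 3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  shj_singly_narrow = list(
    components = .singly3, c_d = rep(2.5, 3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  biconditional = list(
    components = c("wwn", "nnw"), c_d = rep(1.3, 3), alpha = 10,
    alpha_c = 0.001, alpha_g = 0, sigma_r2 = 0.1,
    approximation = "particle_filter"),
  shj_subtype_size = list(
    components = .all3, c_d = c(0.7, 2.3, 2.3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  shj_subtype_shape = list(
    components = .all3, c_d = c(2.3, 0.7, 2.3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  dimensional_development = list(
    components = c("nw", "wn"), c_d = rep(2.3, 2), alpha = 1,
    alpha_c = 0.001, alpha_g = 0, sigma_r2 = 100, approximation = "exact"),
  shj_development_adults = list(
    components = .all3, c_d = rep(1.5, 3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  shj_development_children = list(
    components = .singly3, c_d = rep(1.5, 3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  garner_trained_integral = list(
    components = "www", c_d = rep(0.3, 3), alpha = 10, alpha_c = 0.001,
    alpha_g = 0, sigma_r2 = 0.1, approximation = "particle_filter"),
  garner_trained_separable = list(
    components = c("nww", "wwn"), c_d = rep(0.3, 3), alpha = 10,
    alpha_c = 0.001, alpha_g = 0, sigma_r2 = 0.1,
    approximation = "particle_filter"),
  untrained_gibbs = list(
    components = NULL, c_d = NULL, alpha = 10, alpha_c = 0.001, alpha_g = 1,
    v_t = 30, sigma_r2 = 1, approximation = "gibbs")
)

#' Look up (or list) named simulation regimes
#'
#' Each regime bundles the dispersion parameters, the component set and its
#' per-dimension scales, the cluster-mean prior variance, and the inference
#' engine used for one of the simulated experiments.
#'
#' @param name Regime name; call [list_regimes()] for the vocabulary.
#' @param narrow_sd Optional developmental override of the narrow standard
#'   deviation (see [developmental_variant()]).
#' @return An object of class `simulation_regime`: list with `name`,
#'   `components` (a [component_set()] or `NULL` for untrained regimes),
#'   `crp` ([crp_params()]), `sigma_r2`, `v_t`, and `approximation`.
#' @export
regime <- function(name, narrow_sd = NULL) {
  if (!name %in% names(.regime_table))
    stop("unknown regime '", name, "'; known regimes: ",
         paste(names(.regime_table), collapse = ", "))
  r <- .regime_table[[name]]
  comp <- NULL
  if (!is.null(r$components)) {
    comp <- component_set(r$components, r$c_d)
    if (!is.null(narrow_sd)) comp <- developmental_variant(comp, narrow_sd)
  }
  structure(list(
    name = name,
    components = comp,
    crp = crp_params(r$alpha, r$alpha_c, r$alpha_g),
    sigma_r2 = r$sigma_r2,
    v_t = if (is.null(r$v_t)) NA_real_ else r$v_t,
    approximation = r$approximation
  ), class = "simulation_regime")
}

#' @rdname regime
#' @export
list_regimes <- function() {
  out <- data.frame(
    name = names(.regime_table),
    alpha = vapply(.regime_table, `[[`, numeric(1), "alpha"),
    alpha_c = vapply(.regime_table, `[[`, numeric(1), "alpha_c"),
    alpha_g = vapply(.regime_table, `[[`, numeric(1), "alpha_g"),
    sigma_r2 = vapply(.regime_table, `[[`, numeric(1), "sigma_r2"),
    approximation = vapply(.regime_table, `[[`, character(1),
                           "approximation"),
    components = vapply(.regime_table, function(r)
      if (is.null(r$components)) "(learned)" else
        paste(r$components, collapse = ","), character(1)),
    row.names = NULL
  )
  out
}
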