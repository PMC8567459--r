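# JSON round-tripping for fixed-component hierarchy states.

#' Serialize a hierarchy state to JSON
#'
#' Matrices are written as nested arrays in row-major order; the component
#' set is stored by name pattern, scales, and ratios so it can be rebuilt
#' exactly.
#'
#' @param state A `hier_state` with a fixed [component_set()].
#' @return A JSON string.
#' @export
hier_state_to_json <- function(state) {
  state_check(state)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON serialization")
  comp <- state$components
  payload <- list(
    X = apply(unname(state$X), 1L, as.numeric, simplify = FALSE),
    label = state$label, context = state$context, z = state$z,
    cl_component = state$cl_component, cl_label = state$cl_label,
    cl_context = state$cl_context, label_set = state$label_set,
    components = list(names = comp$names, c_d = comp$c_d,
                      narrow_single = comp$narrow_single,
                      narrow_double = comp$narrow_double),
    hyper = list(alpha = state$hyper$crp$alpha,
                 alpha_c = if (is.infinite(state$hyper$crp$alpha_c)) "Inf"
                           else state$hyper$crp$alpha_c,
                 alpha_g = state$hyper$crp$alpha_g,
                 sigma_r2 = state$hyper$sigma_r2,
                 omega = state$hyper$omega, v_t = state$hyper$v_t,
                 dim = state$hyper$dim))
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
}

#' Rebuild a hierarchy state from its JSON form
#'
#' @param json A string produced by [hier_state_to_json()].
#' @return A `hier_state`.
#' @export
hier_state_from_json <- function(json) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON serialization")
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  h <- p$hyper
  alpha_c <- if (is.character(h$alpha_c)) Inf else h$alpha_c
  hyper <- fr_hyper(crp_params(h$alpha, alpha_c, h$alpha_g),
                    sigma_r2 = h$sigma_r2, omega = h$omega, v_t = h$v_t,
                    dim = as.integer(h$dim))
  comps <- component_set(p$components$names, p$components$c_d,
                         narrow_single = p$components$narrow_single,
                         narrow_double = p$components$narrow_double)
  st <- hier_state(hyper, comps, label_set = as.character(p$label_set))
  if (length(p$z) > 0) {
    xm <- if (is.matrix(p$X)) p$X else
      matrix(unlist(p$X), ncol = hyper$dim, byrow = TRUE)
    st$X <- unname(as.matrix(xm))
  }
  st$label <- as.character(p$label)
  st$context <- as.character(p$context)
  st$z <- as.integer(p$z)
  st$cl_component <- as.integer(p$cl_component)
  st$cl_label <- as.character(p$cl_label)
  st$cl_context <- as.character(p$cl_context)
  state_check(st)
  st
}
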