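#' Parameter set: rate constants plus non-zero initial conditions
#'
#' Holds one vector of strictly positive rate constants (named by the
#' network's rate-constant ids) together with the non-zero initial
#' conditions it carries (named by species id) and a free-text label such
#' as a clone name. Both blocks are treated as unknown model parameters
#' during ensemble estimation; positivity is preserved by the log-space
#' proposals.
#'
#' @param k named numeric vector of rate constants, all `> 0`. Units follow
#'   reaction order: zero-order `A.U. s^-1`, first-order `s^-1`,
#'   second-order `A.U.^-1 s^-1`.
#' @param x0 named numeric vector of non-zero initial conditions (A.U.),
#'   all `> 0`; may be empty, in which case the network's species table
#'   supplies every initial value.
#' @param label free text, e.g. a clone id.
#' @return an object of class `kin_params`.
#' @export
kin_params <- function(k, x0 = numeric(), label = "base") {
  k <- unlist(k)
  x0 <- unlist(x0)
  if (is.null(names(k)) || any(!nzchar(names(k)))) abort("rate constants must be named")
  if (any(!is.finite(k)) || any(k <= 0)) abort("rate constants must be finite and > 0")
  if (length(x0)) {
    if (is.null(names(x0)) || any(!nzchar(names(x0)))) abort("initial conditions must be named")
    if (any(!is.finite(x0)) || any(x0 <= 0)) {
      abort("non-zero initial conditions must be finite and > 0")
    }
  }
  structure(list(k = k, x0 = x0, label = label), class = "kin_params")
}

#' @export
print.kin_params <- function(x, ...) {
  cat("<kin_params> label=", x$label, ": ", length(x$k), " rate constants, ",
      length(x$x0), " non-zero initial conditions\n", sep = "")
  invisible(x)
}

as_kin_params <- function(params, net = NULL) {
  if (inherits(params, "kin_params")) return(params)
  if (is.numeric(params)) return(kin_params(params))
  abort("cannot interpret `params`; give a kin_params object or named vector")
}

# rate-constant vector aligned to the network's reaction order
params_k <- function(params, net) {
  params <- as_kin_params(params)
  ids <- net$reactions$rate_constant
  missing <- setdiff(ids, names(params$k))
  if (length(missing)) {
    abort(paste0("parameter set is missing rate constants: ", paste(missing, collapse = ", ")))
  }
  setNames(as.numeric(params$k[ids]), ids)
}

#' Full initial state of a network under a parameter set
#'
#' Species-table initial values overridden by the parameter set's non-zero
#' initial conditions.
#'
#' @param net a [kin_network()].
#' @param params a [kin_params()].
#' @return named state vector in network species order.
#' @export
initial_state <- function(net, params) {
  params <- as_kin_params(params)
  x0 <- setNames(net$species$initial_value, net$species$id)
  if (length(params$x0)) {
    unknown <- setdiff(names(params$x0), names(x0))
    if (length(unknown)) {
      abort(paste0("initial conditions for unknown species: ", paste(unknown, collapse = ", ")))
    }
    x0[names(params$x0)] <- params$x0
  }
  x0
}

# ---- flat parameter vector used by the Metropolis chain -------------------

IC_PREFIX <- "ic_"

as_theta <- function(params) {
  params <- as_kin_params(params)
  ics <- params$x0
  if (length(ics)) names(ics) <- paste0(IC_PREFIX, names(ics))
  c(params$k, ics)
}

theta_to_params <- function(theta, template) {
  is_ic <- startsWith(names(theta), IC_PREFIX)
  x0 <- theta[is_ic]
  names(x0) <- sub(paste0("^", IC_PREFIX), "", names(x0))
  kin_params(theta[!is_ic], x0 = x0, label = template$label)
}

#' Read / write a parameter set as two-column text
#'
#' Format: `parameter_id<TAB>value`, one per line, `#` comments allowed.
#' Initial-condition entries carry the `ic_` prefix on the species id.
#'
#' @param path file path.
#' @param label label for the returned set.
#' @return `read_params()` returns a [kin_params()]; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path, label = "base") {
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  ids <- vapply(parts, `[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(vals)) abort(paste0(path, ": non-numeric parameter value"))
  theta <- setNames(vals, ids)
  theta_to_params(theta, list(label = label))
}

#' @rdname read_params
#' @param params a [kin_params()].
#' @export
write_params <- function(params, path) {
  theta <- as_theta(as_kin_params(params))
  writeLines(sprintf("%s\t%.17g", names(theta), theta), path)
  invisible(path)
}
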