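HOUR <- 3600  # protocol times are hours; rate constants are per second

#' Simulation protocol: timed events plus an output grid
#'
#' @param events `NULL` or a data frame with columns `time_hr`, `kind`
#'   (`set_species`, `add_species`, `scale_parameter`,
#'   `scale_initial_condition`), `target` (species or rate-constant id) and
#'   `value` (amount in A.U. or a non-negative factor). Events are applied
#'   by stopping and restarting the integrator at the event time.
#' @param t_end_hr end of the simulation, hours.
#' @param output_times_hr output grid in hours; defaults to 201 uniform
#'   points on `[0, t_end_hr]`.
#' @return an object of class `kin_protocol`.
#' @export
kin_protocol <- function(events = NULL, t_end_hr, output_times_hr = NULL) {
  if (is.null(events)) {
    events <- tibble::tibble(time_hr = numeric(), kind = character(),
                             target = character(), value = numeric())
  }
  events <- tibble::as_tibble(events)
  kinds <- c("set_species", "add_species", "scale_parameter", "scale_initial_condition")
  bad <- setdiff(events$kind, kinds)
  if (length(bad)) abort(paste0("unknown event kind: ", paste(bad, collapse = ", ")))
  if (nrow(events) && any(events$time_hr < 0)) abort("event times must be >= 0")
  if (nrow(events) && t_end_hr < max(events$time_hr)) {
    abort("t_end_hr must be >= the latest event time")
  }
  events <- events[order(events$time_hr), , drop = FALSE]
  if (is.null(output_times_hr)) output_times_hr <- seq(0, t_end_hr, length.out = 201L)
  structure(list(events = events, t_end_hr = t_end_hr,
                 output_times_hr = sort(unique(output_times_hr))),
            class = "kin_protocol")
}

apply_event <- function(state, k, ev) {
  if (ev$kind %in% c("set_species", "add_species", "scale_initial_condition")) {
    if (!ev$target %in% names(state)) abort(paste0("event targets unknown species ", ev$target))
    state[ev$target] <- switch(ev$kind,
      set_species = ev$value,
      add_species = state[ev$target] + ev$value,
      scale_initial_condition = state[ev$target] * ev$value)
  } else {
    if (!ev$target %in% names(k)) abort(paste0("event targets unknown parameter ", ev$target))
    k[ev$target] <- k[ev$target] * ev$value
  }
  list(state = state, k = k)
}

make_derivs <- function(net, tabs) {
  S <- tabs$S
  function(t, y, k) {
    y <- pmax(y, 0)  # integrator round-off can step slightly below zero
    list(drop(S %*% (k * rate_monomials(tabs, y))))
  }
}

make_jac <- function(net, tabs) {
  S <- tabs$S
  function(t, y, k) {
    y <- pmax(y, 0)
    S %*% (rate_monomial_grad(tabs, y) * k)
  }
}

ode_segment <- function(y, times_s, k, derivs, jac, rtol, atol) {
  out <- deSolve::lsoda(y = y, times = times_s, func = derivs, parms = k,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    abort(paste0("integrator failure at t = ", max(out[, 1]) / HOUR, " h"))
  }
  out
}

#' Integrate the network ODEs under a protocol
#'
#' Stiff integration (LSODA) with the analytic Jacobian supplied. Events are
#' applied by stopping the integrator at the event time, transforming the
#' state or parameters, and restarting; rows at an event time report the
#' pre-event state.
#'
#' @param net a [kin_network()].
#' @param params a [kin_params()] (or named rate-constant vector).
#' @param protocol a [kin_protocol()].
#' @param x0 optional named initial state (A.U.); defaults to the network's
#'   initial values overridden by `params$x0`.
#' @param rtol,atol relative / absolute integration tolerances.
#' @return a `kin_trajectory`: tibble with `time_hr` plus one column per
#'   species; the post-event final state is in `attr(, "final_state")`.
#' @export
integrate_network <- function(net, params, protocol, x0 = NULL,
                              rtol = 1e-6, atol = 1e-9) {
  tabs <- net_tables(net)
  params <- as_kin_params(params)
  k <- params_k(params, net)
  if (is.null(x0)) x0 <- perturbed_x0(net, params)
  x0 <- order_state(x0, net)
  if (any(x0 < -1e-8)) abort("x0 must be >= 0")
  x0 <- pmax(x0, 0)

  derivs <- make_derivs(net, tabs)
  jac <- make_jac(net, tabs)
  t_end <- protocol$t_end_hr * HOUR
  grid <- protocol$output_times_hr * HOUR
  ev <- protocol$events
  # events at t = 0 fold into the initial state / parameters
  ev0 <- ev[ev$time_hr == 0, , drop = FALSE]
  for (e in seq_len(nrow(ev0))) {
    upd <- apply_event(x0, k, ev0[e, ])
    x0 <- upd$state; k <- upd$k
  }
  ev <- ev[ev$time_hr > 0, , drop = FALSE]
  breaks <- sort(unique(c(0, ev$time_hr * HOUR, t_end)))
  breaks <- breaks[breaks <= t_end]

  state <- x0
  rows <- list()
  for (s in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1L]
    seg_times <- sort(unique(c(t0, grid[grid > t0 & grid <= t1], t1)))
    out <- ode_segment(state, seg_times, k, derivs, jac, rtol, atol)
    keep <- out[, 1] %in% grid
    if (s > 1L) keep[1L] <- FALSE  # segment start repeats the previous end
    if (any(keep)) rows[[length(rows) + 1L]] <- out[keep, , drop = FALSE]
    state <- setNames(out[nrow(out), -1L], net$species$id)
    evs_here <- ev[abs(ev$time_hr * HOUR - t1) < 1e-9 & t1 < t_end + 1e-9, , drop = FALSE]
    if (t1 < t_end || nrow(evs_here)) {
      for (e in seq_len(nrow(evs_here))) {
        upd <- apply_event(state, k, evs_here[e, ])
        state <- upd$state; k <- upd$k
      }
    }
  }
  m <- do.call(rbind, rows)
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  traj <- tibble::as_tibble(as.data.frame(m))
  names(traj) <- c("time_hr", net$species$id)
  traj$time_hr <- traj$time_hr / HOUR
  attr(traj, "final_state") <- state
  class(traj) <- c("kin_trajectory", class(traj))
  traj
}

#' Windowed approximate steady state
#'
#' Repeatedly integrates windows of `window_hr` simulated hours until the
#' Euclidean norm of the full state change over one window drops below
#' `tol`, i.e. `||x(t + T) - x(t)||_2 < tol`, and returns the first
#' qualifying `x(t + T)`.
#'
#' @inheritParams integrate_network
#' @param window_hr window length `T` in hours (default 10).
#' @param tol norm tolerance (default 0.01).
#' @param max_windows give up (with an error) after this many windows.
#' @return list with `state` (named vector), `elapsed_hr`, `windows`,
#'   `norm` (the final window norm) and `converged = TRUE`.
#' @export
find_steady_state <- function(net, params, x0 = NULL, window_hr = 10, tol = 0.01,
                              max_windows = 200, rtol = 1e-6, atol = 1e-9) {
  tabs <- net_tables(net)
  params <- as_kin_params(params)
  k <- params_k(params, net)
  if (is.null(x0)) x0 <- perturbed_x0(net, params)
  x0 <- pmax(order_state(x0, net), 0)
  derivs <- make_derivs(net, tabs)
  jac <- make_jac(net, tabs)
  state <- x0
  for (w in seq_len(max_windows)) {
    out <- ode_segment(state, c(0, window_hr * HOUR), k, derivs, jac, rtol, atol)
    new_state <- setNames(out[2L, -1L], net$species$id)
    nrm <- sqrt(sum((new_state - state)^2))
    state <- new_state
    if (nrm < tol) {
      return(list(state = state, elapsed_hr = w * window_hr, windows = w,
                  norm = nrm, converged = TRUE))
    }
  }
  abort(paste0("no steady state after ", max_windows, " windows (last norm = ",
               signif(nrm, 4), ")"))
}

#' Apply a clone variant to a parameter set
#'
#' Clone variants scale expression-rate parameters, e.g. a phosphatase
#' expression rate reduced to 0.01x of the base clone in the
#' androgen-independent analogue.
#'
#' @param params a [kin_params()].
#' @param clone clone label.
#' @param clones clone table: data frame with columns `clone`, `parameter`,
#'   `factor`. A label absent from the table but equal to `base_clone`
#'   returns the parameters unchanged.
#' @param base_clone label of the unscaled clone.
#' @return a [kin_params()] copy with scaled rate constants and the clone
#'   label attached.
#' @export
apply_clone <- function(params, clone, clones, base_clone = "AD") {
  params <- as_kin_params(params)
  clones <- tibble::as_tibble(clones)
  known <- unique(c(base_clone, clones$clone))
  if (!clone %in% known) {
    abort(paste0("unknown clone '", clone, "'; known: ", paste(known, collapse = ", ")))
  }
  rows <- clones[clones$clone == clone, , drop = FALSE]
  k <- params$k
  for (i in seq_len(nrow(rows))) {
    if (!rows$parameter[i] %in% names(k)) {
      abort(paste0("clone table targets unknown parameter ", rows$parameter[i]))
    }
    k[rows$parameter[i]] <- k[rows$parameter[i]] * rows$factor[i]
  }
  kin_params(k, x0 = params$x0, label = clone)
}

# Reactions whose only net product is `species` (zero-order expression and
# catalytic synthesis such as translation); used so that knock-outs of
# synthesized proteins also silence their expression sources.
expression_sources <- function(net, species) {
  S <- stoichiometric_matrix(net)
  i <- match(species, rownames(S))
  hit <- which(S[i, ] > 0 & colSums(abs(S[-i, , drop = FALSE])) == 0)
  colnames(S)[hit]
}

#' Scale a protein's expression level (knock-in / knock-down / knock-out)
#'
#' Scales the species' initial condition by `factor` and, for synthesized
#' species, every rate constant whose reaction's only net product is that
#' species (zero-order expression and catalytic synthesis). Scaling the
#' initial condition alone would let constitutive expression regenerate the
#' protein, contradicting a knock-out.
#'
#' @param net a [kin_network()].
#' @param params a [kin_params()].
#' @param species species id to perturb.
#' @param factor non-negative scale: 10 knock-in, 0.1 knock-down, 0 knock-out.
#' @return a [kin_params()]; a zero factor removes the species id from the
#'   non-zero initial conditions and is applied through the network initial
#'   value at simulation time.
#' @export
perturb_species <- function(net, params, species, factor) {
  params <- as_kin_params(params)
  if (!species %in% net$species$id) abort(paste0("unknown species ", species))
  if (factor < 0) abort("perturbation factor must be >= 0")
  x0 <- perturbed_x0(net, params)  # compose with earlier perturbations
  x0[species] <- x0[species] * factor
  k <- params$k
  syn <- net$species$synthesized[match(species, net$species$id)]
  if (isTRUE(syn)) {
    src <- expression_sources(net, species)
    if (factor == 0) {
      k[src] <- k[src] * 1e-300  # keep strict positivity; numerically silent
    } else {
      k[src] <- k[src] * factor
    }
  }
  out <- kin_params(k, x0 = x0[x0 > 0], label = params$label)
  attr(out, "zeroed") <- names(x0)[x0 == 0]
  attr(out, "full_x0") <- x0
  out
}

# initial state honouring hard zeros introduced by perturb_species
perturbed_x0 <- function(net, params) {
  full <- attr(params, "full_x0")
  if (!is.null(full)) order_state(full, net) else initial_state(net, params)
}
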