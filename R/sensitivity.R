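# Forward (kinetic) sensitivity analysis.
#
# The first-order sensitivities s_j(t) = dx/dk_j obey the linear matrix ODE
# ds_j/dt = A(t) s_j + b_j(t), with A the state Jacobian and b_j the j-th
# column of the parameter Jacobian, both analytic for mass-action systems.
# States and all requested sensitivity columns are integrated jointly as
# one extended kinetic-sensitivity system.

#' Solve the extended kinetic-sensitivity system
#'
#' Integrates states and sensitivities for every requested rate constant in
#' a single call, starting from `s_j(0) = 0` (rate-constant parameters do
#' not enter the initial condition).
#'
#' @param net a [kin_network()].
#' @param params a [kin_params()].
#' @param x0 named initial state; typically the post-stimulus approximate
#'   steady state.
#' @param t_end_hr end of the sensitivity window, hours.
#' @param parameters rate-constant ids to differentiate against; default all.
#' @param n_out number of uniform output times.
#' @param rtol,atol integration tolerances (tighter than plain simulation;
#'   the finite-difference cross-checks require it).
#' @param method `deSolve` integration method for the extended system.
#' @return an object of class `kin_sensitivity`: `times_hr`, `states`
#'   (n_times x n_species) and `s`, a 3-d array
#'   (n_times x n_species x n_parameters) of `dx_i/dk_j`.
#' @export
solve_sensitivities <- function(net, params, x0, t_end_hr, parameters = NULL,
                                n_out = 101L, rtol = 1e-8, atol = 1e-12,
                                method = "lsoda") {
  tabs <- net_tables(net)
  params <- as_kin_params(params)
  k <- params_k(params, net)
  if (is.null(parameters)) parameters <- names(k)
  pidx <- match(parameters, names(k))
  if (anyNA(pidx)) abort("unknown parameter ids in `parameters`")
  x0 <- order_state(x0, net)
  nsp <- tabs$nsp
  np <- length(pidx)
  S <- tabs$S

  derivs <- function(t, y, kk) {
    x <- pmax(y[seq_len(nsp)], 0)
    Sm <- matrix(y[-seq_len(nsp)], nsp, np)
    pr <- rate_monomials(tabs, x)
    G <- rate_monomial_grad(tabs, x)
    A <- S %*% (G * kk)
    B <- sweep(S, 2, pr, `*`)[, pidx, drop = FALSE]
    dx <- drop(S %*% (kk * pr))
    dS <- A %*% Sm + B
    list(c(dx, as.vector(dS)))
  }
  times <- seq(0, t_end_hr * HOUR, length.out = n_out)
  y0 <- c(x0, rep(0, nsp * np))
  out <- deSolve::ode(y = y0, times = times, func = derivs, parms = k,
                      method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    abort(paste0("sensitivity integration failed (parameters ",
                 paste(parameters, collapse = ","), ")"))
  }
  states <- out[, 1 + seq_len(nsp), drop = FALSE]
  colnames(states) <- net$species$id
  s <- array(out[, -(seq_len(nsp + 1L)), drop = FALSE],
             dim = c(nrow(out), nsp, np),
             dimnames = list(NULL, net$species$id, parameters))
  structure(list(times_hr = times / HOUR, states = states, s = s,
                 parameters = parameters, k = k[pidx]),
            class = "kin_sensitivity")
}

#' @export
print.kin_sensitivity <- function(x, ...) {
  d <- dim(x$s)
  cat("<kin_sensitivity> ", d[1], " times x ", d[2], " species x ", d[3],
      " parameters\n", sep = "")
  invisible(x)
}

#' Overall State Sensitivity Coefficients
#'
#' Aggregates time-resolved sensitivities into one scalar per parameter:
#' `OSSC_j = sqrt( (1 / (N_T N_x)) * sum_t sum_i shat_ij(t)^2 )` with the
#' log-scaled sensitivities `shat_ij = (k_j / max(x_i, eps)) * s_ij`.
#' `eps = eps_frac * max(x)` guards division by near-zero states. A
#' parameter with no influence on any state has OSSC 0.
#'
#' @param sens a [solve_sensitivities()] result.
#' @param eps_frac fraction of the maximum state value used as the
#'   near-zero guard.
#' @return tibble with columns `parameter`, `ossc`.
#' @export
ossc <- function(sens, eps_frac = 1e-6) {
  stopifnot(inherits(sens, "kin_sensitivity"))
  eps <- eps_frac * max(sens$states)
  if (eps == 0) eps <- eps_frac
  xs <- pmax(sens$states, eps)            # n_t x n_sp
  vals <- vapply(seq_along(sens$parameters), function(j) {
    shat <- sens$k[j] * sens$s[, , j] / xs
    sqrt(mean(shat^2))
  }, numeric(1))
  tibble::tibble(parameter = sens$parameters, ossc = vals)
}

#' OSSC ranking under the stimulus protocol
#'
#' Runs the full protocol: find the clone's approximate steady state, add
#' the hormone stimulus, solve the kinetic-sensitivity system over a short
#' window (100 s by default, 101 uniform points), aggregate to OSSC and
#' rank. Larger OSSC means larger rank number (rank `P` = most fragile);
#' ties break deterministically by parameter order.
#'
#' @param net a [kin_network()].
#' @param params a [kin_params()].
#' @param clone clone label.
#' @param clones clone table (see [apply_clone()]).
#' @param stimulus list with `species` and `amount` (A.U.) added at the
#'   window start.
#' @param window_s sensitivity window, seconds.
#' @param parameters rate-constant ids; default all.
#' @param n_out time points in the OSSC sum.
#' @param ss_control settings for [find_steady_state()].
#' @return an object of class `kin_ossc`: tibble with `parameter`, `ossc`,
#'   `rank` and a `clone` attribute.
#' @export
ossc_protocol <- function(net, params, clone, clones,
                          stimulus = list(species = "H", amount = 10),
                          window_s = 100, parameters = NULL, n_out = 101L,
                          ss_control = list()) {
  ss_control <- utils::modifyList(list(window_hr = 10, tol = 0.01, max_windows = 200),
                                  ss_control)
  p <- apply_clone(as_kin_params(params), clone, clones)
  ss <- find_steady_state(net, p, window_hr = ss_control$window_hr,
                          tol = ss_control$tol, max_windows = ss_control$max_windows)
  x0 <- ss$state
  x0[stimulus$species] <- x0[stimulus$species] + stimulus$amount
  sens <- solve_sensitivities(net, p, x0, t_end_hr = window_s / HOUR,
                              parameters = parameters, n_out = n_out)
  res <- ossc(sens)
  res$rank <- rank_ossc(res$ossc)
  attr(res, "clone") <- clone
  class(res) <- c("kin_ossc", class(res))
  res
}

# ascending rank, largest OSSC gets rank P, ties broken by parameter index
rank_ossc <- function(values) {
  as.integer(rank(values, ties.method = "first"))
}

#' Rank shifts between two clones over the ensemble
#'
#' For every parameter, a Welch (unequal-variance, two-sided) t-test on its
#' OSSC ranks across ensemble members in clone B versus clone A. A shift is
#' flagged `large` when its absolute mean exceeds one standard deviation of
#' all mean shifts, and `significant` at the 95% confidence level.
#'
#' @param rankings tibble with columns `member`, `clone`, `parameter`,
#'   `rank` (e.g. rows of [ossc_protocol()] results over members).
#' @param clone_a,clone_b clone labels; shifts are `mean(B) - mean(A)`
#'   (positive = more fragile in B).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` by default (no correction applied, a
#'   config switch enables e.g. `"BH"`).
#' @param conf confidence level for significance flags.
#' @return tibble with `parameter`, `mean_shift`, `t`, `p`, `significant`,
#'   `large`.
#' @export
rank_shift_test <- function(rankings, clone_a, clone_b, p_adjust = "none",
                            conf = 0.95) {
  rankings <- tibble::as_tibble(rankings)
  n_members <- length(unique(rankings$member))
  if (n_members < 3L) abort("rank shift test needs at least 3 ensemble members")
  a <- rankings[rankings$clone == clone_a, ]
  b <- rankings[rankings$clone == clone_b, ]
  pars <- unique(rankings$parameter)
  rows <- lapply(pars, function(p) {
    ra <- a$rank[a$parameter == p]
    rb <- b$rank[b$parameter == p]
    shift <- mean(rb) - mean(ra)
    if (stats::sd(ra) == 0 && stats::sd(rb) == 0) {
      tt <- list(statistic = c(t = if (shift == 0) 0 else Inf * sign(shift)),
                 p.value = if (shift == 0) 1 else 0)
    } else {
      tt <- stats::t.test(rb, ra, var.equal = FALSE)
    }
    tibble::tibble(parameter = p, mean_shift = shift,
                   t = unname(tt$statistic), p = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adj < (1 - conf)
  sd_shift <- stats::sd(out$mean_shift)
  out$large <- if (is.na(sd_shift) || sd_shift == 0) {
    abs(out$mean_shift) > 0
  } else {
    abs(out$mean_shift) > sd_shift
  }
  out
}

#' OSSC rankings for every ensemble member
#'
#' @param net a [kin_network()].
#' @param ensemble a `kin_ensemble`.
#' @param clone clone label.
#' @param clones clone table.
#' @param members member indices to use; default all.
#' @param ... passed to [ossc_protocol()].
#' @return tibble with `member`, `clone`, `parameter`, `ossc`, `rank`.
#' @export
ensemble_rankings <- function(net, ensemble, clone, clones, members = NULL, ...) {
  if (is.null(members)) members <- seq_len(ensemble_size(ensemble))
  dplyr::bind_rows(lapply(members, function(i) {
    r <- ossc_protocol(net, ensemble_member(ensemble, i), clone, clones, ...)
    tibble::tibble(member = i, clone = clone, parameter = r$parameter,
                   ossc = r$ossc, rank = r$rank)
  }))
}
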