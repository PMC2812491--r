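# Synergy between two signaling axes.
#
# The steady states of four systems -- wild type, each single knock-out and
# the double knock-out (the control) -- are compared through the
# interaction contrast
#   alpha_j = (D_AB - D_A - D_B) / q_wt,
# where D_A = q(A present, B absent) - q(control), analogously D_B, and
# D_AB = q(wild type) - q(control). alpha > 0 marks super-additive
# (positive) synergy, alpha < 0 sub-additive coupling, alpha = 0 no
# connection between the quantity and the two axes.

axis_steady_quantities <- function(net, params, axis_out, ss_control, rtol, atol) {
  p <- params
  for (sp in axis_out) p <- perturb_species(net, p, sp, 0)
  ss <- find_steady_state(net, p, x0 = perturbed_x0(net, p),
                          window_hr = ss_control$window_hr, tol = ss_control$tol,
                          max_windows = ss_control$max_windows,
                          rtol = rtol, atol = atol)
  state <- pmax(ss$state, 0)  # integrator round-off guard
  flux <- massaction_rates(net, p, state)
  names(flux) <- net$reactions$rate_constant
  list(species = state, flux = flux)
}

synergy_states <- function(net, params, axis_a, axis_b, clone, clones,
                           ss_control, rtol, atol) {
  p <- apply_clone(as_kin_params(params), clone, clones)
  list(
    wt = axis_steady_quantities(net, p, character(), ss_control, rtol, atol),
    a_only = axis_steady_quantities(net, p, axis_b, ss_control, rtol, atol),
    b_only = axis_steady_quantities(net, p, axis_a, ss_control, rtol, atol),
    control = axis_steady_quantities(net, p, c(axis_a, axis_b), ss_control, rtol, atol))
}

alpha_from_states <- function(states, type, id) {
  pick <- function(s) s[[type]][[id]]
  q_wt <- pick(states$wt)
  if (q_wt == 0) return(NA_real_)
  d_a <- pick(states$a_only) - pick(states$control)
  d_b <- pick(states$b_only) - pick(states$control)
  d_ab <- q_wt - pick(states$control)
  (d_ab - d_a - d_b) / q_wt
}

#' Synergy coefficient of one quantity with respect to two axes
#'
#' Knock-out of an axis zeroes the axis species' total protein (initial
#' condition plus any expression source, as in [perturb_species()]). All
#' four systems are run to their own approximate steady state without
#' hormone stimulation.
#'
#' @param net a [kin_network()].
#' @param params a [kin_params()].
#' @param axis_a,axis_b species ids of the two axes (e.g. the MAPK terminal
#'   kinase and Akt).
#' @param quantity species id (`type = "species"`) or rate-constant id of a
#'   reaction flux (`type = "flux"`).
#' @param type `"species"` or `"flux"`.
#' @param clone clone label; `clones` the clone table.
#' @param ss_control settings for [find_steady_state()].
#' @param rtol,atol integration tolerances.
#' @return scalar `alpha_j`; `NA` when the wild-type steady-state value is
#'   zero.
#' @export
synergy_coefficient <- function(net, params, axis_a, axis_b, quantity,
                                type = c("species", "flux"), clone, clones,
                                ss_control = list(), rtol = 1e-6, atol = 1e-9) {
  type <- match.arg(type)
  ss_control <- utils::modifyList(list(window_hr = 10, tol = 0.01, max_windows = 200),
                                  ss_control)
  states <- synergy_states(net, params, axis_a, axis_b, clone, clones,
                           ss_control, rtol, atol)
  alpha_from_states(states, type, quantity)
}

#' Ensemble-wide synergy screen over all species and fluxes
#'
#' Computes `alpha_j` for every modeled species and reaction flux in every
#' ensemble member (four steady states per member). Classification uses the
#' percentile 95% confidence interval over the ensemble: `positive` when
#' the whole interval lies above 0, `negative` below, otherwise `none`. A
#' degenerate (all-identical) ensemble classifies by sign with tolerance
#' `tol`. The `all_same_sign` column reports whether every member agrees in
#' sign, mirroring the member-by-member inspection used to confirm
#' super-additive marker expression.
#'
#' @inheritParams synergy_coefficient
#' @param ensemble a `kin_ensemble`.
#' @param members member indices; default all.
#' @param conf confidence level of the percentile interval.
#' @param tol sign tolerance for degenerate intervals.
#' @return an object of class `kin_synergy`: tibble with `quantity`,
#'   `type`, `alpha_mean`, `ci_lo`, `ci_hi`, `class`, `all_same_sign`.
#' @export
synergy_screen <- function(net, ensemble, axis_a, axis_b, clone, clones,
                           members = NULL, conf = 0.95, tol = 1e-8,
                           ss_control = list(), rtol = 1e-6, atol = 1e-9) {
  ss_control <- utils::modifyList(list(window_hr = 10, tol = 0.01, max_windows = 200),
                                  ss_control)
  if (is.null(members)) members <- seq_len(ensemble_size(ensemble))
  quantities <- tibble::tibble(
    quantity = c(net$species$id, net$reactions$rate_constant),
    type = rep(c("species", "flux"), c(nrow(net$species), nrow(net$reactions))))
  per_member <- lapply(members, function(i) {
    st <- synergy_states(net, ensemble_member(ensemble, i), axis_a, axis_b,
                         clone, clones, ss_control, rtol, atol)
    alpha <- vapply(seq_len(nrow(quantities)), function(r)
      alpha_from_states(st, quantities$type[r], quantities$quantity[r]),
      numeric(1))
    dplyr::mutate(quantities, member = i, alpha = alpha)
  })
  all <- dplyr::bind_rows(per_member)
  lo_q <- (1 - conf) / 2
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$quantity, .data$type),
    alpha_mean = mean(.data$alpha),
    ci_lo = stats::quantile(.data$alpha, lo_q, na.rm = TRUE, names = FALSE),
    ci_hi = stats::quantile(.data$alpha, 1 - lo_q, na.rm = TRUE, names = FALSE),
    all_same_sign = all(sign(.data$alpha) == sign(.data$alpha[1])),
    .groups = "drop")
  degenerate <- (out$ci_hi - out$ci_lo) <= tol
  out$class <- dplyr::case_when(
    degenerate & out$alpha_mean > tol ~ "positive",
    degenerate & out$alpha_mean < -tol ~ "negative",
    degenerate ~ "none",
    out$ci_lo > 0 ~ "positive",
    out$ci_hi < 0 ~ "negative",
    TRUE ~ "none")
  attr(out, "per_member") <- all
  attr(out, "axes") <- c(axis_a, axis_b)
  class(out) <- c("kin_synergy", class(out))
  out
}
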