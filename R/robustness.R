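# Knock-in / knock-down / knock-out robustness coefficients.
#
# f(i, j) is the ratio of a marker's time-integrated concentration under a
# perturbation to its wild-type integral over the same window: f > 1 means
# the perturbation increases the output, f < 1 decreases it, f = 1 no
# influence.

logspaced_grid <- function(t_end_hr, n) {
  c(0, 10^seq(log10(t_end_hr) - 4, log10(t_end_hr), length.out = n - 1L))
}

trapz_integral <- function(t, y) {
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

marker_integral <- function(net, params, marker, stimulus_time_hr, t_end_hr,
                            stimulus, grid, ss_control, rtol, atol) {
  ss <- find_steady_state(net, params, x0 = perturbed_x0(net, params),
                          window_hr = ss_control$window_hr, tol = ss_control$tol,
                          max_windows = ss_control$max_windows,
                          rtol = rtol, atol = atol)
  ev <- tibble::tibble(time_hr = stimulus_time_hr, kind = "add_species",
                       target = stimulus$species, value = stimulus$amount)
  proto <- kin_protocol(ev, t_end_hr = t_end_hr, output_times_hr = grid)
  traj <- integrate_network(net, params, proto, x0 = ss$state, rtol = rtol, atol = atol)
  list(integral = trapz_integral(traj$time_hr, traj[[marker]]), trajectory = traj)
}

#' Robustness coefficient of a marker under one perturbation
#'
#' Both the perturbed and the wild-type system are run from their own
#' approximate steady states; the hormone stimulus is added at 1 h and the
#' marker concentration is integrated (trapezoid rule on a shared grid of
#' 500 log-spaced points) until 72 h after the stimulus.
#'
#' @param net a [kin_network()].
#' @param params a [kin_params()].
#' @param marker output species id.
#' @param target perturbed species id.
#' @param factor expression scale: 10 knock-in, 0.1 knock-down, 0 knock-out,
#'   1 null perturbation (returns exactly 1).
#' @param clone clone label; `clones` the clone table.
#' @param stimulus list with `species` and `amount`, added at
#'   `stimulus_time_hr`.
#' @param stimulus_time_hr stimulus time (1 h).
#' @param post_stimulus_hr integration horizon after the stimulus (72 h).
#' @param n_grid output/integration grid size.
#' @param ss_control settings for [find_steady_state()].
#' @param rtol,atol integration tolerances.
#' @return scalar `f >= 0`; `NA` when the wild-type integral is zero.
#' @export
robustness_coefficient <- function(net, params, marker, target, factor,
                                   clone, clones,
                                   stimulus = list(species = "H", amount = 10),
                                   stimulus_time_hr = 1, post_stimulus_hr = 72,
                                   n_grid = 500L, ss_control = list(),
                                   rtol = 1e-6, atol = 1e-9) {
  ss_control <- utils::modifyList(list(window_hr = 10, tol = 0.01, max_windows = 200),
                                  ss_control)
  if (!marker %in% net$species$id) abort(paste0("unknown marker ", marker))
  p <- apply_clone(as_kin_params(params), clone, clones)
  t_end <- stimulus_time_hr + post_stimulus_hr
  grid <- logspaced_grid(t_end, n_grid)
  wt <- marker_integral(net, p, marker, stimulus_time_hr, t_end, stimulus,
                        grid, ss_control, rtol, atol)
  if (factor == 1) return(1)
  pp <- perturb_species(net, p, target, factor)
  pert <- marker_integral(net, pp, marker, stimulus_time_hr, t_end, stimulus,
                          grid, ss_control, rtol, atol)
  if (wt$integral == 0) return(NA_real_)
  pert$integral / wt$integral
}

#' Robustness panel over markers, targets and the ensemble
#'
#' Grid of robustness coefficients for every marker x target x factor cell,
#' averaged over ensemble members (mean and sd reported). Wild-type runs
#' are shared across cells within a member.
#'
#' @inheritParams robustness_coefficient
#' @param ensemble a `kin_ensemble`.
#' @param markers output species ids.
#' @param targets perturbed species ids.
#' @param factors perturbation factors (default knock-in 10, knock-down
#'   0.1, knock-out 0).
#' @param members member indices to use; default all.
#' @return an object of class `kin_robustness`: tibble with `marker`,
#'   `target`, `factor`, `f_mean`, `f_sd`, `n_members`.
#' @export
robustness_panel <- function(net, ensemble, markers, targets,
                             factors = c(10, 0.1, 0), clone, clones,
                             members = NULL,
                             stimulus = list(species = "H", amount = 10),
                             stimulus_time_hr = 1, post_stimulus_hr = 72,
                             n_grid = 500L, ss_control = list(),
                             rtol = 1e-6, atol = 1e-9) {
  ss_control <- utils::modifyList(list(window_hr = 10, tol = 0.01, max_windows = 200),
                                  ss_control)
  if (is.null(members)) members <- seq_len(ensemble_size(ensemble))
  t_end <- stimulus_time_hr + post_stimulus_hr
  grid <- logspaced_grid(t_end, n_grid)
  per_member <- lapply(members, function(i) {
    p <- apply_clone(ensemble_member(ensemble, i), clone, clones)
    wt <- lapply(markers, function(m)
      marker_integral(net, p, m, stimulus_time_hr, t_end, stimulus, grid,
                      ss_control, rtol, atol)$integral)
    names(wt) <- markers
    cells <- tidyr::expand_grid(target = targets, factor = factors)
    rows <- lapply(seq_len(nrow(cells)), function(r) {
      pp <- perturb_species(net, p, cells$target[r], cells$factor[r])
      ss <- find_steady_state(net, pp, x0 = perturbed_x0(net, pp),
                              window_hr = ss_control$window_hr, tol = ss_control$tol,
                              max_windows = ss_control$max_windows,
                              rtol = rtol, atol = atol)
      ev <- tibble::tibble(time_hr = stimulus_time_hr, kind = "add_species",
                           target = stimulus$species, value = stimulus$amount)
      proto <- kin_protocol(ev, t_end_hr = t_end, output_times_hr = grid)
      traj <- integrate_network(net, pp, proto, x0 = ss$state, rtol = rtol, atol = atol)
      f <- vapply(markers, function(m) {
        wti <- wt[[m]]
        if (wti == 0) return(NA_real_)
        trapz_integral(traj$time_hr, traj[[m]]) / wti
      }, numeric(1))
      tibble::tibble(member = i, marker = markers, target = cells$target[r],
                     factor = cells$factor[r], f = f)
    })
    dplyr::bind_rows(rows)
  })
  all <- dplyr::bind_rows(per_member)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$marker, .data$target, .data$factor),
    f_mean = mean(.data$f), f_sd = stats::sd(.data$f),
    n_members = dplyr::n(), .groups = "drop")
  attr(out, "per_member") <- all
  attr(out, "clone") <- clone
  class(out) <- c("kin_robustness", class(out))
  out
}
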