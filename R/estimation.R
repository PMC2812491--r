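# Ensemble parameter estimation against arbitrary-unit training data.
#
# Immunoblot-style observations are accurate only up to a multiplicative
# constant, so each (dataset, species) series gets a least-squares scale
# factor beta before residuals are formed. The normalized mean squared
# error E drives a Metropolis random walk in log-parameter space; accepted
# states are decorrelated by autocorrelation thinning into the ensemble.

#' Training set: observations plus per-dataset simulation recipes
#'
#' @param observations tibble with columns `dataset_id`, `species_id`,
#'   `condition`, `value` (A.U.) and `std` (> 0). `condition` is
#'   `"<arm>@<time_hr>"` for a time point after the arm's steady state, or
#'   `"<arm>@ss"` for the arm's steady-state value itself.
#' @param datasets named list (by `dataset_id`); each element is a list with
#'   `clone` (label) and `arms`, itself a named list of arms, each a list
#'   with optional `events` (event data frame as in [kin_protocol()]),
#'   `k_scale` and `ic_scale` (named factors applied to rate constants /
#'   initial conditions before the arm's own steady state is found).
#' @param clones clone table for [apply_clone()].
#' @return an object of class `kin_training`.
#' @export
kin_training <- function(observations, datasets, clones) {
  observations <- tibble::as_tibble(observations)
  stopifnot(all(c("dataset_id", "species_id", "condition", "value", "std") %in%
                  names(observations)))
  if (any(observations$std <= 0)) abort("observation std must be > 0")
  missing <- setdiff(unique(observations$dataset_id), names(datasets))
  if (length(missing)) {
    abort(paste0("datasets without a simulation recipe: ", paste(missing, collapse = ", ")))
  }
  empty <- setdiff(names(datasets), unique(observations$dataset_id))
  if (length(empty)) {
    abort(paste0("datasets without observations: ", paste(empty, collapse = ", ")))
  }
  structure(list(observations = observations, datasets = datasets,
                 clones = tibble::as_tibble(clones)),
            class = "kin_training")
}

#' @export
print.kin_training <- function(x, ...) {
  cat("<kin_training> ", nrow(x$observations), " observations in ",
      length(x$datasets), " datasets\n", sep = "")
  invisible(x)
}

#' Default measurement standard deviations
#'
#' Observations without a reported error get a standard deviation of 10% of
#' the reported value; observations flagged as unclearly quantified get an
#' augmented fraction in `[0.20, 1.00]` instead. A positive floor guards
#' zero-valued observations.
#'
#' @param value numeric vector of observed values.
#' @param flagged logical vector: unclear quantification.
#' @param augment augmented fraction for flagged observations.
#' @param floor minimum returned std.
#' @return numeric vector of stds, all `> 0`.
#' @export
default_stds <- function(value, flagged = FALSE, augment = 0.5, floor = 1e-3) {
  if (augment < 0.20 || augment > 1.00) abort("augment must lie in [0.20, 1.00]")
  frac <- ifelse(rep_len(flagged, length(value)), augment, 0.10)
  pmax(frac * abs(value), floor)
}

#' Least-squares scale factor for arbitrary-unit data
#'
#' The factor `beta` minimizing `sum_i ((M_i - beta * xhat_i) / sigma_i)^2`
#' in closed form, `beta = sum(M xhat / sigma^2) / sum(xhat^2 / sigma^2)`,
#' clamped to be non-negative (concentrations cannot change sign). If the
#' simulated values are all zero `beta` is undefined and `NA` is returned;
#' the caller scores that series unscaled.
#'
#' @param observed,simulated,stds numeric vectors of equal length; `stds > 0`.
#' @return scalar `beta >= 0`, or `NA_real_`.
#' @export
scale_factor <- function(observed, simulated, stds) {
  stopifnot(length(observed) == length(simulated), length(observed) == length(stds))
  if (any(stds <= 0)) abort("stds must be > 0")
  denom <- sum(simulated^2 / stds^2)
  if (denom == 0) return(NA_real_)
  max(0, sum(observed * simulated / stds^2) / denom)
}

# scale signature -> steady-state cache key
arm_key <- function(clone, arm) {
  paste(clone,
        paste(names(arm$k_scale), unlist(arm$k_scale), collapse = ";"),
        paste(names(arm$ic_scale), unlist(arm$ic_scale), collapse = ";"),
        sep = "|")
}

apply_arm_scales <- function(net, params, arm) {
  k <- params$k
  for (id in names(arm$k_scale)) k[id] <- k[id] * arm$k_scale[[id]]
  x0 <- initial_state(net, params)
  for (id in names(arm$ic_scale)) x0[id] <- x0[id] * arm$ic_scale[[id]]
  list(params = kin_params(k, label = params$label), x0 = x0)
}

# simulate one dataset arm at the needed times; returns named list:
# xhat[["<time or ss>"]] = named state vector
simulate_arm <- function(net, params, arm, times_hr, want_ss, ss_cache, key,
                         ss_control, rtol, atol) {
  if (!is.null(ss_cache[[key]])) {
    ss <- ss_cache[[key]]
  } else {
    prep <- apply_arm_scales(net, params, arm)
    ss <- find_steady_state(net, prep$params, x0 = prep$x0,
                            window_hr = ss_control$window_hr, tol = ss_control$tol,
                            max_windows = ss_control$max_windows,
                            rtol = rtol, atol = atol)
    ss$params <- prep$params
    ss_cache[[key]] <- ss
  }
  out <- list()
  if (want_ss) out[["ss"]] <- ss$state
  if (length(times_hr)) {
    ev_max <- if (is.null(arm$events) || nrow(tibble::as_tibble(arm$events)) == 0) 0 else max(arm$events$time_hr)
    proto <- kin_protocol(arm$events, t_end_hr = max(times_hr, ev_max),
                          output_times_hr = sort(unique(c(0, times_hr))))
    traj <- integrate_network(net, ss$params, proto, x0 = ss$state,
                              rtol = rtol, atol = atol)
    m <- as.matrix(traj[, -1, drop = FALSE])
    for (t in times_hr) {
      i <- which.min(abs(traj$time_hr - t))
      out[[format_time(t)]] <- setNames(m[i, ], colnames(m))
    }
  }
  out
}

format_time <- function(t) format(t, trim = TRUE, scientific = FALSE, digits = 15)

#' Observation condition labels
#'
#' `"<arm>@<time_hr>"` (hours after the arm's steady state) or
#' `"<arm>@ss"` (the steady state itself).
#'
#' @param arm arm name.
#' @param time_hr numeric time in hours, or the string `"ss"`.
#' @return character vector of condition labels.
#' @export
obs_condition <- function(arm, time_hr) {
  at <- vapply(as.list(time_hr), function(t) {
    if (identical(t, "ss")) "ss" else format_time(as.numeric(t))
  }, character(1))
  paste0(arm, "@", at)
}

parse_condition <- function(condition) {
  parts <- strsplit(condition, "@", fixed = TRUE)
  tibble::tibble(arm = vapply(parts, `[`, character(1), 1L),
                 at = vapply(parts, `[`, character(1), 2L))
}

#' Normalized mean squared simulation error
#'
#' `E = (1/N_obs) * sum(((M - beta * xhat) / sigma)^2)` over all
#' observations, with `beta` fitted per (dataset, species) series by
#' [scale_factor()]. Every dataset arm is simulated from its own windowed
#' approximate steady state. A failed simulation returns `Inf`, which the
#' Metropolis rule auto-rejects.
#'
#' @param params a [kin_params()].
#' @param net a [kin_network()].
#' @param training a [kin_training()].
#' @param ss_control list of [find_steady_state()] settings
#'   (`window_hr`, `tol`, `max_windows`).
#' @param details return the per-observation table instead of the scalar.
#' @param rtol,atol integration tolerances.
#' @return scalar `E >= 0` (or a tibble when `details = TRUE`).
#' @export
simulation_error <- function(params, net, training, ss_control = list(),
                             details = FALSE, rtol = 1e-6, atol = 1e-9) {
  ss_control <- utils::modifyList(list(window_hr = 10, tol = 0.01, max_windows = 200),
                                  ss_control)
  params <- as_kin_params(params)
  obs <- training$observations
  res <- tryCatch({
    ss_cache <- new.env(parent = emptyenv())
    per_ds <- lapply(names(training$datasets), function(ds_id) {
      ds <- training$datasets[[ds_id]]
      p_clone <- apply_clone(params, ds$clone, training$clones)
      obs_ds <- obs[obs$dataset_id == ds_id, , drop = FALSE]
      cond <- parse_condition(obs_ds$condition)
      xhat <- numeric(nrow(obs_ds))
      for (arm_name in unique(cond$arm)) {
        arm <- ds$arms[[arm_name]]
        if (is.null(arm)) abort(paste0("dataset ", ds_id, " has no arm '", arm_name, "'"))
        rows <- which(cond$arm == arm_name)
        ats <- cond$at[rows]
        times <- sort(unique(as.numeric(ats[ats != "ss"])))
        sims <- simulate_arm(net, p_clone, arm, times, any(ats == "ss"),
                             ss_cache, paste(ds$clone, arm_key(ds$clone, arm)),
                             ss_control, rtol, atol)
        for (r in rows) {
          state <- sims[[cond$at[r]]]
          xhat[r] <- state[[obs_ds$species_id[r]]]
        }
      }
      dplyr::mutate(obs_ds, xhat = xhat)
    })
    scored <- dplyr::bind_rows(per_ds)
    scored <- dplyr::group_by(scored, .data$dataset_id, .data$species_id)
    scored <- dplyr::mutate(scored,
      beta = {
        b <- scale_factor(.data$value, .data$xhat, .data$std)
        if (is.na(b)) 1 else b
      })
    scored <- dplyr::ungroup(scored)
    scored$residual <- (scored$value - scored$beta * scored$xhat) / scored$std
    scored
  }, error = function(e) NULL)
  if (is.null(res)) {
    if (details) abort("simulation failed; no details available")
    return(Inf)
  }
  if (details) return(res)
  mean(res$residual^2)
}

#' Build an error function for the Metropolis chain
#'
#' @inheritParams simulation_error
#' @return a function mapping a [kin_params()] to its scalar error `E`.
#' @export
make_error_fn <- function(net, training, ss_control = list(), rtol = 1e-6, atol = 1e-9) {
  force(net); force(training); force(ss_control)
  function(params) simulation_error(params, net, training, ss_control = ss_control,
                                    rtol = rtol, atol = atol)
}

# ---- Metropolis random walk ----------------------------------------------

#' Chain configuration
#'
#' @param sigma proposal standard deviation in (natural) log-parameter space.
#' @param E0 acceptance temperature: a worse proposal is accepted with
#'   probability `exp(-(E_new - E_old) / E0)`.
#' @param n_steps number of Monte-Carlo steps.
#' @param seed RNG seed; the chain is bitwise reproducible under it.
#' @param block_size number of parameters perturbed per step; `NULL`
#'   perturbs all of them.
#' @return an object of class `kin_chain_config`.
#' @export
kin_chain_config <- function(sigma = 0.05, E0 = 1, n_steps = 500, seed = 1,
                             block_size = NULL) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (E0 <= 0) abort("E0 must be > 0")
  structure(list(sigma = sigma, E0 = E0, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), block_size = block_size),
            class = "kin_chain_config")
}

#' Log-space random-walk proposal
#'
#' `log k_new = log k + N(0, sigma^2)` elementwise (on a random block of
#' `block_size` parameters when configured), guaranteeing strictly positive
#' proposals. Uses the current RNG stream.
#'
#' @param current a [kin_params()].
#' @param config a [kin_chain_config()].
#' @return a proposed [kin_params()].
#' @export
propose <- function(current, config) {
  theta <- as_theta(as_kin_params(current))
  idx <- seq_along(theta)
  if (!is.null(config$block_size) && config$block_size < length(theta)) {
    idx <- sample(idx, config$block_size)
  }
  theta[idx] <- exp(log(theta[idx]) + stats::rnorm(length(idx), 0, config$sigma))
  theta_to_params(theta, as_kin_params(current))
}

#' Metropolis acceptance rule
#'
#' Accept with probability 1 when the proposal does not increase the error,
#' otherwise with probability `exp(-(E_proposed - E_current) / E0)`
#' (likelihood ratio of the Boltzmann-form likelihood). Uses the current
#' RNG stream.
#'
#' @param E_current,E_proposed scalar errors.
#' @param config a [kin_chain_config()].
#' @return logical.
#' @export
accept_proposal <- function(E_current, E_proposed, config) {
  if (!is.finite(E_proposed)) return(FALSE)
  if (E_proposed <= E_current) return(TRUE)
  stats::runif(1) < exp(-(E_proposed - E_current) / config$E0)
}

#' Run one Metropolis chain
#'
#' @param start a [kin_params()] starting point (the hand-tuned initial
#'   guess in the bundled workflow).
#' @param config a [kin_chain_config()].
#' @param error_fn function mapping a [kin_params()] to a scalar error,
#'   e.g. from [make_error_fn()].
#' @param progress print a line every `progress` steps; 0 is silent.
#' @return an object of class `kin_chain`: the visited states (step 0 is
#'   the start), their errors, and per-step acceptance flags.
#' @export
run_chain <- function(start, config, error_fn, progress = 0) {
  start <- as_kin_params(start)
  set.seed(config$seed)
  theta <- as_theta(start)
  n <- config$n_steps
  states <- matrix(NA_real_, n + 1L, length(theta),
                   dimnames = list(NULL, names(theta)))
  E <- numeric(n + 1L)
  proposed_E <- numeric(n)
  accepted <- logical(n)
  states[1L, ] <- theta
  current <- start
  E[1L] <- error_fn(current)
  for (s in seq_len(n)) {
    cand <- propose(current, config)
    Ec <- error_fn(cand)
    proposed_E[s] <- Ec
    if (accept_proposal(E[s], Ec, config)) {
      current <- cand
      E[s + 1L] <- Ec
      accepted[s] <- TRUE
    } else {
      E[s + 1L] <- E[s]
    }
    states[s + 1L, ] <- as_theta(current)
    if (progress > 0 && s %% progress == 0) {
      message(sprintf("step %d/%d E=%.4g acc=%.2f", s, n, E[s + 1L], mean(accepted[1:s])))
    }
  }
  structure(list(states = states, E = E, proposed_E = proposed_E,
                 accepted = accepted, config = config, template = start),
            class = "kin_chain")
}

#' @export
print.kin_chain <- function(x, ...) {
  cat("<kin_chain> ", length(x$accepted), " steps, acceptance rate ",
      signif(mean(x$accepted), 3), ", final E ", signif(x$E[length(x$E)], 4),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.kin_chain <- function(x, ...) {
  tibble::tibble(step = seq_along(x$E) - 1L, E = x$E,
                 accepted = c(NA, x$accepted))
}

#' Decorrelation interval from the error autocorrelation
#'
#' Fits `C(tau) = exp(-tau / tau_c)` to the positive part of the empirical
#' autocorrelation of a scalar series (least squares on `log C`) and
#' returns the lag at which the fit drops to 5% of its initial value,
#' `ceiling(tau_c * log(20))`. A series whose lag-1 autocorrelation is
#' already at or below 5% gets interval 1.
#'
#' @param e numeric series (chain errors).
#' @param lag_max maximum lag used.
#' @return integer interval `>= 1`.
#' @export
thinning_interval <- function(e, lag_max = min(length(e) - 1L, 500L)) {
  ac <- stats::acf(e, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1L]
  if (!length(ac) || is.na(ac[1L]) || ac[1L] <= 0.05) return(1L)
  below <- which(ac <= 0.05)
  L <- if (length(below)) below[1L] - 1L else length(ac)
  use <- seq_len(L)
  use <- use[ac[use] > 0]
  fit <- stats::lm.fit(x = cbind(use), y = log(ac[use]))
  slope <- fit$coefficients[[1L]]
  if (!is.finite(slope) || slope >= 0) return(1L)
  tau_c <- -1 / slope
  max(1L, as.integer(ceiling(tau_c * log(20))))
}

#' Thin a chain into a decorrelated ensemble
#'
#' Computes the thinning interval from the chain's error series (after
#' discarding `burn` initial steps) with [thinning_interval()] and keeps
#' every interval-th accepted parameter set.
#'
#' @param chain a [run_chain()] result.
#' @param burn number of initial steps discarded before thinning.
#' @param interval override the fitted interval.
#' @return an object of class `kin_ensemble`.
#' @export
thin_by_autocorrelation <- function(chain, burn = 0L, interval = NULL) {
  e <- chain$E[-seq_len(burn + 1L)]  # drop burn-in and the start state
  if (is.null(interval)) interval <- thinning_interval(e)
  acc_steps <- which(chain$accepted)  # 1-based MC steps
  acc_steps <- acc_steps[acc_steps > burn]
  keep <- acc_steps[seq(1L, length(acc_steps), by = interval)]
  if (!length(keep)) abort("no accepted steps survive burn-in; nothing to thin")
  members <- chain$states[keep + 1L, , drop = FALSE]
  structure(list(members = members, errors = chain$E[keep + 1L],
                 interval = as.integer(interval),
                 provenance = tibble::tibble(chain = 1L, step = keep),
                 config = chain$config, template = chain$template),
            class = "kin_ensemble")
}

#' Build an ensemble directly from parameter sets
#'
#' Mainly for small deterministic analyses (e.g. running the perturbation
#' panels on a single known parameter set).
#'
#' @param params_list list of [kin_params()] over identical parameter names.
#' @param errors optional per-member errors.
#' @return a `kin_ensemble`.
#' @export
ensemble_from_params <- function(params_list, errors = NA_real_) {
  stopifnot(length(params_list) >= 1L)
  thetas <- lapply(params_list, function(p) as_theta(as_kin_params(p)))
  members <- do.call(rbind, thetas)
  structure(list(members = members, errors = rep_len(errors, length(params_list)),
                 interval = 1L,
                 provenance = tibble::tibble(chain = NA_integer_,
                                             step = seq_along(params_list)),
                 config = kin_chain_config(),
                 template = as_kin_params(params_list[[1L]])),
            class = "kin_ensemble")
}

#' Combine ensembles from multiple chains
#'
#' @param ... `kin_ensemble` objects over identical parameter vectors.
#' @return a `kin_ensemble`.
#' @export
bind_ensembles <- function(...) {
  ens <- list(...)
  stopifnot(length(ens) >= 1L, all(vapply(ens, inherits, logical(1), "kin_ensemble")))
  prov <- dplyr::bind_rows(lapply(seq_along(ens), function(i) {
    dplyr::mutate(ens[[i]]$provenance, chain = i)
  }))
  structure(list(members = do.call(rbind, lapply(ens, `[[`, "members")),
                 errors = unlist(lapply(ens, `[[`, "errors")),
                 interval = ens[[1L]]$interval,
                 provenance = prov,
                 config = ens[[1L]]$config, template = ens[[1L]]$template),
            class = "kin_ensemble")
}

#' @export
print.kin_ensemble <- function(x, ...) {
  cat("<kin_ensemble> ", nrow(x$members), " members x ", ncol(x$members),
      " parameters (thinning interval ", x$interval, ")\n", sep = "")
  invisible(x)
}

#' Number of ensemble members
#' @param ensemble a `kin_ensemble`.
#' @return integer.
#' @export
ensemble_size <- function(ensemble) nrow(ensemble$members)

#' Extract one ensemble member as a parameter set
#'
#' @param ensemble a `kin_ensemble`.
#' @param i member index.
#' @return a [kin_params()].
#' @export
ensemble_member <- function(ensemble, i) {
  theta_to_params(ensemble$members[i, ], ensemble$template)
}

#' Per-parameter ensemble statistics
#'
#' Mean, standard deviation and coefficient of variation (CV = sd / mean)
#' for every parameter across the ensemble.
#'
#' @param ensemble a `kin_ensemble`.
#' @return tibble with columns `parameter`, `mean`, `sd`, `cv`.
#' @export
ensemble_stats <- function(ensemble) {
  m <- ensemble$members
  mu <- unname(colMeans(m))
  sd <- unname(apply(m, 2, stats::sd))
  tibble::tibble(parameter = colnames(m), mean = mu, sd = sd, cv = sd / mu)
}

#' @export
tidy.kin_ensemble <- function(x, ...) ensemble_stats(x)

#' @export
glance.kin_ensemble <- function(x, ...) {
  st <- ensemble_stats(x)
  tibble::tibble(n_members = nrow(x$members), n_parameters = ncol(x$members),
                 interval = x$interval, error_mean = mean(x$errors),
                 error_min = min(x$errors),
                 frac_cv_above_1 = mean(st$cv > 1))
}
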