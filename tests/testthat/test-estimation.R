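# Scale factors, error scoring, Metropolis machinery, thinning, ensemble.

test_that("scale factor matches exact proportionality and a grid-search oracle", {
  # exact proportionality: beta recovers the ratio with zero residual
  expect_equal(scale_factor(c(2, 4), c(1, 2), c(1, 1)), 2)

  grid_beta <- function(M, x, s) {
    bs <- seq(0, 5, by = 1e-4)
    obj <- vapply(bs, function(b) sum(((M - b * x) / s)^2), numeric(1))
    bs[which.min(obj)]
  }
  expect_equal(scale_factor(c(2, 0), c(1, 1), c(1, 1)),
               grid_beta(c(2, 0), c(1, 1), c(1, 1)), tolerance = 1e-3)
  # unequal sigmas reweight toward the precise observation
  b <- scale_factor(c(2, 0), c(1, 1), c(1, 10))
  expect_equal(b, grid_beta(c(2, 0), c(1, 1), c(1, 10)), tolerance = 1e-3)
  expect_equal(b, 1.980, tolerance = 1e-3)

  set.seed(3)
  for (i in 1:10) {
    M <- stats::runif(5, 0, 3); x <- stats::runif(5, 0.1, 3); s <- stats::runif(5, 0.2, 2)
    expect_equal(scale_factor(M, x, s), grid_beta(M, x, s), tolerance = 1e-3)
  }
  # all-zero simulation: beta undefined
  expect_true(is.na(scale_factor(c(1, 2), c(0, 0), c(1, 1))))
})

test_that("default stds follow the 10% rule with augmentation and floor", {
  expect_equal(default_stds(5), 0.5)
  expect_equal(default_stds(0), 1e-3)
  expect_equal(default_stds(5, flagged = TRUE, augment = 0.5), 2.5)
  expect_error(default_stds(5, flagged = TRUE, augment = 0.1), "augment")
})

# a two-species analytic fixture: zero-order source -> A -> degraded,
# steady state A* = k_in / k_out
analytic_training <- function(values, stds, clones = no_clones()) {
  obs <- tibble::tibble(dataset_id = "d1", species_id = "A",
                        condition = obs_condition("basal", c("ss", "ss"))[1:length(values)],
                        value = values, std = stds)
  kin_training(obs, list(d1 = list(clone = "AD", arms = list(basal = list()))),
               clones)
}

source_network <- function() {
  kin_network(sp_tbl("A", 1, TRUE),
              dplyr::bind_rows(
                rxn(side(character()), side("A"), "k_in", "zero-order"),
                rxn(side("A"), side(character()), "k_out", "dissociation")))
}

test_that("simulation error is zero up to scale and normalizes by observation count", {
  net <- source_network()
  p <- kin_params(c(k_in = 1e-3, k_out = 1e-4))  # A* = 10
  # observed = 3 x simulated: beta absorbs it exactly
  tr <- analytic_training(c(30, 30), c(1, 1))
  expect_equal(simulation_error(p, net, tr), 0, tolerance = 1e-8)
  # residuals of exactly 1 sigma each: E = 1 (beta = 1 by symmetry)
  tr2 <- analytic_training(c(11, 9), c(1, 1))
  expect_equal(simulation_error(p, net, tr2), 1, tolerance = 1e-4)
})

test_that("error is invariant to rescaling one observed series' units", {
  bundle <- toy_bundle()
  tr <- generate_training_data(bundle, seed = 5)
  E1 <- simulation_error(bundle$theta_star, bundle$network, tr)
  obs2 <- tr$observations
  pick <- obs2$dataset_id == "dht_timecourse_AD" & obs2$species_id == "PSA"
  obs2$value[pick] <- obs2$value[pick] * 10
  obs2$std[pick] <- obs2$std[pick] * 10
  tr2 <- kin_training(obs2, tr$datasets, tr$clones)
  E2 <- simulation_error(bundle$theta_star, bundle$network, tr2)
  expect_equal(E1, E2, tolerance = 1e-10)
})

test_that("failed simulations score as infinite error", {
  net <- source_network()
  tr <- analytic_training(c(10, 10), c(1, 1))
  # runaway accumulation never reaches the windowed steady state
  p_bad <- kin_params(c(k_in = 1, k_out = 1e-12))
  expect_equal(simulation_error(p_bad, net, tr, ss_control = list(max_windows = 3)), Inf)
})

test_that("log-space proposals are positive, centred and sigma-calibrated", {
  p <- kin_params(c(a = 1, b = 2), x0 = c(X = 3))
  cfg0 <- kin_chain_config(sigma = 0, n_steps = 1, seed = 1)
  set.seed(1)
  expect_equal(propose(p, cfg0)$k, p$k)

  cfg <- kin_chain_config(sigma = 0.2, n_steps = 1, seed = 1)
  set.seed(2)
  draws <- replicate(10000, as_theta(propose(p, cfg))[1])
  expect_true(all(draws > 0))
  emp_sd <- stats::sd(log(draws / 1))
  expect_lt(abs(emp_sd - 0.2) / 0.2, 0.05)
})

test_that("acceptance rule implements the Boltzmann ratio", {
  cfg <- kin_chain_config(E0 = 2, n_steps = 1, seed = 1)
  set.seed(3)
  # improvements always accepted
  expect_true(all(replicate(100, accept_proposal(5, 4.9, cfg))))
  # dE = E0 ln 2 accepted half the time
  dE <- 2 * log(2)
  acc <- mean(replicate(10000, accept_proposal(1, 1 + dE, cfg)))
  expect_lt(abs(acc - 0.5), 0.02)
  # infinite error never accepted
  expect_false(any(replicate(100, accept_proposal(1, Inf, cfg))))
})

test_that("chains are deterministic under a fixed seed", {
  efn <- function(p) sum(log(as_theta(p))^2)
  start <- kin_params(c(a = 1, b = 1))
  cfg <- kin_chain_config(sigma = 0.3, E0 = 1, n_steps = 50, seed = 99)
  c1 <- run_chain(start, cfg, efn)
  c2 <- run_chain(start, cfg, efn)
  expect_identical(c1$states, c2$states)
  expect_identical(c1$E, c2$E)
  expect_identical(c1$accepted, c2$accepted)
})

test_that("the E0 -> 0 limit is greedy descent", {
  efn <- function(p) sum(log(as_theta(p))^2)
  start <- kin_params(c(a = 3, b = 0.2))
  cfg <- kin_chain_config(sigma = 0.2, E0 = 1e-12, n_steps = 200, seed = 4)
  ch <- run_chain(start, cfg, efn)
  expect_true(all(diff(ch$E) <= 1e-12))
})

test_that("sampler reproduces the Boltzmann stationary density on a quadratic target", {
  # E = (log a)^2/2 + (log b)^2/2, E0 = 1: log-parameters are iid N(0, 1)
  efn <- function(p) sum(log(as_theta(p))^2) / 2
  cfg <- kin_chain_config(sigma = 1.2, E0 = 1, n_steps = 20000, seed = 7)
  ch <- run_chain(kin_params(c(a = 1, b = 1)), cfg, efn)
  la <- log(ch$states[-(1:2000), "a"])
  la <- la[seq(1, length(la), by = 10)]
  breaks <- stats::qnorm(seq(0, 1, by = 0.1))
  counts <- table(cut(la, breaks))
  chi <- stats::chisq.test(as.numeric(counts))
  expect_gt(chi$p.value, 0.01)
  expect_lt(abs(mean(la)), 0.1)
  expect_lt(abs(stats::sd(la) - 1), 0.1)
})

test_that("thinning interval recovers known autocorrelation structure", {
  set.seed(10)
  # white noise: everything kept
  expect_equal(thinning_interval(stats::rnorm(4000)), 1L)
  # AR(1) with rho = 0.9: interval ~ ln 20 / ln(1/0.9) ~ 28.4
  rho <- 0.9
  e <- as.numeric(stats::arima.sim(list(ar = rho), 20000))
  interval <- thinning_interval(e)
  expect_lt(abs(interval - log(20) / log(1 / rho)) / (log(20) / log(1 / rho)), 0.2)
})

test_that("thinning keeps every interval-th accepted state", {
  efn <- function(p) sum(log(as_theta(p))^2)
  cfg <- kin_chain_config(sigma = 0.5, E0 = 1, n_steps = 300, seed = 12)
  ch <- run_chain(kin_params(c(a = 1, b = 1)), cfg, efn)
  ens <- thin_by_autocorrelation(ch, interval = 7L)
  acc <- which(ch$accepted)
  expect_equal(ens$provenance$step, acc[seq(1, length(acc), by = 7)])
  expect_equal(ens$members,
               ch$states[ens$provenance$step + 1L, , drop = FALSE])
})

test_that("ensemble statistics compute CV exactly", {
  p1 <- kin_params(c(a = 1, b = 2))
  ensA <- ensemble_from_params(list(p1, p1, p1))
  expect_equal(ensemble_stats(ensA)$cv, c(0, 0))
  # two members k and 3k: mean 2k, sd sqrt(2) k, CV = sqrt(2)/2
  ensB <- ensemble_from_params(list(kin_params(c(a = 1)), kin_params(c(a = 3))))
  st <- ensemble_stats(ensB)
  expect_equal(st$mean, 2)
  expect_equal(st$cv, sqrt(2) / 2)
  g <- glance(ensB)
  expect_equal(g$n_members, 2L)
})

test_that("ensemble archives round-trip through the plain-text format", {
  efn <- function(p) sum(log(as_theta(p))^2)
  cfg <- kin_chain_config(sigma = 0.5, E0 = 1, n_steps = 100, seed = 13)
  ch <- run_chain(kin_params(c(a = 1, b = 2), x0 = c(X = 4)), cfg, efn)
  ens <- thin_by_autocorrelation(ch)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  ens2 <- read_ensemble(dir)
  expect_equal(ens2$members, ens$members)
  expect_equal(ens2$errors, ens$errors)
  expect_equal(ens2$interval, ens$interval)
  expect_equal(as_theta(ens2$template), as_theta(ens$template))
})
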