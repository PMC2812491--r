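# Kinetic sensitivities, OSSC aggregation, ranking, rank-shift tests.

test_that("sensitivities reproduce the one-species closed form", {
  # dx/dt = -k x, x(0) = 1: dx/dk = -t x(0) e^{-k t}
  net <- decay_network()
  k <- 2 / 3600  # per second; two e-folds per hour
  sens <- solve_sensitivities(net, kin_params(c(k = k)), c(A = 1, B = 0),
                              t_end_hr = 1, parameters = "k", n_out = 21)
  t_s <- sens$times_hr * 3600
  expect_equal(sens$s[, "A", "k"], -t_s * exp(-k * t_s), tolerance = 1e-5)
  # zero initial condition for rate-constant sensitivities
  expect_equal(sens$s[1, , "k"], c(A = 0, B = 0))
})

test_that("extended-system sensitivities match finite differences on a random network", {
  set.seed(21)
  net <- random_network(6, 9)
  p <- random_k(net)
  x0 <- stats::setNames(stats::runif(6, 0.5, 3), net$species$id)
  sens <- solve_sensitivities(net, p, x0, t_end_hr = 0.5, n_out = 21)
  k <- p$k
  for (pid in names(k)) {
    h <- 1e-4 * k[[pid]]
    proto <- kin_protocol(NULL, 0.5, output_times_hr = sens$times_hr)
    kp <- k; kp[pid] <- k[[pid]] + h
    km <- k; km[pid] <- k[[pid]] - h
    tp <- integrate_network(net, kin_params(kp), proto, x0 = x0, rtol = 1e-10, atol = 1e-13)
    tm <- integrate_network(net, kin_params(km), proto, x0 = x0, rtol = 1e-10, atol = 1e-13)
    fd <- (as.matrix(tp[, -1]) - as.matrix(tm[, -1])) / (2 * h)
    dev <- abs(sens$s[, , pid] - fd)
    scale <- pmax(abs(fd), 1e-8)
    expect_lt(max(dev / scale), 1e-4)
  }
})

test_that("OSSC collapses correctly in degenerate geometries", {
  bundle <- toy_bundle()
  net <- bundle$network
  p <- bundle$theta_star
  ss <- find_steady_state(net, p)
  # hormone activation rate has no influence without hormone: OSSC = 0
  sens <- solve_sensitivities(net, p, ss$state, t_end_hr = 100 / 3600,
                              parameters = c("k_act_AR_h", "k_deg_PSA"), n_out = 11)
  o <- ossc(sens)
  expect_equal(o$ossc[o$parameter == "k_act_AR_h"], 0)
  expect_gt(o$ossc[o$parameter == "k_deg_PSA"], 0)

  # single state, single time point: OSSC = |shat|
  sens1 <- list(times_hr = 0, states = matrix(2, 1, 1, dimnames = list(NULL, "A")),
                s = array(3, c(1, 1, 1), dimnames = list(NULL, "A", "k")),
                parameters = "k", k = c(k = 0.5))
  class(sens1) <- "kin_sensitivity"
  expect_equal(ossc(sens1)$ossc, abs(0.5 * 3 / 2))
})

test_that("OSSC is invariant under species relabeling", {
  set.seed(31)
  net <- random_network(5, 8)
  p <- random_k(net)
  x0 <- stats::setNames(stats::runif(5, 0.5, 3), net$species$id)
  o1 <- ossc(solve_sensitivities(net, p, x0, 0.3, n_out = 11))
  # permute species order in the network definition
  perm <- c(3, 1, 5, 2, 4)
  net2 <- kin_network(net$species[perm, ], net$reactions)
  o2 <- ossc(solve_sensitivities(net2, p, x0[perm], 0.3, n_out = 11))
  expect_equal(o1$ossc, o2$ossc, tolerance = 1e-7)
})

test_that("OSSC ordering agrees with a brute-force perturbation ranking", {
  # linear chain: the source step dominates the degradation of a bystander
  net <- chain_network()
  p <- chain_params()
  ss <- find_steady_state(net, p)
  sens <- solve_sensitivities(net, p, ss$state, t_end_hr = 2, n_out = 51)
  o <- ossc(sens)
  # brute force: +/-10% bumps, RMS change of all states over the window
  proto <- kin_protocol(NULL, 2, output_times_hr = sens$times_hr)
  base <- as.matrix(integrate_network(net, p, proto, x0 = ss$state)[, -1])
  bump <- vapply(names(p$k), function(pid) {
    kp <- p$k; kp[pid] <- kp[pid] * 1.1
    km <- p$k; km[pid] <- km[pid] * 0.9
    up <- as.matrix(integrate_network(net, kin_params(kp), proto, x0 = ss$state)[, -1])
    dn <- as.matrix(integrate_network(net, kin_params(km), proto, x0 = ss$state)[, -1])
    sqrt(mean(((up - dn) / pmax(base, 1e-6))^2))
  }, numeric(1))
  expect_equal(order(o$ossc), order(bump))
})

test_that("protocol rankings are deterministic permutations", {
  bundle <- toy_bundle()
  r1 <- ossc_protocol(bundle$network, bundle$theta_star, "AD", bundle$clones,
                      parameters = names(bundle$theta_star$k)[1:10], n_out = 21)
  r2 <- ossc_protocol(bundle$network, bundle$theta_star, "AD", bundle$clones,
                      parameters = names(bundle$theta_star$k)[1:10], n_out = 21)
  expect_identical(r1$rank, r2$rank)
  expect_setequal(r1$rank, 1:10)
  # ties break by parameter order
  expect_equal(rank_ossc(c(0.5, 0.5, 0.1)), c(2L, 3L, 1L))
})

test_that("clone variants reorder parameter importance", {
  bundle <- toy_bundle()
  pars <- c("k_act_lig", "k_deact_phos", "k_tx_PHOS", "k_tl_CYCD",
            "k_act_AR_mapk", "k_deg_PSA", "k_act_K3", "k_release_4E")
  rAD <- ossc_protocol(bundle$network, bundle$theta_star, "AD", bundle$clones,
                       parameters = pars, n_out = 21)
  rAI <- ossc_protocol(bundle$network, bundle$theta_star, "AI", bundle$clones,
                       parameters = pars, n_out = 21)
  expect_gt(sum(rAD$rank != rAI$rank), 0)
})

test_that("rank-shift testing flags constructed shifts and controls the null", {
  # identical ensembles: nothing shifts
  rk <- tidyr::expand_grid(member = 1:5, clone = c("A", "B"), parameter = letters[1:4])
  rk$rank <- rep(1:4, 10)
  res0 <- rank_shift_test(rk, "A", "B")
  expect_true(all(res0$mean_shift == 0))
  expect_false(any(res0$significant))

  # N(10, 1) vs N(20, 1): significant positive shift
  set.seed(41)
  mk <- function(mu, clone) tidyr::expand_grid(member = 1:30, clone = clone,
                                               parameter = "p1") |>
    dplyr::mutate(rank = stats::rnorm(30, mu, 1))
  res1 <- rank_shift_test(dplyr::bind_rows(mk(10, "A"), mk(20, "B")), "A", "B")
  expect_true(res1$significant)
  expect_gt(res1$mean_shift, 5)

  # under the null with no correction, ~5% false positives
  set.seed(42)
  null_rk <- tidyr::expand_grid(member = 1:20, clone = c("A", "B"),
                                parameter = paste0("p", 1:300))
  null_rk$rank <- stats::rnorm(nrow(null_rk), 10, 2)
  resn <- rank_shift_test(null_rk, "A", "B")
  expect_lt(abs(mean(resn$significant) - 0.05), 0.03)
  # BH switch suppresses them
  resb <- rank_shift_test(null_rk, "A", "B", p_adjust = "BH")
  expect_lt(mean(resb$significant), 0.02)
  # tiny ensembles are refused
  expect_error(rank_shift_test(rk[rk$member < 3, ], "A", "B"), "at least 3")
})
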