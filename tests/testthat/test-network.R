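# Network model: parser, stoichiometry, rate laws, analytic derivatives.

test_that("flat-format parsing builds the documented stoichiometry", {
  path <- write_lines_tmp(c(
    "[SPECIES]",
    "A\tcytosol\t1\t0",
    "B\tcytosol\t2\t0",
    "C\tcytosol\t0\t0",
    "[REACTIONS]",
    "r1\tA + B -> C\tk1"))
  net <- read_network(path)
  expect_equal(nrow(net$species), 3L)
  expect_equal(nrow(net$reactions), 1L)
  expect_equal(unname(stoichiometric_matrix(net)[, 1]), c(-1, -1, 1))
  # species order is file order (reproducibility contract)
  expect_equal(net$species$id, c("A", "B", "C"))
})

test_that("reversible syntax expands to two irreversible reactions", {
  path <- write_lines_tmp(c(
    "[SPECIES]",
    "A\tcytosol\t1\t0",
    "B\tcytosol\t2\t0",
    "C\tcytosol\t0\t0",
    "[REACTIONS]",
    "r1\tA + B <-> C\tkf, kr"))
  net <- read_network(path)
  expect_equal(nrow(net$reactions), 2L)
  expect_equal(net$reactions$rate_constant, c("kf", "kr"))
  S <- stoichiometric_matrix(net)
  expect_equal(unname(S[, "kf"]), c(-1, -1, 1))
  expect_equal(unname(S[, "kr"]), c(1, 1, -1))
  # net flux of the pair equals the reversible mass-action law for any state
  p <- kin_params(c(kf = 2, kr = 0.5))
  for (i in 1:5) {
    x <- stats::runif(3, 0, 4)
    r <- massaction_rates(net, p, stats::setNames(x, c("A", "B", "C")))
    net_flux <- sum(S["C", ] * r)
    expect_equal(net_flux, 2 * x[1] * x[2] - 0.5 * x[3])
  }
})

test_that("undeclared species and malformed input are reported with the line", {
  path <- write_lines_tmp(c(
    "[SPECIES]",
    "A\tcytosol\t1\t0",
    "[REACTIONS]",
    "r1\tA -> D\tk1"))
  expect_error(read_network(path), "undeclared species: D")
  expect_error(read_network(path), ":4:")
  path2 <- write_lines_tmp(c(
    "[SPECIES]",
    "A\tcytosol\t-1\t0",
    "[REACTIONS]",
    "r1\tA -> A\tk1"))
  expect_error(read_network(path2), "initial value")
})

test_that("stoichiometric matrix handles net, zero-order and coefficient cases", {
  # catalytic self-reaction 2A -> A nets to -1
  net <- kin_network(sp_tbl("A", 1),
                     rxn(side("A", 2L), side("A"), "k", "catalytic"))
  expect_equal(unname(stoichiometric_matrix(net)[, 1]), -1)
  # zero-order production: all zeros except +1 at the product
  net2 <- kin_network(sp_tbl(c("A", "P"), c(1, 0), c(FALSE, TRUE)),
                      rxn(side(character()), side("P"), "k", "zero-order"))
  expect_equal(unname(stoichiometric_matrix(net2)[, 1]), c(0, 1))
})

test_that("mass-action rates follow the rate law", {
  path <- write_lines_tmp(c(
    "[SPECIES]", "A\tcytosol\t3\t0", "B\tcytosol\t4\t0", "C\tcytosol\t0\t0",
    "[REACTIONS]", "r1\tA + B -> C\tk1"))
  net <- read_network(path)
  r <- massaction_rates(net, kin_params(c(k1 = 2)), c(A = 3, B = 4, C = 0))
  expect_equal(r, 24)
  # a zero-concentration reactant silences the reaction
  expect_equal(massaction_rates(net, kin_params(c(k1 = 2)), c(A = 0, B = 4, C = 0)), 0)
  expect_error(massaction_rates(net, kin_params(c(k1 = 2)), c(A = -1, B = 4, C = 0)),
               "negative")
})

test_that("rates match independent symbolic evaluation on random networks", {
  set.seed(42)
  for (rep in 1:3) {
    net <- random_network()
    p <- random_k(net)
    x <- stats::setNames(stats::runif(nrow(net$species), 0, 5), net$species$id)
    r <- massaction_rates(net, p, x)
    # independent oracle: evaluate each monomial from the reaction table
    expected <- vapply(seq_len(nrow(net$reactions)), function(q) {
      re <- net$reactions$reactants[[q]]
      p$k[[net$reactions$rate_constant[q]]] *
        prod(x[re$id]^re$coef)
    }, numeric(1))
    expect_equal(r, expected, tolerance = 1e-12)
  }
})

test_that("rhs is the stoichiometric image of the rates", {
  net <- decay_network()
  d <- network_rhs(net, kin_params(c(k = 1)), c(A = 1, B = 0))
  expect_equal(unname(d), c(-1, 1))
  # all-zero rates give a zero derivative vector
  d0 <- network_rhs(net, kin_params(c(k = 1)), c(A = 0, B = 5))
  expect_equal(unname(d0), c(0, 0))
})

test_that("analytic Jacobians match central finite differences", {
  net <- decay_network()
  A <- network_jacobian(net, kin_params(c(k = 0.7)), c(A = 2, B = 0))
  expect_equal(unname(A), rbind(c(-0.7, 0), c(0.7, 0)))

  set.seed(7)
  for (rep in 1:20) {
    net <- random_network()
    p <- random_k(net)
    x <- stats::setNames(stats::runif(nrow(net$species), 0.1, 5), net$species$id)
    A <- network_jacobian(net, p, x)
    B <- parameter_jacobian(net, p, x)
    hx <- 1e-6 * pmax(1, abs(x))
    Afd <- sapply(seq_along(x), function(m) {
      xp <- x; xp[m] <- x[m] + hx[m]
      xm <- x; xm[m] <- x[m] - hx[m]
      (network_rhs(net, p, xp) - network_rhs(net, p, xm)) / (2 * hx[m])
    })
    scale_A <- max(abs(Afd), 1)
    expect_lt(max(abs(A - Afd)) / scale_A, 1e-5)
    k <- p$k
    hk <- 1e-6 * pmax(1, abs(k))
    Bfd <- sapply(seq_along(k), function(j) {
      kp <- k; kp[j] <- k[j] + hk[j]
      km <- k; km[j] <- k[j] - hk[j]
      (network_rhs(net, kin_params(kp), x) - network_rhs(net, kin_params(km), x)) / (2 * hk[j])
    })
    scale_B <- max(abs(Bfd), 1)
    expect_lt(max(abs(B - Bfd)) / scale_B, 1e-5)
  }
})

test_that("parameter-derivative columns vanish with a zero-concentration reactant", {
  path <- write_lines_tmp(c(
    "[SPECIES]", "A\tcytosol\t2\t0", "B\tcytosol\t0\t0", "C\tcytosol\t0\t0",
    "[REACTIONS]", "r1\tA -> B\tk1", "r2\tB + A -> C\tk2"))
  net <- read_network(path)
  B <- parameter_jacobian(net, kin_params(c(k1 = 1, k2 = 1)), c(A = 2, B = 0, C = 0))
  expect_equal(unname(B[, "k1"]), c(-2, 2, 0))
  expect_equal(unname(B[, "k2"]), c(0, 0, 0))
})

test_that("network round-trips through the writer", {
  net <- toy_bundle()$network
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, path)
  net2 <- read_network(path)
  expect_equal(net2$species, net$species)
  expect_equal(stoichiometric_matrix(net2), stoichiometric_matrix(net))
  expect_equal(net2$reactions$rate_constant, net$reactions$rate_constant)
})

test_that("conserved moieties are constant along toy trajectories", {
  bundle <- toy_bundle()
  net <- bundle$network
  M <- conserved_moieties(net)
  expect_gte(nrow(M), 10)  # protein pools, ligands, ribosome
  # hormone folded into the initial state: events change the hormone total
  # by design, conservation holds between events
  x0 <- initial_state(net, bundle$theta_star)
  x0["H"] <- 10
  proto <- kin_protocol(NULL, t_end_hr = 72, output_times_hr = seq(0, 72, by = 4))
  traj <- integrate_network(net, bundle$theta_star, proto, x0 = x0)
  X <- as.matrix(traj[, net$species$id])
  totals <- X %*% t(M)
  drift <- apply(totals, 2, function(v) max(abs(v - v[1])) / max(abs(v[1]), 1e-8))
  expect_lt(max(drift), 1e-6)
})
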