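#' @importFrom rlang .data abort warn
#' @importFrom stats setNames
NULL

VALID_COMPARTMENTS <- c("cytosol", "membrane", "extracellular")
REACTION_KINDS <- c("association", "dissociation", "catalytic", "zero-order")

#' Construct a validated reaction network
#'
#' A `kin_network` holds an ordered species table, an ordered table of
#' irreversible mass-action reactions, and the stoichiometric matrix `S`
#' (species x reactions, integer entries; negative for consumption,
#' positive for production). The species and reaction order is part of the
#' reproducibility contract: matrix layouts and output columns follow it.
#'
#' @param species tibble with columns `id`, `compartment`
#'   (`cytosol`/`membrane`/`extracellular`), `initial_value` (A.U., >= 0)
#'   and `synthesized` (logical: species participates in zero-order or
#'   catalytic expression).
#' @param reactions tibble with columns `id`, `rate_constant` (parameter
#'   id), `kind`, and list-columns `reactants`/`products`, each a data
#'   frame with columns `id` (species id) and `coef` (positive integer
#'   stoichiometric coefficient).
#' @return an object of class `kin_network`.
#' @export
kin_network <- function(species, reactions) {
  species <- tibble::as_tibble(species)
  reactions <- tibble::as_tibble(reactions)
  if (anyDuplicated(species$id)) {
    abort(paste0("duplicate species id: ",
                 paste(unique(species$id[duplicated(species$id)]), collapse = ", ")))
  }
  if (any(species$initial_value < 0)) {
    abort("species initial values must be >= 0")
  }
  bad <- setdiff(species$compartment, VALID_COMPARTMENTS)
  if (length(bad)) abort(paste0("unknown compartment: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(reactions$rate_constant)) {
    abort("rate constant ids must be unique across irreversible reactions")
  }
  for (q in seq_len(nrow(reactions))) {
    for (side in c("reactants", "products")) {
      tbl <- reactions[[side]][[q]]
      unknown <- setdiff(tbl$id, species$id)
      if (length(unknown)) {
        abort(paste0("reaction ", reactions$id[q], " references undeclared species: ",
                     paste(unknown, collapse = ", ")))
      }
      if (nrow(tbl) && (any(tbl$coef < 1) || any(tbl$coef != round(tbl$coef)))) {
        abort(paste0("reaction ", reactions$id[q],
                     " has non positive-integer stoichiometric coefficients"))
      }
    }
    if (nrow(reactions$reactants[[q]]) == 0L && reactions$kind[q] != "zero-order") {
      abort(paste0("reaction ", reactions$id[q],
                   " has no reactants but is not zero-order"))
    }
  }
  new_kin_network(species, reactions)
}

new_kin_network <- function(species, reactions) {
  nsp <- nrow(species)
  nrx <- nrow(reactions)
  S <- matrix(0, nsp, nrx, dimnames = list(species$id, reactions$rate_constant))
  for (q in seq_len(nrx)) {
    re <- reactions$reactants[[q]]
    pr <- reactions$products[[q]]
    for (i in seq_len(nrow(re))) {
      S[re$id[i], q] <- S[re$id[i], q] - re$coef[i]
    }
    for (i in seq_len(nrow(pr))) {
      S[pr$id[i], q] <- S[pr$id[i], q] + pr$coef[i]
    }
  }
  ridx <- lapply(reactions$reactants, function(re) match(re$id, species$id))
  rcoef <- lapply(reactions$reactants, function(re) as.numeric(re$coef))
  net <- structure(list(species = species, reactions = reactions, stoich = S),
                   class = "kin_network")
  # fast-path tables: with all reactant coefficients equal to 1 the rate
  # monomials are plain products, evaluated with a sentinel-padded index
  # matrix (index nsp + 1 holds the constant 1)
  unit_coef <- all(vapply(rcoef, function(co) all(co == 1), logical(1)))
  maxar <- max(c(0L, lengths(ridx)))
  Rmat <- matrix(nsp + 1L, nrx, max(maxar, 1L))
  for (q in seq_len(nrx)) {
    if (length(ridx[[q]])) Rmat[q, seq_along(ridx[[q]])] <- ridx[[q]]
  }
  attr(net, "tables") <- list(nsp = nsp, nrx = nrx, ridx = ridx, rcoef = rcoef,
                              S = S, unit_coef = unit_coef, Rmat = Rmat,
                              maxar = maxar)
  net
}

#' @export
print.kin_network <- function(x, ...) {
  cat("<kin_network> ", nrow(x$species), " species, ",
      nrow(x$reactions), " irreversible reactions\n", sep = "")
  counts <- table(x$reactions$kind)
  cat("  kinds: ", paste(names(counts), counts, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

net_tables <- function(net) attr(net, "tables")

#' Stoichiometric matrix of a network
#'
#' @param net a `kin_network`.
#' @return numeric matrix (species x reactions); entry `S[i, q]` is negative
#'   if species `i` is net-consumed by reaction `q`, positive if produced,
#'   zero otherwise. Catalysts (same species on both sides) net to zero.
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "kin_network"))
  net$stoich
}

# ---- rate laws ------------------------------------------------------------

# product over reactants of x^coef, per reaction; the rate with k = 1.
# Zero-order reactions give 1 by the empty product.
rate_monomials <- function(tabs, state) {
  if (tabs$unit_coef) {
    xx <- c(unname(state), 1)
    pr <- xx[tabs$Rmat[, 1L]]
    if (tabs$maxar > 1L) {
      for (j in 2:tabs$maxar) pr <- pr * xx[tabs$Rmat[, j]]
    }
    return(pr)
  }
  pr <- rep(1, tabs$nrx)
  for (q in seq_len(tabs$nrx)) {
    idx <- tabs$ridx[[q]]
    if (length(idx)) pr[q] <- prod(state[idx]^tabs$rcoef[[q]])
  }
  pr
}

# d(monomial_q)/d(x_m): nrx x nsp matrix, nonzero only at reactant species.
rate_monomial_grad <- function(tabs, state) {
  if (tabs$unit_coef) {
    xx <- c(unname(state), 1)
    cols <- lapply(seq_len(tabs$maxar), function(j) xx[tabs$Rmat[, j]])
    G <- matrix(0, tabs$nrx, tabs$nsp + 1L)
    qs <- seq_len(tabs$nrx)
    for (j in seq_len(tabs$maxar)) {
      gj <- rep(1, tabs$nrx)
      for (l in seq_len(tabs$maxar)) if (l != j) gj <- gj * cols[[l]]
      G[cbind(qs, tabs$Rmat[, j])] <- gj
    }
    return(G[, seq_len(tabs$nsp), drop = FALSE])
  }
  G <- matrix(0, tabs$nrx, tabs$nsp)
  for (q in seq_len(tabs$nrx)) {
    idx <- tabs$ridx[[q]]
    co <- tabs$rcoef[[q]]
    if (!length(idx)) next
    for (j in seq_along(idx)) {
      others <- if (length(idx) > 1L) prod(state[idx[-j]]^co[-j]) else 1
      G[q, idx[j]] <- co[j] * state[idx[j]]^(co[j] - 1) * others
    }
  }
  G
}

check_params <- function(params, net) {
  k <- params_k(params, net)
  if (any(!is.finite(k)) || any(k <= 0)) {
    abort("all rate constants must be finite and strictly positive")
  }
  k
}

#' Mass-action reaction rates
#'
#' The rate of reaction `q` is `r_q = k_q * prod_j x_j^c_jq` over its
#' reactants; zero-order reactions run at `k_q`.
#'
#' @param net a `kin_network`.
#' @param params a [kin_params()] object or named vector of rate constants.
#' @param state named (or network-ordered) non-negative concentration vector.
#' @return numeric vector of length `n_reactions`, all entries `>= 0`.
#' @export
massaction_rates <- function(net, params, state) {
  tabs <- net_tables(net)
  state <- order_state(state, net)
  if (any(state < 0)) abort("negative concentrations passed to massaction_rates")
  k <- check_params(params, net)
  unname(k * rate_monomials(tabs, state))
}

#' Right-hand side of the mass-balance ODE system
#'
#' `dx/dt = S r(x; k)` with `S` the stoichiometric matrix and `r` the
#' mass-action rate vector.
#'
#' @inheritParams massaction_rates
#' @return named derivative vector of length `n_species`.
#' @export
network_rhs <- function(net, params, state) {
  tabs <- net_tables(net)
  state <- order_state(state, net)
  drop(tabs$S %*% massaction_rates(net, params, state))
}

#' Analytic Jacobian of the mass balances with respect to the states
#'
#' Mass-action rates are polynomial in the state, so
#' `A[i, m] = d(dx_i/dt)/dx_m` has a closed form.
#'
#' @inheritParams massaction_rates
#' @return `n_species x n_species` matrix.
#' @export
network_jacobian <- function(net, params, state) {
  tabs <- net_tables(net)
  state <- order_state(state, net)
  k <- check_params(params, net)
  G <- rate_monomial_grad(tabs, state)   # nrx x nsp
  A <- tabs$S %*% (G * k)
  dimnames(A) <- list(rownames(tabs$S), rownames(tabs$S))
  A
}

#' Analytic derivative of the mass balances with respect to the rate constants
#'
#' Each mass-action rate depends linearly on exactly one rate constant, so
#' column `q` of `B` is `S[, q] * r_q / k_q` (the rate monomial, no division
#' performed).
#'
#' @inheritParams massaction_rates
#' @return `n_species x n_reactions` matrix, columns named by rate-constant id.
#' @export
parameter_jacobian <- function(net, params, state) {
  tabs <- net_tables(net)
  state <- order_state(state, net)
  check_params(params, net)
  pr <- rate_monomials(tabs, state)
  B <- sweep(tabs$S, 2, pr, `*`)
  dimnames(B) <- dimnames(tabs$S)
  B
}

# Reorder a state vector to network species order; unnamed vectors are
# assumed to already be in order.
order_state <- function(state, net) {
  ids <- net$species$id
  if (is.null(names(state))) {
    if (length(state) != length(ids)) abort("state length does not match network")
    return(setNames(as.numeric(state), ids))
  }
  missing <- setdiff(ids, names(state))
  if (length(missing)) abort(paste0("state is missing species: ", paste(missing, collapse = ", ")))
  setNames(as.numeric(state[ids]), ids)
}

#' Conserved moieties of a network
#'
#' Rows span the left null space of the stoichiometric matrix: every
#' returned combination `y' x(t)` is constant along any trajectory of the
#' mass-balance ODEs (e.g. total receptor = inactive + active form).
#'
#' @param net a `kin_network`.
#' @param tol singular values below `tol * max(singular value)` are treated
#'   as zero.
#' @return matrix with one row per conserved combination (possibly 0 rows),
#'   columns named by species.
#' @export
conserved_moieties <- function(net, tol = 1e-10) {
  S <- stoichiometric_matrix(net)
  ns <- MASS::Null(S)  # basis of the null space of t(S): y with y'S = 0
  if (length(ns) == 0) {
    return(matrix(0, 0, nrow(S), dimnames = list(NULL, rownames(S))))
  }
  M <- t(ns)
  colnames(M) <- rownames(S)
  M
}
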