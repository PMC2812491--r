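# Small networks and fixtures built in code.

rxn <- function(reactants, products, k_id, kind) {
  tibble::tibble(id = k_id, rate_constant = k_id, kind = kind,
                 reactants = list(reactants), products = list(products))
}

side <- function(ids, coef = rep(1L, length(ids))) {
  tibble::tibble(id = ids, coef = as.integer(coef))
}

sp_tbl <- function(ids, iv, synthesized = rep(FALSE, length(ids))) {
  tibble::tibble(id = ids, compartment = "cytosol", initial_value = iv,
                 synthesized = synthesized)
}

# one-species exponential decay: dx/dt = -k x, in per-hour units
# (k value chosen per test)
decay_network <- function() {
  kin_network(sp_tbl(c("A", "B"), c(1, 0)),
              rxn(side("A"), side("B"), "k", "dissociation"))
}

# linear chain S -> M -> P (constant source, both steps first order)
chain_network <- function() {
  species <- sp_tbl(c("S", "M", "P"), c(5, 0, 0))
  reactions <- dplyr::bind_rows(
    rxn(side("S"), side(c("S", "M")), "k_make_M", "catalytic"),
    rxn(side("M"), side("P"), "k_make_P", "dissociation"),
    rxn(side("M"), side(character()), "k_deg_M", "dissociation"),
    rxn(side("P"), side(character()), "k_deg_P", "dissociation"))
  kin_network(species, reactions)
}

chain_params <- function() {
  kin_params(c(k_make_M = 1e-3, k_make_P = 5e-4, k_deg_M = 1e-3, k_deg_P = 1e-3))
}

# random mass-action network for property tests (fixed seed set by caller)
random_network <- function(n_species = 10L, n_reactions = 14L) {
  ids <- paste0("X", seq_len(n_species))
  species <- sp_tbl(ids, stats::runif(n_species, 0.5, 5))
  reactions <- dplyr::bind_rows(lapply(seq_len(n_reactions), function(q) {
    arity <- sample(0:2, 1, prob = c(0.15, 0.45, 0.4))
    re <- sample(ids, arity)
    pr <- sample(setdiff(ids, re), sample(1:2, 1))
    kind <- if (arity == 0) "zero-order" else if (arity == 2) "association" else "dissociation"
    rxn(side(re), side(pr), paste0("k", q), kind)
  }))
  kin_network(species, reactions)
}

random_k <- function(net) {
  ks <- net$reactions$rate_constant
  kin_params(stats::setNames(10^stats::runif(length(ks), -4, -2), ks))
}

# two uncoupled axes A/B producing Q additively: alpha must vanish
additive_synergy_network <- function() {
  species <- sp_tbl(c("A", "B", "Q"), c(2, 3, 0))
  reactions <- dplyr::bind_rows(
    rxn(side("A"), side(c("A", "Q")), "k_from_A", "catalytic"),
    rxn(side("B"), side(c("B", "Q")), "k_from_B", "catalytic"),
    rxn(side("Q"), side(character()), "k_deg_Q", "dissociation"))
  kin_network(species, reactions)
}

# AND-gate: Q produced only by the bimolecular A+B encounter
andgate_synergy_network <- function() {
  species <- sp_tbl(c("A", "B", "Q"), c(2, 3, 0))
  reactions <- dplyr::bind_rows(
    rxn(side(c("A", "B")), side(c("A", "B", "Q")), "k_and", "catalytic"),
    rxn(side("Q"), side(character()), "k_deg_Q", "dissociation"))
  kin_network(species, reactions)
}

no_clones <- function() {
  tibble::tibble(clone = character(), parameter = character(), factor = numeric())
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
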