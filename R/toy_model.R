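# Bundled synthetic signaling network.
#
# A reduced receptor / MAPK-cascade / Akt-translation / hormone-receptor
# network with the structural features the analyses need: conserved protein
# pools, zero-order gene expression, a phosphatase negative feedback on the
# growth-factor receptor whose own expression is repressed by the active
# hormone receptor, and a bimolecular translation step coupling the two
# signaling axes. Clone variants differ only in the phosphatase expression
# rate (AD 1.0, MID 0.5, AI 0.01), emulating progressively
# hormone-independent cell lines.

toy_file <- function(name) {
  path <- system.file("extdata", name, package = "enkin")
  if (!nzchar(path)) abort(paste0("bundled file not found: ", name))
  path
}

#' Build the bundled toy model
#'
#' Deterministic (no RNG): reads the versioned network, ground-truth
#' parameters, hand-tuned starting guess, clone table and stimulus protocol
#' shipped with the package.
#'
#' @return an object of class `kin_bundle` with elements `network`,
#'   `theta_star` (ground truth [kin_params()]), `k0` (hand-tuned chain
#'   start), `clones`, `protocols` (named list of [kin_protocol()]),
#'   `stimulus`, `markers`, `targets`, `axes` and `identifiable`
#'   (parameters directly constrained by the observed species).
#' @export
build_toy_network <- function() {
  network <- read_network(toy_file("toy_network.txt"))
  theta_star <- read_params(toy_file("toy_theta_star.txt"), label = "AD")
  k0 <- read_params(toy_file("toy_k0.txt"), label = "AD")
  clones <- utils::read.csv(toy_file("toy_clones.csv"), stringsAsFactors = FALSE)
  protocols <- list(
    dht = read_protocol(toy_file("toy_protocol_dht.yml")))
  structure(list(
    network = network, theta_star = theta_star, k0 = k0,
    clones = tibble::as_tibble(clones), protocols = protocols,
    stimulus = list(species = "H", amount = 10),
    markers = c("CYCD", "PSA", "K1a", "ARa"),
    targets = c("K3", "K2", "K1", "AKT", "TOR", "EIF4E", "FEBP"),
    axes = c("K1", "AKT"),
    identifiable = c("k_deg_PSA", "k_deg_CYCD", "k_deg_PHOS",
                     "k_act_AR_h", "k_deact_K1")),
    class = "kin_bundle")
}

#' @export
print.kin_bundle <- function(x, ...) {
  cat("<kin_bundle> toy signaling network: ", nrow(x$network$species),
      " species, ", nrow(x$network$reactions), " reactions, clones ",
      paste(unique(c("AD", x$clones$clone)), collapse = "/"), "\n", sep = "")
  invisible(x)
}

dht_event <- function(time_hr = 1, amount = 10) {
  tibble::tibble(time_hr = time_hr, kind = "add_species", target = "H",
                 value = amount)
}

# dataset recipes simulated by the generator and reused by the scorer
toy_datasets <- function() {
  list(
    dht_timecourse_AD = list(
      clone = "AD",
      arms = list(dht = list(events = dht_event())),
      species = c("PSA", "PHOS", "Ra"),
      times = c(0, 2, 4, 8, 16, 24, 48, 73)),
    dht_timecourse_AI = list(
      clone = "AI",
      arms = list(dht = list(events = dht_event())),
      species = c("PSA", "CYCD"),
      times = c(0, 2, 6, 12, 24, 48, 73)),
    cascade_activation_AD = list(
      clone = "AD",
      arms = list(gf = list(events = tibble::tibble(
        time_hr = 0, kind = "add_species", target = "L", value = 8))),
      species = c("K1a", "Ra"),
      times = c(0.05, 0.1, 0.25, 0.5, 1, 2)),
    receptor_perturbation_AD = list(
      clone = "AD",
      arms = list(basal = list(),
                  up = list(ic_scale = list(R = 1.5)),
                  down = list(ic_scale = list(R = 0.5))),
      species = c("PSA", "CYCD"),
      times = "ss"),
    kinase_perturbation_AI = list(
      clone = "AI",
      arms = list(basal = list(),
                  up = list(ic_scale = list(K2 = 1.5)),
                  down = list(ic_scale = list(K2 = 0.5))),
      species = "PSA",
      times = "ss"),
    dht_dose_AD = list(
      clone = "AD",
      arms = list(dose1 = list(events = dht_event(amount = 1)),
                  dose10 = list(events = dht_event(amount = 10))),
      species = c("CYCD", "PSA"),
      times = 25),
    basal_signaling_AD = list(
      clone = "AD",
      arms = list(basal = list()),
      species = c("Ra", "K1a", "AKTa", "PHOS"),
      times = "ss"))
}

#' Generate pseudo-immunoblot training data from the toy model
#'
#' Simulates every dataset at the ground truth, multiplies each
#' (dataset, species) series by a hidden scale drawn log-uniformly from
#' `[0.1, 10]` (the arbitrary-unit regime the scale-factor machinery must
#' absorb), adds Gaussian noise with a standard deviation of 10% of each
#' value, and records that 10% standard deviation with the observation.
#'
#' @param bundle a [build_toy_network()] bundle.
#' @param seed RNG seed; the returned set is identical under a fixed seed.
#' @param noise add the 10% Gaussian noise (disable for self-consistency
#'   checks: the noiseless set gives simulation error 0 at the truth).
#' @param hidden_scales draw the per-series scales (disable to keep
#'   simulated units).
#' @return a [kin_training()]; the hidden scales are attached as attribute
#'   `hidden_scales` for validation studies only.
#' @export
generate_training_data <- function(bundle, seed = 1L, noise = TRUE,
                                   hidden_scales = TRUE) {
  set.seed(seed)
  net <- bundle$network
  recipes <- toy_datasets()
  rows <- list()
  for (ds_id in names(recipes)) {
    rec <- recipes[[ds_id]]
    p <- apply_clone(bundle$theta_star, rec$clone, bundle$clones)
    for (arm_name in names(rec$arms)) {
      arm <- rec$arms[[arm_name]]
      prep <- apply_arm_scales(net, p, arm)
      ss <- find_steady_state(net, prep$params, x0 = prep$x0)
      if (identical(rec$times, "ss")) {
        vals <- stats::setNames(ss$state[rec$species], rec$species)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          dataset_id = ds_id, species_id = rec$species,
          condition = obs_condition(arm_name, rep("ss", length(rec$species))),
          value = as.numeric(vals))
      } else {
        proto <- kin_protocol(arm$events, t_end_hr = max(rec$times),
                              output_times_hr = sort(unique(c(0, rec$times))))
        traj <- integrate_network(net, prep$params, proto, x0 = ss$state)
        for (sp in rec$species) {
          idx <- vapply(rec$times, function(t) which.min(abs(traj$time_hr - t)),
                        integer(1))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            dataset_id = ds_id, species_id = sp,
            condition = obs_condition(arm_name, rec$times),
            value = traj[[sp]][idx])
        }
      }
    }
  }
  obs <- dplyr::bind_rows(rows)
  # hidden per-(dataset, species) blot scale
  series <- unique(obs[, c("dataset_id", "species_id")])
  series$scale <- if (hidden_scales) {
    10^stats::runif(nrow(series), -1, 1)
  } else {
    rep(1, nrow(series))
  }
  obs <- dplyr::left_join(obs, series, by = c("dataset_id", "species_id"))
  obs$value <- obs$value * obs$scale
  if (noise) obs$value <- obs$value + stats::rnorm(nrow(obs), 0, 0.10 * abs(obs$value))
  obs$std <- default_stds(obs$value)
  obs$scale <- NULL
  datasets <- lapply(recipes, function(rec) rec[c("clone", "arms")])
  tr <- kin_training(obs, datasets, bundle$clones)
  attr(tr, "hidden_scales") <- series
  tr
}

#' Parameter-recovery experiment on the toy model
#'
#' Generates training data at the ground truth, runs a Metropolis chain
#' from the hand-tuned start, thins it into an ensemble and reports
#' per-parameter z-scores of the truth against the ensemble,
#' `z = (mean - theta*) / sd`. Parameters directly constrained by the
#' observed species are flagged `identifiable`.
#'
#' @param bundle a [build_toy_network()] bundle.
#' @param config a [kin_chain_config()]; the default (sigma 0.05, E0 0.5,
#'   300 steps per chain) is sized for a desk-scale run.
#' @param seed seed for the training data; chain `i` runs at
#'   `config$seed + 1000 * (i - 1)`.
#' @param n_chains number of independent chains, all started from `k0`.
#' @param training optionally reuse an existing training set.
#' @return list with `ensemble`, `chains`, `stats` (tibble: `parameter`,
#'   `truth`, `mean`, `sd`, `cv`, `z`, `identifiable`) and
#'   `frac_identifiable_z2` (fraction of identifiable parameters with
#'   `|z| <= 2`).
#' @export
recovery_experiment <- function(bundle, config = NULL, seed = 1L, n_chains = 2L,
                                training = NULL) {
  if (is.null(config)) {
    config <- kin_chain_config(sigma = 0.05, E0 = 0.5, n_steps = 300,
                               seed = seed + 1000L)
  }
  if (is.null(training)) training <- generate_training_data(bundle, seed = seed)
  error_fn <- make_error_fn(bundle$network, training)
  chains <- lapply(seq_len(n_chains), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * (i - 1L)
    run_chain(bundle$k0, cfg, error_fn)
  })
  ensemble <- do.call(bind_ensembles, lapply(chains, thin_by_autocorrelation))
  st <- ensemble_stats(ensemble)
  truth <- as_theta(bundle$theta_star)
  st$truth <- as.numeric(truth[st$parameter])
  st$z <- ifelse(st$sd > 0, (st$mean - st$truth) / st$sd,
                 ifelse(st$mean == st$truth, 0, Inf))
  st$identifiable <- st$parameter %in% bundle$identifiable
  st <- st[, c("parameter", "truth", "mean", "sd", "cv", "z", "identifiable")]
  ident <- st[st$identifiable, ]
  list(ensemble = ensemble, chains = chains, stats = tibble::as_tibble(st),
       frac_identifiable_z2 = mean(abs(ident$z) <= 2))
}
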