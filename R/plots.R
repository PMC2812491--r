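# ggplot2 methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.kin_trajectory <- function(object, species = NULL, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_hr",
                            names_to = "species", values_to = "concentration")
  if (!is.null(species)) df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_hr, .data$concentration,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (A.U.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kin_ossc <- function(object, top = 20L, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$rank))
  df <- utils::head(df, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(.data$ossc, .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "OSSC", y = NULL,
                  title = paste0("Most fragile interactions (",
                                 attr(object, "clone"), ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kin_robustness <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$perturbation <- factor(df$factor, levels = c(10, 0.1, 0),
                            labels = c("knock-in", "knock-down", "knock-out"))
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$marker,
                                   fill = log2(.data$f_mean))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~perturbation) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, name = "log2 f") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.kin_synergy <- function(object, type = "species", ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$type == type, ]
  df <- df[order(df$alpha_mean), ]
  df$quantity <- factor(df$quantity, levels = df$quantity)
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha_mean, .data$quantity,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "darkgreen",
                                            negative = "red", none = "grey60")) +
    ggplot2::labs(x = "synergy coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Ensemble mean and standard-deviation band for selected species
#'
#' Integrates the protocol for every requested ensemble member from its own
#' approximate steady state and plots the ensemble mean with a one-sd band
#' (the figure convention used for trajectory predictions).
#'
#' @param net a [kin_network()].
#' @param ensemble a `kin_ensemble`.
#' @param protocol a [kin_protocol()].
#' @param species species ids to show.
#' @param clone clone label; `clones` the clone table.
#' @param members member indices; default all.
#' @param ss_control settings for [find_steady_state()].
#' @return a ggplot; the plotted tibble is in `attr(, "data")`.
#' @export
plot_ensemble_trajectories <- function(net, ensemble, protocol, species,
                                       clone, clones, members = NULL,
                                       ss_control = list()) {
  ss_control <- utils::modifyList(list(window_hr = 10, tol = 0.01, max_windows = 200),
                                  ss_control)
  if (is.null(members)) members <- seq_len(ensemble_size(ensemble))
  runs <- lapply(members, function(i) {
    p <- apply_clone(ensemble_member(ensemble, i), clone, clones)
    ss <- find_steady_state(net, p, window_hr = ss_control$window_hr,
                            tol = ss_control$tol, max_windows = ss_control$max_windows)
    traj <- integrate_network(net, p, protocol, x0 = ss$state)
    df <- tidyr::pivot_longer(tibble::as_tibble(traj)[, c("time_hr", species)],
                              -"time_hr", names_to = "species", values_to = "value")
    df$member <- i
    df
  })
  df <- dplyr::bind_rows(runs)
  band <- dplyr::summarise(dplyr::group_by(df, .data$time_hr, .data$species),
                           mean = mean(.data$value), sd = stats::sd(.data$value),
                           .groups = "drop")
  gg <- ggplot2::ggplot(band, ggplot2::aes(.data$time_hr, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (A.U.)",
                  subtitle = paste0(clone, " clone: ensemble mean ± 1 sd")) +
    ggplot2::theme_minimal()
  attr(gg, "data") <- band
  gg
}
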