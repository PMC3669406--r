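#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang %||% .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a corona system into a per-species tibble
#'
#' @param x A [corona_system()].
#' @param ... Unused.
#' @return A tibble with the species table plus the derived equilibrium
#'   constant `K = ka/kd` (`NA` where `kd = 0`), the site capacity
#'   `cap = n * N0` (M), and `N0`.
#' @export
tidy.corona_system <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$K <- ifelse(out$kd > 0, out$ka / out$kd, NA_real_)
  out$cap <- site_capacity(x)
  out$N0 <- n0_of(x)
  out
}

#' @export
glance.corona_system <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_species = nrow(x), N0 = n0_of(x)),
    time_scales(x),
    epsilon_separation(x)
  )
}

#' @export
tidy.corona_composition <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$label <- attr(x, "label")
  out
}

#' @export
glance.corona_composition <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"),
    theta = attr(x, "theta"),
    total_coverage = sum(x$f)
  )
}

#' @export
tidy.corona_trajectory <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$model <- attr(x, "model") %||% NA_character_
  out
}

#' @export
glance.corona_trajectory <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model") %||% NA_character_,
    n_times = length(unique(x$time)),
    n_species = length(unique(x$species)),
    t_max = max(x$time),
    final_theta = x$theta[which.max(x$time)][1]
  )
}

#' @export
tidy.corona_sensitivity <- function(x, ...) tibble::as_tibble(x)

#' Plot a corona trajectory
#'
#' Occupied surface fraction of each species against time (log-scaled where
#' the grid spans decades), with the free surface fraction as a dashed
#' line.
#'
#' @param object A `corona_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corona_trajectory <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  tab <- tab[tab$time > 0, , drop = FALSE]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$f,
                                         colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$theta),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "surface fraction",
                  colour = "species",
                  title = paste0("Corona formation (",
                                 attr(object, "model") %||% "model", ")")) +
    ggplot2::theme_minimal()
  if (max(tab$time) / min(tab$time) > 100) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a corona composition as a bar chart
#'
#' @param object A `corona_composition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corona_composition <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$species, y = .data$f)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "surface fraction",
                  title = paste0(attr(object, "label"), " composition")) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Recomputed composition fractions (solid) against the first-order
#' sensitivity prediction (dashed) across the parameter multiplier range.
#'
#' @param object A `corona_sweep` from [sweep_composition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corona_sweep <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$multiplier,
                                    colour = .data$species)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_recomputed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_first_order),
                       linetype = "dashed") +
    ggplot2::labs(
      x = paste0(attr(object, "parameter"), " multiplier (",
                 attr(object, "perturbed_species"), ")"),
      y = "surface fraction",
      title = paste0(attr(object, "target_label"),
                     " composition sweep (solid: exact, dashed: first order)")
    ) +
    ggplot2::theme_minimal()
}
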