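#' @title Local sensitivity of corona compositions
#' @description Relative (logarithmic) sensitivities of the closed-form
#'   metastable and stable compositions to their kinetic parameters, plus
#'   numeric parameter sweeps comparing the first-order prediction with the
#'   recomputed composition.
#' @name sensitivity
NULL

new_sensitivity <- function(system, f, param_label, target_label) {
  m <- nrow(system)
  # own-parameter sensitivity 1 - f_i, cross sensitivity -f_j:
  # relative change of fraction i per relative change of the parameter of j
  S <- diag(m) - matrix(f, nrow = m, ncol = m, byrow = TRUE)
  structure(
    tibble::tibble(
      species = rep(system$name, times = m),
      parameter = rep(paste0(param_label, "_", system$name), each = m),
      sensitivity = as.vector(S)
    ),
    target_label = target_label,
    f = stats::setNames(f, system$name),
    class = c("corona_sensitivity", class(tibble::tibble()))
  )
}

#' @export
print.corona_sensitivity <- function(x, ...) {
  cat(sprintf("<corona_sensitivity: %s composition>\n",
              attr(x, "target_label")))
  print(tidyr::pivot_wider(tibble::as_tibble(x), names_from = "parameter",
                           values_from = "sensitivity"), ...)
  invisible(x)
}

#' Sensitivity of the metastable composition to association rates
#'
#' Differentiating the fast-phase closed form
#' `fbar_i = ka_i c0_i / sum_j ka_j c0_j` gives the relative sensitivities
#' \deqn{\partial \log \bar f_j / \partial \log k_{a,i}
#'       = \delta_{ij} - \bar f_i:}
#' a relative error in `ka_i` inflates species `i`'s own fraction by factor
#' `1 - fbar_i` and deflates every other fraction by factor `fbar_i`. The
#' sensitivities depend only on the fractions themselves.
#'
#' @param system A [corona_system()].
#' @return A `corona_sensitivity` tibble in long form: `species` (the
#'   fraction observed), `parameter` (the rate perturbed), `sensitivity`.
#' @export
metastable_sensitivity <- function(system) {
  assert_system(system)
  comp <- metastable_composition(system)
  new_sensitivity(system, comp$f, "ka", "metastable")
}

#' Sensitivity of the stable composition to equilibrium constants
#'
#' Differentiating the competitive Langmuir form
#' `f_i = K_i c0_i / (1 + sum_j K_j c0_j)` gives
#' \deqn{\partial \log f_j / \partial \log K_i = \delta_{ij} - f_i,}
#' and the free surface fraction responds with relative sensitivity `-f_i`.
#' A species holding 90% of the surface is thus nearly insensitive to its
#' own equilibrium constant (factor 0.1), while errors in a dominant
#' species' constant propagate to every minor fraction at full strength.
#'
#' @param system A [corona_system()]; all `kd > 0`.
#' @return A `corona_sensitivity` tibble (long form, as
#'   [metastable_sensitivity()]).
#' @export
stable_sensitivity <- function(system) {
  assert_system(system)
  comp <- stable_composition(system)
  new_sensitivity(system, comp$f, "K", "stable")
}

#' Parameter sweep of a closed-form corona composition
#'
#' Recomputes the metastable or stable composition while one kinetic
#' parameter of one species is scaled across `[1 - relative_range,
#' 1 + relative_range]`, and tabulates alongside the first-order prediction
#' from the analytic sensitivity. Useful for judging how far the local
#' sensitivities remain a faithful picture of parameter uncertainty.
#'
#' @param system A [corona_system()].
#' @param species Name of the species whose parameter is perturbed.
#' @param parameter One of `"ka"`, `"kd"`, `"K"`, `"c0"`. For the metastable
#'   target only `ka` and `c0` act (they enter as a product); `K` perturbs
#'   `ka` at fixed `kd` for the stable target.
#' @param relative_range Half-width of the multiplier range, in `(0, 1]`.
#' @param n_points Number of multipliers (>= 3).
#' @param target `"metastable"` or `"stable"`.
#' @return A tibble of class `corona_sweep` with columns `multiplier`,
#'   `species`, `f_recomputed`, `f_first_order`.
#' @export
sweep_composition <- function(system, species, parameter = c("ka", "kd", "K", "c0"),
                              relative_range = 0.5, n_points = 21,
                              target = c("metastable", "stable")) {
  assert_system(system)
  parameter <- match.arg(parameter)
  target <- match.arg(target)
  stopifnot(relative_range > 0, relative_range <= 1, n_points >= 3)
  idx <- match(species, system$name)
  if (is.na(idx)) {
    stop("Unknown species '", species, "'.", call. = FALSE)
  }
  compose <- switch(target,
    metastable = metastable_composition,
    stable = stable_composition
  )
  if (target == "metastable" && parameter %in% c("kd", "K")) {
    stop("The metastable composition does not depend on '", parameter,
         "'; sweep ka or c0 instead.", call. = FALSE)
  }
  base <- compose(system)
  sens <- switch(target,
    metastable = metastable_sensitivity(system),
    stable = stable_sensitivity(system)
  )
  # column of the perturbed species: own/cross structure delta_ij - f_idx
  prefix <- if (target == "metastable") "ka" else "K"
  scol <- sens$sensitivity[sens$parameter == paste0(prefix, "_", species)]
  # kd enters the stable composition only through K = ka/kd: flipped sign
  if (target == "stable" && parameter == "kd") scol <- -scol

  multipliers <- seq(1 - relative_range, 1 + relative_range,
                     length.out = n_points)
  rows <- purrr::map(multipliers, function(mult) {
    pert <- tibble::as_tibble(system)
    if (parameter == "K") {
      # perturb K at fixed kd by scaling ka
      pert$ka[idx] <- pert$ka[idx] * mult
    } else {
      pert[[parameter]][idx] <- pert[[parameter]][idx] * mult
    }
    psys <- corona_system(pert, n0_of(system))
    comp <- compose(psys)
    tibble::tibble(
      multiplier = mult,
      species = comp$species,
      f_recomputed = comp$f,
      f_first_order = base$f * (1 + scol * (mult - 1))
    )
  })
  structure(dplyr::bind_rows(rows),
            target_label = target, parameter = parameter,
            perturbed_species = species,
            class = c("corona_sweep", class(tibble::tibble())))
}
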