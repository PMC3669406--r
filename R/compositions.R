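#' @title Static corona compositions
#' @description Closed-form metastable (fast-phase) and stable (equilibrium)
#'   corona compositions, an exact depletion-aware equilibrium solver, and
#'   the two characteristic time scales of corona formation.
#' @name compositions
NULL

new_composition <- function(system, f, theta, label) {
  structure(
    tibble::tibble(
      species = system$name,
      f = f,
      x = f * site_capacity(system)
    ),
    theta = theta,
    label = label,
    class = c("corona_composition", class(tibble::tibble()))
  )
}

#' @export
print.corona_composition <- function(x, ...) {
  cat(sprintf("<corona_composition: %s> free surface fraction theta = %.6g\n",
              attr(x, "label"), attr(x, "theta")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Metastable corona composition (fast-phase closed form)
#'
#' During the fast phase proteins race to cover the bare nanoparticle
#' surface; dissociation is too slow to matter. Species `i` recruits surface
#' at rate proportional to `ka_i * c0_i`, so when the surface fills the
#' occupied fractions are
#' \deqn{\bar f_i = k_{a,i} c_{i0} / \sum_j k_{a,j} c_{j0},}
#' independent of the coverage numbers `n_i` and of `N0`. The corresponding
#' bound concentrations are `x_i = n_i N0 \bar f_i` and the free surface
#' fraction is exactly zero.
#'
#' The formula assumes protein excess (enough of each species in solution to
#' fill its share of the surface); [validate_corona()] flags panels where
#' this fails, and the empirical fast-phase composition from
#' [two_phase_summary()] is the recommended fallback there.
#'
#' @param system A [corona_system()].
#' @return A `corona_composition` (label `"metastable"`).
#' @export
metastable_composition <- function(system) {
  assert_system(system)
  rates <- system$ka * system$c0
  total <- sum(rates)
  if (total <= 0) {
    stop("Metastable composition undefined: all ka * c0 are zero.",
         call. = FALSE)
  }
  new_composition(system, f = rates / total, theta = 0, label = "metastable")
}

#' Stable corona composition (competitive Langmuir closed form)
#'
#' The long-run equilibrium reached once association and dissociation
#' balance. Neglecting protein depletion (free concentration ~ `c0`), the
#' stationary occupied fractions follow the competitive Langmuir isotherm
#' \deqn{f_i = K_i c_{i0} / (1 + \sum_j K_j c_{j0}), \quad
#'       \theta = 1 / (1 + \sum_j K_j c_{j0}),}
#' with equilibrium constants `K_i = ka_i / kd_i`. Fractions are independent
#' of `n_i` and `N0`. All species must have `kd > 0`.
#'
#' @param system A [corona_system()].
#' @return A `corona_composition` (label `"stable_approx"`).
#' @export
stable_composition <- function(system) {
  assert_system(system)
  zero_kd <- system$name[system$kd <= 0]
  if (length(zero_kd) > 0) {
    stop("Stable composition undefined: kd = 0 for species ",
         paste0("'", zero_kd, "'", collapse = ", "),
         " (equilibrium constant undefined).", call. = FALSE)
  }
  Kc <- (system$ka / system$kd) * system$c0
  denom <- 1 + sum(Kc)
  new_composition(system, f = Kc / denom, theta = 1 / denom,
                  label = "stable_approx")
}

#' Exact equilibrium composition with protein depletion
#'
#' Solves the full stationary equations
#' `ka_i (c0_i - x_i) n_i N0 theta = kd_i x_i` with
#' `theta = 1 - sum_j x_j / (n_j N0)`, i.e. the equilibrium of the dynamical
#' model without the protein-excess approximation of
#' [stable_composition()]. For a given `theta` each species' balance has the
#' scalar solution
#' `x_i(theta) = c0_i * n_i N0 K_i theta / (1 + n_i N0 K_i theta)`;
#' substituting into the coverage identity leaves one strictly monotone
#' scalar equation in `theta`, solved by bracketed root finding on
#' `log(theta)` and polished with Newton steps.
#'
#' @param system A [corona_system()]; all species need `kd > 0`.
#' @param tol Relative residual tolerance on each species' balance equation.
#' @param max_iter Iteration cap for the scalar solve.
#' @return A `corona_composition` (label `"stable_exact"`).
#' @export
stable_composition_exact <- function(system, tol = 1e-12, max_iter = 1e5) {
  assert_system(system)
  zero_kd <- system$name[system$kd <= 0]
  if (length(zero_kd) > 0) {
    stop("Exact stable composition undefined: kd = 0 for species ",
         paste0("'", zero_kd, "'", collapse = ", "), ".", call. = FALSE)
  }
  N0 <- n0_of(system)
  cap <- site_capacity(system)
  K <- system$ka / system$kd
  a <- cap * K # n_i N0 K_i, dimensionless against theta

  x_of_theta <- function(theta) system$c0 * a * theta / (1 + a * theta)
  # residual of the coverage identity; strictly increasing in theta
  g <- function(theta) theta - 1 + sum(x_of_theta(theta) / cap)

  # bisection on log10(theta): g(10^-300) ~ -1 < 0 and g(1) > 0 always,
  # and g is strictly increasing, so the bracket is guaranteed
  lo <- -300; hi <- 0
  it <- 0
  while (hi - lo > 1e-13 && it < max_iter) {
    mid <- (lo + hi) / 2
    if (g(10^mid) > 0) hi <- mid else lo <- mid
    it <- it + 1
  }
  theta_star <- 10^((lo + hi) / 2)
  # Newton polish in linear scale
  for (k in 1:8) {
    gp <- 1 + sum(system$c0 * a / (cap * (1 + a * theta_star)^2))
    step <- g(theta_star) / gp
    theta_new <- theta_star - step
    if (!is.finite(theta_new) || theta_new <= 0) break
    theta_star <- theta_new
    if (abs(step) <= 1e-16 * theta_star) break
  }

  x <- x_of_theta(theta_star)
  # relative residual check on each balance equation
  lhs <- system$ka * (system$c0 - x) * cap * theta_star
  rhs <- system$kd * x
  scale <- pmax(abs(lhs), abs(rhs), system$kd * system$c0 * .Machine$double.xmin)
  rel <- ifelse(scale > 0, abs(lhs - rhs) / scale, 0)
  if (any(rel > max(tol, 1e-10))) {
    stop("Exact equilibrium solve did not converge (max relative residual ",
         format(max(rel), digits = 3), ").", call. = FALSE)
  }
  new_composition(system, f = x / cap, theta = 1 - sum(x / cap),
                  label = "stable_exact")
}

#' Characteristic time scales of corona formation
#'
#' The fast (surface-filling) phase has time constant
#' `tau_fast = 1 / sum_j ka_j c0_j`; the slow protein-exchange phase relaxes
#' no faster than the smallest dissociation rate, giving the lower bound
#' `tau_slow_lower_bound = 1 / min(kd_i > 0)` (infinite when no species
#' dissociates).
#'
#' @param system A [corona_system()].
#' @return A tibble with columns `tau_fast` and `tau_slow_lower_bound` (s).
#' @export
time_scales <- function(system) {
  assert_system(system)
  total <- sum(system$ka * system$c0)
  if (total <= 0) {
    stop("tau_fast undefined: all ka * c0 are zero.", call. = FALSE)
  }
  kd_pos <- system$kd[system$kd > 0]
  tibble::tibble(
    tau_fast = 1 / total,
    tau_slow_lower_bound = if (length(kd_pos) == 0) Inf else 1 / min(kd_pos)
  )
}
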