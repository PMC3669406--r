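#' Quasi-steady free surface fraction
#'
#' On the slow manifold the total coverage `s = sum_i f_i` is in
#' quasi-equilibrium: association onto the residual free surface balances
#' total dissociation. Setting the sum of the fraction derivatives of the
#' full model to zero gives
#' \deqn{\theta^* = \frac{\sum_j k_{d,j} x_j / (n_j N_0)}
#'                       {\sum_j k_{a,j} (c_{j0} - x_j)}.}
#' This is the free surface fraction the fast dynamics would relax to for
#' the current bound state `x`.
#'
#' @param x Bound concentrations (M), one per species.
#' @param system A [corona_system()].
#' @return The quasi-steady free surface fraction (dimensionless scalar).
#' @export
theta_quasi_steady <- function(x, system) {
  assert_system(system)
  check_state_dim(x, system)
  denom <- sum(system$ka * (system$c0 - x))
  if (denom <= 0) {
    stop("Slow manifold undefined: all free protein exhausted ",
         "(sum ka * (c0 - x) <= 0).", call. = FALSE)
  }
  sum(system$kd * x / site_capacity(system)) / denom
}

#' Right-hand side of the reduced (slow) corona model
#'
#' The full model's fast variable (total coverage) is eliminated by
#' substituting the quasi-steady free surface fraction
#' [theta_quasi_steady()] into the mass-action rate law:
#' \deqn{dx_i/dt = k_{a,i}(c_{i0} - x_i)\, n_i N_0\, \theta^* - k_{d,i} x_i.}
#' All remaining terms are of the order of the dissociation rates, so the
#' system is non-stiff on the slow time scale. By construction
#' `sum_i (1/(n_i N0)) dx_i/dt = 0` exactly: total coverage is conserved on
#' the slow manifold and only the composition evolves.
#'
#' @inheritParams theta_quasi_steady
#' @return Numeric vector of time derivatives (M/s).
#' @export
reduced_rhs <- function(x, system) {
  theta_star <- theta_quasi_steady(x, system)
  system$ka * (system$c0 - x) * site_capacity(system) * theta_star -
    system$kd * x
}

#' Simulate the reduced (slow-phase) corona model
#'
#' Integrates [reduced_rhs()] starting from the closed-form metastable
#' composition, reproducing the slow protein-exchange phase without
#' resolving the fast surface-filling transient. Converges to the same
#' equilibrium as the full model.
#'
#' @param system A [corona_system()]; all species need `kd > 0` (without
#'   dissociation the slow dynamics are trivial).
#' @param times Output times (s); defaults to a geometric grid over the slow
#'   phase.
#' @param settings A [solver_settings()]. The reduced system tolerates
#'   non-stiff explicit integration (`stiff = FALSE`) with steps of the
#'   order of the dissociation times; the default keeps lsoda for long
#'   horizons where the dissociation rates themselves span decades.
#' @return A `corona_trajectory` (metadata `model = "reduced"`). Because the
#'   fast variable is eliminated, `theta` is reported as the quasi-steady
#'   value and `f` sums to 1 up to solver drift.
#' @export
simulate_reduced <- function(system, times = NULL,
                             settings = solver_settings(rel_tol = 1e-10,
                                                        abs_tol = 1e-18)) {
  assert_system(system)
  if (any(system$kd <= 0)) {
    stop("Reduced model requires kd > 0 for every species.", call. = FALSE)
  }
  if (is.null(times)) {
    ts <- time_scales(system)
    times <- c(0, exp(seq(log(ts$tau_slow_lower_bound / 1e3),
                          log(100 * ts$tau_slow_lower_bound),
                          length.out = 150)))
  }
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  x0 <- metastable_composition(system)$x
  xmat <- integrate_model(system, times, x0, settings, reduced_rhs, NULL,
                          "Reduced model")
  traj <- new_trajectory(times, xmat, system, "reduced", settings)
  # on the slow manifold theta is the quasi-steady value, not 1 - sum f
  theta_star <- apply(xmat, 1, theta_quasi_steady, system = system)
  traj$theta <- rep(theta_star, each = nrow(system))
  traj
}

#' Time-scale separation parameter
#'
#' The singular-perturbation reduction is valid when dissociation is much
#' slower than surface filling. The separation parameter is
#' `epsilon = max_i kd_i / sum_j ka_j c0_j`, the ratio of the fastest slow
#' rate to the fast-phase rate.
#'
#' @param system A [corona_system()].
#' @return A tibble with columns `epsilon` and `reduction_valid` (`FALSE`
#'   when `epsilon > 0.01`, flagging that the fast/slow split is dubious).
#' @export
epsilon_separation <- function(system) {
  assert_system(system)
  total <- sum(system$ka * system$c0)
  if (total <= 0) stop("epsilon undefined: all ka * c0 are zero.",
                       call. = FALSE)
  eps <- max(system$kd) / total
  tibble::tibble(epsilon = eps, reduction_valid = eps <= 0.01)
}
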