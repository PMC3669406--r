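#' Solver settings for corona dynamics
#'
#' @param rel_tol Relative integration tolerance (dimensionless). The fast
#'   and slow phases can be separated by many orders of magnitude and the
#'   free surface fraction is a near-cancelling difference of the states,
#'   so the default is tight: resolving theta to the package's 1e-9
#'   fraction tolerance requires a relative state accuracy well below that.
#' @param abs_tol Absolute tolerance on bound concentrations (M). Must
#'   resolve free surface fractions far below typical occupied fractions.
#' @param max_step Maximum internal step (s); `Inf` leaves it to the solver.
#' @param stiff Use a stiff-capable integrator (lsoda; default `TRUE`).
#'   `FALSE` requests a non-stiff Adams method, appropriate only for the
#'   reduced slow model.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-10, abs_tol = 1e-16,
                            max_step = Inf, stiff = TRUE) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_step > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, stiff = isTRUE(stiff)),
            class = "solver_settings")
}

#' Right-hand side of the corona formation ODE system
#'
#' The mass-action model for competitive adsorption onto a shared surface:
#' \deqn{dx_i/dt = k_{a,i} (c_{i0} - x_i) \, n_i N_0 \, \theta
#'       - k_{d,i} x_i,}
#' where `x_i` is the bound concentration of species `i`,
#' `c0_i - x_i` its free concentration (conservation of molecules),
#' `n_i N0 theta` the concentration of surface sites still available, and
#' `theta = 1 - sum_j x_j / (n_j N0)` the free surface fraction. Small
#' negative entries of `x` (solver round-off) are clipped to zero before
#' evaluation.
#'
#' @param x Bound concentrations (M), one per species.
#' @param system A [corona_system()].
#' @return Numeric vector of time derivatives `dx/dt` (M/s).
#' @export
corona_rhs <- function(x, system) {
  assert_system(system)
  check_state_dim(x, system)
  x <- pmax(x, 0)
  cap <- site_capacity(system)
  theta <- 1 - sum(x / cap)
  system$ka * (system$c0 - x) * cap * theta - system$kd * x
}

# analytic Jacobian of corona_rhs; speeds up the stiff solver considerably
corona_jac <- function(x, system) {
  x <- pmax(x, 0)
  cap <- site_capacity(system)
  theta <- 1 - sum(x / cap)
  m <- nrow(system)
  # d rhs_i / d x_j = -ka_i (c0_i - x_i) cap_i / cap_j
  #                   + delta_ij * (-ka_i cap_i theta - kd_i)
  J <- outer(-system$ka * (system$c0 - x) * cap, 1 / cap)
  diag(J) <- diag(J) - system$ka * cap * theta - system$kd
  J
}

new_trajectory <- function(times, xmat, system, model, settings,
                           seed = NA_integer_) {
  cap <- site_capacity(system)
  fmat <- sweep(xmat, 2, cap, "/")
  theta <- 1 - rowSums(fmat)
  out <- tibble::tibble(
    time = rep(times, each = nrow(system)),
    species = rep(system$name, times = length(times)),
    x = as.vector(t(xmat)),
    f = as.vector(t(fmat)),
    theta = rep(theta, each = nrow(system))
  )
  structure(out,
    class = c("corona_trajectory", class(tibble::tibble())),
    model = model,
    settings = settings,
    seed = seed,
    panel_hash = rlang::hash(list(tibble::as_tibble(system), n0_of(system)))
  )
}

#' @export
print.corona_trajectory <- function(x, ...) {
  cat(sprintf("<corona_trajectory: %s> %d times x %d species\n",
              attr(x, "model"), length(unique(x$time)),
              length(unique(x$species))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# geometric default grid covering both phases
default_time_grid <- function(system, n_points = 200) {
  ts <- time_scales(system)
  t_lo <- ts$tau_fast / 100
  t_hi <- if (is.finite(ts$tau_slow_lower_bound)) {
    100 * ts$tau_slow_lower_bound
  } else {
    100 * ts$tau_fast
  }
  c(0, exp(seq(log(t_lo), log(t_hi), length.out = n_points)))
}

# shared deSolve driver for the full and reduced models
integrate_model <- function(system, times, x0, settings, rhs_fun, jac_fun,
                            model_label) {
  m <- nrow(system)
  deriv <- function(t, x, parms) list(rhs_fun(x, system))
  method <- if (settings$stiff) "lsoda" else "adams"
  use_jac <- settings$stiff && !is.null(jac_fun)
  jac <- if (use_jac) function(t, x, parms) jac_fun(x, system) else NULL
  sol <- deSolve::ode(
    y = x0, times = times, func = deriv, parms = NULL,
    method = method, jacfunc = jac,
    jactype = if (use_jac) "fullusr" else "fullint",
    rtol = settings$rel_tol, atol = settings$abs_tol,
    hmax = if (is.finite(settings$max_step)) settings$max_step else NULL,
    maxsteps = 200000
  )
  if (nrow(sol) < length(times)) {
    stop(model_label, " integration failed at t = ",
         format(sol[nrow(sol), 1], digits = 6), " s.", call. = FALSE)
  }
  matrix(sol[, -1, drop = FALSE], nrow = length(times), ncol = m)
}

#' Simulate the full corona formation dynamics
#'
#' Integrates the mass-action ODE system of [corona_rhs()] with a
#' stiff-capable solver. The dynamics exhibit two phases: a fast
#' association-dominated phase (time scale `tau_fast = 1/sum(ka*c0)`) during
#' which proteins race to cover the bare surface, then a slow exchange phase
#' (time scale of order `1/kd`) during which weakly bound species are
#' displaced by high-affinity ones.
#'
#' @param system A [corona_system()].
#' @param times Strictly increasing output times (s), first entry >= 0.
#'   Defaults to a geometric grid spanning both phases.
#' @param settings A [solver_settings()].
#' @param x0 Initial bound concentrations (M); default all zero (bare
#'   particles).
#' @return A `corona_trajectory` tibble with columns `time`, `species`, `x`
#'   (bound concentration, M), `f` (occupied surface fraction), `theta`
#'   (free surface fraction, shared across species at each time).
#' @export
simulate_corona <- function(system, times = NULL,
                            settings = solver_settings(), x0 = NULL) {
  assert_system(system)
  if (is.null(times)) times <- default_time_grid(system)
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  m <- nrow(system)
  if (is.null(x0)) x0 <- rep(0, m)
  check_state_dim(x0, system)
  xmat <- integrate_model(system, times, x0, settings, corona_rhs,
                          corona_jac, "Full model")
  check_trajectory_invariants(xmat, system)
  new_trajectory(times, xmat, system, "full", settings)
}

check_trajectory_invariants <- function(xmat, system) {
  tol <- fraction_tol()
  cap <- site_capacity(system)
  fmat <- sweep(pmax(xmat, 0), 2, cap, "/")
  cover <- rowSums(fmat)
  worst <- max(c(-(xmat) / pmax(system$c0, .Machine$double.xmin)[col(xmat)],
                 cover - 1,
                 sweep(xmat, 2, system$c0, "-") /
                   pmax(system$c0, .Machine$double.xmin)[col(xmat)]))
  if (worst > 10 * tol) {
    stop("Trajectory breaches state invariants by ",
         format(worst, digits = 3), " (> 10x tolerance).", call. = FALSE)
  }
  invisible(TRUE)
}

#' Two-phase summary of a corona trajectory
#'
#' Locates the end of the fast phase (first time the free surface fraction
#' drops below 0.01, i.e. 99% coverage) and reports the empirical corona
#' composition there (the observed metastable state) and at the final time
#' (the observed long-run state).
#'
#' @param traj A `corona_trajectory` from [simulate_corona()].
#' @param system The [corona_system()] that produced it.
#' @return A list of class `corona_two_phase` with elements
#'   `fast_phase_complete` (logical), `t99` (s; `NA` if coverage never
#'   reaches 99%), `metastable` and `final` (`corona_composition`s; the
#'   metastable one is `NULL` when the fast phase is incomplete).
#' @export
two_phase_summary <- function(traj, system) {
  assert_system(system)
  wide <- tidyr::pivot_wider(tibble::as_tibble(traj),
                             id_cols = c("time", "theta"),
                             names_from = "species", values_from = "f")
  fcols <- as.matrix(wide[system$name])
  idx <- which(wide$theta < 0.01)
  if (length(idx) == 0) {
    out <- list(fast_phase_complete = FALSE, t99 = NA_real_,
                metastable = NULL,
                final = new_composition(system, fcols[nrow(fcols), ],
                                        wide$theta[nrow(wide)],
                                        "stable_empirical"))
    return(structure(out, class = "corona_two_phase"))
  }
  k <- idx[1]
  t99 <- if (k == 1) wide$time[1] else {
    # log-linear interpolation of theta between the bracketing grid points
    t0 <- wide$time[k - 1]; t1 <- wide$time[k]
    th0 <- wide$theta[k - 1]; th1 <- wide$theta[k]
    if (th0 > 0.01 && th1 > 0 && th0 > th1) {
      t0 + (t1 - t0) * (log(th0) - log(0.01)) / (log(th0) - log(max(th1, 1e-300)))
    } else {
      t1
    }
  }
  structure(list(
    fast_phase_complete = TRUE,
    t99 = t99,
    metastable = new_composition(system, fcols[k, ], wide$theta[k],
                                 "metastable_empirical"),
    final = new_composition(system, fcols[nrow(fcols), ],
                            wide$theta[nrow(wide)], "stable_empirical")
  ), class = "corona_two_phase")
}

#' @export
print.corona_two_phase <- function(x, ...) {
  if (!x$fast_phase_complete) {
    cat("<corona_two_phase> fast phase incomplete (coverage never reached 99%)\n")
  } else {
    cat(sprintf("<corona_two_phase> 99%% coverage at t = %.4g s\n", x$t99))
    cat("Empirical metastable composition:\n")
    print(x$metastable, ...)
  }
  cat("Final composition:\n")
  print(x$final, ...)
  invisible(x)
}
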