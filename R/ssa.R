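#' Particle-resolved stochastic simulation of corona formation
#'
#' Exact Gillespie-type simulation of the adsorption/desorption biochemistry
#' at the resolution of individual nanoparticles and protein molecules,
#' used as an independent oracle for the mean-field ODE model
#' ([simulate_corona()]). Each particle `p` carries a continuous free
#' surface fraction `theta_p`; binding of species `i` onto particle `p`
#' occurs with propensity `ka_i * c_free_i * n_i * theta_p` and consumes a
#' random surface increment with mean `1/n_i`; unbinding occurs at `kd_i`
#' per bound molecule and restores the increment recorded at binding, so
#' each particle's surface bookkeeping is exact. Molecule counts are linked
#' to molar concentrations through `volume_scale` (count = M *
#' `volume_scale`), which defaults to `n_particles / N0` so that the
#' simulated particle ensemble is consistent with the panel's nanoparticle
#' concentration.
#'
#' @param system A [corona_system()].
#' @param n_particles Number of nanoparticles to track (>= 1).
#' @param t_max Final time (s).
#' @param times Output times; default 50 geometric points over
#'   `[t_max/1000, t_max]`.
#' @param seed Integer seed; identical seeds and settings give bit-identical
#'   event sequences.
#' @param replicates Number of independent replicate runs.
#' @param increment_model `"deterministic"` (every binding consumes exactly
#'   `1/n_i` of the surface) or `"uniform"` (increment uniform on
#'   `[0, 2/n_i]`, same mean). The mean-field limit holds under both.
#' @param volume_scale Counts per molar; default `n_particles / N0`.
#' @param max_events Guard on the total event count per replicate.
#'
#' @return A list of class `corona_ssa` with elements `trajectory` (a
#'   `corona_trajectory`-style tibble with columns `time`, `species`, `x`,
#'   `f`, `theta`, `replicate`, `seed`; `x` is the count-based bound
#'   concentration while `f` is the ensemble-mean surface fraction actually
#'   occupied, i.e. the sum of the per-binding surface increments -- the two
#'   agree except for increment clipping near full coverage) and `ensemble`
#'   (final
#'   `corona_ensemble` of the last replicate: per-particle free surface
#'   fractions and bound counts).
#' @export
ssa_simulate <- function(system, n_particles = 500, t_max,
                         times = NULL, seed = 1, replicates = 1,
                         increment_model = c("deterministic", "uniform"),
                         volume_scale = NULL, max_events = 5e7) {
  assert_system(system)
  increment_model <- match.arg(increment_model)
  stopifnot(n_particles >= 1, t_max > 0, replicates >= 1)
  N0 <- n0_of(system)
  if (is.null(volume_scale)) volume_scale <- n_particles / N0
  counts <- floor(system$c0 * volume_scale + 0.5)
  if (any(counts < 1)) {
    stop("volume_scale too small: species ",
         paste0("'", system$name[counts < 1], "'", collapse = ", "),
         " would have fewer than one molecule.", call. = FALSE)
  }
  if (is.null(times)) {
    times <- exp(seq(log(t_max / 1000), log(t_max), length.out = 50))
  }
  stopifnot(all(diff(times) > 0), all(times > 0))

  cap <- site_capacity(system)
  set.seed(seed)
  runs <- vector("list", replicates)
  ens <- NULL
  for (r in seq_len(replicates)) {
    res <- ssa_run_cpp(system$ka, system$kd, system$n, system$c0, N0,
                       as.integer(n_particles), volume_scale, times,
                       if (increment_model == "deterministic") 0L else 1L,
                       max_events)
    xmat <- res$x
    # f is the surface actually occupied (sum of per-binding increments),
    # exact by bookkeeping; x/(n*N0) differs from it only through increment
    # clipping near full coverage
    fmat <- res$f
    runs[[r]] <- tibble::tibble(
      time = rep(times, each = nrow(system)),
      species = rep(system$name, times = length(times)),
      x = as.vector(t(xmat)),
      f = as.vector(t(fmat)),
      theta = rep(res$theta_bar, each = nrow(system)),
      replicate = r,
      seed = seed
    )
    ens <- res
  }
  trajectory <- structure(dplyr::bind_rows(runs),
    class = c("corona_trajectory", class(tibble::tibble())),
    model = "ssa", seed = seed,
    panel_hash = rlang::hash(list(tibble::as_tibble(system), N0))
  )
  ensemble <- structure(list(
    theta_p = ens$theta_p,
    bound_counts = ens$bound_counts, # species x particle
    free_counts = stats::setNames(as.numeric(ens$free_counts), system$name),
    species = system$name,
    n = system$n,
    volume_scale = volume_scale,
    N0 = N0,
    n_events = ens$n_events,
    ended_early = isTRUE(ens$ended_early)
  ), class = "corona_ensemble")
  structure(list(trajectory = trajectory, ensemble = ensemble),
            class = "corona_ssa")
}

#' @export
print.corona_ssa <- function(x, ...) {
  cat(sprintf("<corona_ssa> %d particles, %d replicate(s), %.0f events (last run)%s\n",
              length(x$ensemble$theta_p),
              max(x$trajectory$replicate),
              x$ensemble$n_events,
              if (x$ensemble$ended_early) ", ended early (zero propensity)" else ""))
  invisible(x)
}

#' Distribution of per-particle free surface fractions
#'
#' Histograms the free surface fraction `theta_p` across the particle
#' ensemble. The mean of this distribution is the ensemble free surface
#' fraction that the mean-field ODE tracks as `theta`.
#'
#' @param ensemble A `corona_ensemble` from [ssa_simulate()].
#' @param bins Number of equal-width bins on `[0, 1]`.
#' @return A tibble with columns `mid` (bin midpoint), `density`
#'   (normalised so the histogram integrates to 1), and `count`; the
#'   ensemble mean is attached as attribute `mean_theta`.
#' @export
occupancy_histogram <- function(ensemble, bins = 20) {
  stopifnot(inherits(ensemble, "corona_ensemble"), bins >= 1)
  th <- ensemble$theta_p
  if (length(th) == 0) stop("Empty ensemble.", call. = FALSE)
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(th, breaks, rightmost.closed = TRUE), 1), bins)
  counts <- tabulate(idx, nbins = bins)
  width <- 1 / bins
  structure(tibble::tibble(
    mid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
    count = counts,
    density = counts / (sum(counts) * width)
  ), mean_theta = mean(th))
}
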