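#' Sampling ranges for synthetic protein panels
#'
#' Log-uniform sampling bounds for the kinetic and coverage parameters of a
#' synthetic panel. The defaults span serum-plausible magnitudes:
#' association rates of 1e3--1e7 M^-1 s^-1, dissociation rates of
#' 1e-6--1e-3 s^-1 (hard-corona residence times of minutes to days),
#' coverage numbers of 10--1000 molecules per particle, protein
#' concentrations of 0.1 uM -- 1 mM, and a fixed nanoparticle concentration
#' of 1 nM. These ranges are engineering defaults for exercising the model
#' across regimes, not measurements of any particular protein.
#'
#' @param ka,kd,n,c0 Length-2 numeric vectors `c(low, high)` of positive
#'   bounds (log-uniform sampling; collapse to a point by `low == high`).
#' @param N0 Nanoparticle concentration (M), fixed.
#' @param m Number of species per panel.
#' @return A list of class `panel_ranges`.
#' @export
panel_ranges <- function(ka = c(1e3, 1e7), kd = c(1e-6, 1e-3),
                         n = c(10, 1000), c0 = c(1e-7, 1e-3),
                         N0 = 1e-9, m = 3) {
  for (b in list(ka = ka, kd = kd, n = n, c0 = c0)) {
    stopifnot(length(b) == 2, all(b > 0), b[1] <= b[2])
  }
  stopifnot(N0 > 0, m >= 1)
  structure(list(ka = ka, kd = kd, n = n, c0 = c0, N0 = N0, m = as.integer(m)),
            class = "panel_ranges")
}

log_uniform <- function(k, bounds) {
  if (bounds[1] == bounds[2]) return(rep(bounds[1], k))
  exp(stats::runif(k, log(bounds[1]), log(bounds[2])))
}

#' Generate a seeded synthetic protein panel
#'
#' Draws each species' parameters log-uniformly from `ranges` and reports
#' the regime diagnostics tests and users select on: the time-scale
#' separation parameter `epsilon` and the protein-excess factor
#' `min_i c0_i / (n_i N0)` (how many surface-fuls of each protein the fluid
#' holds).
#'
#' @param ranges A [panel_ranges()].
#' @param seed Integer seed; the same seed always yields the same panel.
#' @return A [corona_system()] with attributes `epsilon` and
#'   `excess_factor`.
#' @export
generate_panel <- function(ranges = panel_ranges(), seed = 1) {
  stopifnot(inherits(ranges, "panel_ranges"))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
    code
  }
  species <- withr_seed(tibble::tibble(
    name = paste0("P", seq_len(ranges$m)),
    ka = log_uniform(ranges$m, ranges$ka),
    kd = log_uniform(ranges$m, ranges$kd),
    n = log_uniform(ranges$m, ranges$n),
    c0 = log_uniform(ranges$m, ranges$c0)
  ))
  sys <- corona_system(species, ranges$N0)
  attr(sys, "epsilon") <- epsilon_separation(sys)$epsilon
  attr(sys, "excess_factor") <- min(sys$c0 / site_capacity(sys))
  sys
}

#' Canonical three-species demonstration panel
#'
#' A fixed serum-like panel whose early and late corona compositions invert
#' (the Vroman-type exchange the model is built to capture):
#' \describe{
#'   \item{Alb}{an albumin-like binder: very abundant and fast-associating,
#'     so it dominates the metastable corona, but also fast-dissociating
#'     (low affinity), so it is displaced later.}
#'   \item{Lip}{a lipoprotein-like species of intermediate abundance and
#'     affinity.}
#'   \item{Fib}{a fibrinogen-like species: scarce and slow to arrive, but
#'     with a very small dissociation rate (high affinity), so it dominates
#'     the stable corona.}
#' }
#' The panel has strong time-scale separation (`epsilon` about 3e-5) and
#' ample protein excess, so all closed-form results apply.
#'
#' @return A [corona_system()].
#' @examples
#' sys <- demo_panel()
#' metastable_composition(sys)
#' stable_composition(sys)
#' @export
demo_panel <- function() {
  corona_system(
    tibble::tibble(
      name = c("Alb", "Lip", "Fib"),
      ka = c(1.0e5, 3.0e5, 2.0e5), # M^-1 s^-1
      kd = c(1.0e-3, 2.0e-3, 1.0e-6), # s^-1
      n = c(100, 60, 30), # molecules per particle
      c0 = c(6.0e-4, 2.0e-5, 8.0e-6) # M
    ),
    N0 = 1e-9
  )
}
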