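#' Define a nanoparticle--protein panel
#'
#' A `corona_system` bundles a protein panel with the nanoparticle
#' concentration. Each protein species is characterised by its association
#' rate to the nanoparticle surface, its dissociation rate, the average
#' number of molecules needed to fully cover one particle, and its initial
#' (total) concentration in the fluid. Units are fixed package-wide:
#' concentrations in molar (M), time in seconds, `ka` in M^-1 s^-1, `kd` in
#' s^-1; `n` is dimensionless.
#'
#' @param species A data frame with one row per protein species and columns
#'   `name` (unique identifier), `ka` (association rate, M^-1 s^-1), `kd`
#'   (dissociation rate, s^-1; zero permitted for pure-association runs),
#'   `n` (number of molecules fully covering one particle), and `c0`
#'   (initial concentration, M).
#' @param N0 Nanoparticle concentration in M; must be positive.
#'
#' @return An object of class `corona_system`: a tibble of species carrying
#'   `N0` as an attribute. The derived per-species equilibrium constant
#'   `K = ka / kd` (M^-1) is available via [tidy()] and is `NA` where
#'   `kd = 0`.
#'
#' @examples
#' sys <- corona_system(
#'   data.frame(
#'     name = c("A", "B"),
#'     ka = c(1e5, 3e5), kd = c(1e-3, 1e-6),
#'     n = c(100, 50), c0 = c(6e-4, 2e-5)
#'   ),
#'   N0 = 1e-9
#' )
#' sys
#' @export
corona_system <- function(species, N0) {
  if (!is.data.frame(species)) {
    stop("`species` must be a data frame (one row per protein species).",
         call. = FALSE)
  }
  required <- c("name", "ka", "kd", "n", "c0")
  missing_cols <- setdiff(required, names(species))
  if (length(missing_cols) > 0) {
    stop("`species` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  species <- tibble::as_tibble(species)[required]
  species$name <- as.character(species$name)
  for (col in c("ka", "kd", "n", "c0")) {
    if (!is.numeric(species[[col]])) {
      stop("Column `", col, "` must be numeric.", call. = FALSE)
    }
  }
  if (!is.numeric(N0) || length(N0) != 1 || !is.finite(N0)) {
    stop("`N0` must be a single finite number (M).", call. = FALSE)
  }
  out <- structure(species,
    class = c("corona_system", class(tibble::tibble())),
    N0 = as.numeric(N0)
  )
  diag <- validate_corona(out, check_excess = FALSE)
  errs <- diag[diag$level == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("Invalid corona system:\n",
         paste0("- ", errs$message, collapse = "\n"), call. = FALSE)
  }
  out
}

#' @export
print.corona_system <- function(x, ...) {
  cat(sprintf("<corona_system> %d species, N0 = %.6g M\n", nrow(x), n0_of(x)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# nanoparticle concentration stored on the object
n0_of <- function(system) attr(system, "N0", exact = TRUE)

# per-species site capacity n_i * N0 in concentration units (M)
site_capacity <- function(system) system$n * n0_of(system)

assert_system <- function(system) {
  if (!inherits(system, "corona_system")) {
    stop("Expected a `corona_system`; see `corona_system()`.", call. = FALSE)
  }
  invisible(system)
}

check_state_dim <- function(x, system) {
  if (!is.numeric(x) || length(x) != nrow(system)) {
    stop("State `x` must be numeric with one entry per species (",
         nrow(system), ").", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("State `x` contains non-finite values.",
                               call. = FALSE)
  invisible(x)
}

# absolute tolerance on dimensionless fractions, package-wide
fraction_tol <- function() 1e-9

#' Validate a corona system
#'
#' Checks the structural invariants of a panel (positive rates and
#' capacities, unique names, non-negative concentrations) and, optionally,
#' the protein-excess assumption behind the closed-form metastable
#' composition: the fast phase consumes `n_i * N0 * fbar_i` of species `i`,
#' and the closed form is only trustworthy when this demand stays below the
#' available concentration `c0_i`.
#'
#' @param system A [corona_system()].
#' @param check_excess Also test the protein-excess assumption (default
#'   `TRUE`); violations are reported as warnings, not errors.
#'
#' @return A tibble of diagnostics with columns `level` (`"error"` or
#'   `"warning"`), `species` (name or `NA` for panel-level issues), and
#'   `message`. Zero rows means the panel is clean.
#' @export
validate_corona <- function(system, check_excess = TRUE) {
  if (!is.data.frame(system)) {
    stop("Expected a `corona_system` or species data frame.", call. = FALSE)
  }
  N0 <- n0_of(system)
  diags <- list()
  add <- function(level, species, message) {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      level = level, species = species, message = message
    )
  }
  if (nrow(system) < 1) add("error", NA_character_, "panel has no species")
  if (is.null(N0) || !is.finite(N0) || N0 <= 0) {
    add("error", NA_character_, "nanoparticle concentration N0 must be > 0")
  }
  dup <- unique(system$name[duplicated(system$name)])
  for (d in dup) add("error", d, paste0("duplicate species name '", d, "'"))
  for (i in seq_len(nrow(system))) {
    nm <- system$name[i]
    if (!is.finite(system$ka[i]) || system$ka[i] <= 0) {
      add("error", nm, paste0("species '", nm, "': ka must be > 0"))
    }
    if (!is.finite(system$kd[i]) || system$kd[i] < 0) {
      add("error", nm, paste0("species '", nm, "': kd must be >= 0"))
    }
    if (!is.finite(system$n[i]) || system$n[i] <= 0) {
      add("error", nm, paste0("species '", nm, "': n must be > 0"))
    }
    if (!is.finite(system$c0[i]) || system$c0[i] < 0) {
      add("error", nm, paste0("species '", nm, "': c0 must be >= 0"))
    }
  }
  no_error <- !any(vapply(diags, function(d) d$level == "error", logical(1)))
  if (check_excess && no_error) {
    rates <- system$ka * system$c0
    if (sum(rates) > 0) {
      fbar <- rates / sum(rates)
      demand <- system$n * N0 * fbar
      short <- which(demand > system$c0)
      for (i in short) {
        add("warning", system$name[i], paste0(
          "species '", system$name[i],
          "': protein-excess assumption violated (metastable demand ",
          format(demand[i], digits = 4), " M exceeds c0 = ",
          format(system$c0[i], digits = 4), " M)"
        ))
      }
    }
  }
  if (length(diags) == 0) {
    return(tibble::tibble(level = character(), species = character(),
                          message = character()))
  }
  dplyr::bind_rows(diags)
}

#' Surface fractions of a bound-protein state
#'
#' Converts a vector of bound concentrations into per-species occupied
#' surface fractions `f_i = x_i / (n_i * N0)` and the free surface fraction
#' `theta = 1 - sum(f_i)`.
#'
#' @param x Numeric vector of bound concentrations (M), one per species, in
#'   the system's species order.
#' @param system A [corona_system()].
#'
#' @return A tibble with columns `species`, `x` (M), `f`, and `theta`
#'   (repeated on every row for convenience in tidy pipelines).
#' @export
surface_fractions <- function(x, system) {
  assert_system(system)
  check_state_dim(x, system)
  f <- x / site_capacity(system)
  theta <- 1 - sum(f)
  tibble::tibble(species = system$name, x = x, f = f, theta = theta)
}
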