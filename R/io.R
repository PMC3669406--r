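#' Read a protein panel from YAML or CSV
#'
#' YAML schema: top-level `nanoparticle: {N0: <M>}` and `species:` a list of
#' maps with keys `name, ka, kd, n, c0`. CSV schema: header
#' `name,ka,kd,n,c0`, with the nanoparticle concentration either passed as
#' `N0` or embedded as a leading comment line `#N0=<value>`. Scientific
#' notation is accepted everywhere. The parsed panel must pass
#' [validate_corona()] without errors.
#'
#' @param path Path to the panel file.
#' @param format `"yaml"` or `"csv"`; guessed from the file extension by
#'   default.
#' @param N0 Nanoparticle concentration (M) for CSV panels lacking a
#'   `#N0=` header comment.
#' @return A [corona_system()].
#' @export
read_panel <- function(path, format = c("auto", "yaml", "csv"), N0 = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) "yaml" else "csv"
  }
  if (!file.exists(path)) stop("Panel file not found: ", path, call. = FALSE)
  if (format == "yaml") {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$nanoparticle$N0)) {
      stop("YAML panel missing `nanoparticle: N0:` key.", call. = FALSE)
    }
    if (is.null(doc$species) || length(doc$species) == 0) {
      stop("YAML panel missing `species:` list.", call. = FALSE)
    }
    rows <- purrr::imap(doc$species, function(sp, i) {
      missing_keys <- setdiff(c("name", "ka", "kd", "n", "c0"), names(sp))
      if (length(missing_keys) > 0) {
        stop("YAML species entry ", i, " missing key(s): ",
             paste(missing_keys, collapse = ", "), call. = FALSE)
      }
      tibble::tibble(name = as.character(sp$name),
                     ka = as.numeric(sp$ka), kd = as.numeric(sp$kd),
                     n = as.numeric(sp$n), c0 = as.numeric(sp$c0))
    })
    species <- dplyr::bind_rows(rows)
    N0 <- as.numeric(doc$nanoparticle$N0)
  } else {
    first <- readLines(path, n = 1)
    if (grepl("^#\\s*N0\\s*=", first)) {
      N0 <- as.numeric(sub("^#\\s*N0\\s*=\\s*", "", first))
    }
    if (is.null(N0) || is.na(N0)) {
      stop("CSV panel needs N0: pass `N0 = ` or a `#N0=<value>` first line.",
           call. = FALSE)
    }
    species <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
    missing_cols <- setdiff(c("name", "ka", "kd", "n", "c0"), names(species))
    if (length(missing_cols) > 0) {
      stop("CSV panel missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (col in c("ka", "kd", "n", "c0")) {
      if (!is.numeric(species[[col]])) {
        stop("CSV column `", col, "` is not numeric.", call. = FALSE)
      }
    }
  }
  sys <- corona_system(species, N0)
  diag <- validate_corona(sys)
  for (w in diag$message[diag$level == "warning"]) warning(w, call. = FALSE)
  sys
}

#' Write a protein panel to YAML or CSV
#'
#' Inverse of [read_panel()]: `write_panel()` then `read_panel()` is
#' value-identical.
#'
#' @param system A [corona_system()].
#' @param path Output path.
#' @param format `"yaml"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_panel <- function(system, path, format = c("auto", "yaml", "csv")) {
  assert_system(system)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) "yaml" else "csv"
  }
  if (format == "yaml") {
    doc <- list(
      nanoparticle = list(N0 = n0_of(system)),
      species = purrr::pmap(tibble::as_tibble(system),
                            function(name, ka, kd, n, c0) {
                              list(name = name, ka = ka, kd = kd,
                                   n = n, c0 = c0)
                            })
    )
    yaml::write_yaml(doc, path, precision = 15)
  } else {
    writeLines(sprintf("#N0=%.15g", n0_of(system)), path)
    readr::write_csv(tibble::as_tibble(system), path, append = TRUE,
                     col_names = TRUE)
  }
  invisible(path)
}

format_sig <- function(x, digits = 12) {
  if (is.numeric(x)) signif(x, digits) else x
}

#' Write a result object to CSV or JSON
#'
#' Serialises the package's result types with their documented tidy
#' schemas: trajectories as one row per (time, species) with columns
#' `time_s, species, x_molar, f, theta` (plus `replicate`, `seed`, and
#' `model` metadata where present); compositions as two-column
#' `species, fraction` CSV (JSON adds `theta` and `label`); sensitivity
#' matrices and sweep tables in their long forms. Floating point is written
#' with 12 significant digits.
#'
#' @param object A `corona_trajectory`, `corona_composition`,
#'   `corona_sensitivity`, or `corona_sweep`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (inherits(object, "corona_trajectory")) {
    tab <- tibble::as_tibble(object)
    tab <- dplyr::rename(tab, time_s = "time", x_molar = "x")
    tab$model <- attr(object, "model") %||% NA_character_
  } else if (inherits(object, "corona_composition")) {
    if (format == "csv") {
      tab <- tibble::tibble(species = object$species, fraction = object$f)
    } else {
      tab <- list(label = attr(object, "label"),
                  theta = format_sig(attr(object, "theta")),
                  species = object$species,
                  fraction = format_sig(object$f),
                  x_molar = format_sig(object$x))
    }
  } else if (inherits(object, "corona_sensitivity") ||
             inherits(object, "corona_sweep")) {
    tab <- tibble::as_tibble(object)
  } else if (is.data.frame(object)) {
    tab <- tibble::as_tibble(object)
  } else {
    stop("Don't know how to write objects of class ",
         paste(class(object), collapse = "/"), ".", call. = FALSE)
  }
  if (format == "csv") {
    tab <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric),
                                            ~ format_sig(.x)))
    readr::write_csv(tab, path)
  } else {
    if (is.data.frame(tab)) {
      tab <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric),
                                              ~ format_sig(.x)))
    }
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
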