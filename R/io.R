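#' Read a controlled-feeding experiment CSV
#'
#' Expects UTF-8, comma-separated, dot-decimal, with a header row. Required
#' columns: `study_id`, `diet_d15n`, `diet_sigma`, and per row either
#' `consumer_d15n`/`consumer_sigma` or `discrimination`/
#' `discrimination_sigma`; optional `diet_source`, `environment`,
#' `equilibrium`, `tissue`. Empty cells are missing. Validation errors
#' report row numbers.
#'
#' @param path Path to the CSV file.
#' @param sd_to_se Optional column name holding per-study sample sizes; when
#'   given, reported errors are treated as SDs and divided by `sqrt(n)`.
#' @return An `experiment_obs` tibble (see [experiment_observations()]).
#' @export
read_experiments <- function(path, sd_to_se = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         locale = readr::locale(decimal_mark = "."),
                         col_types = readr::cols(.default = "c"))
  nsz <- NULL
  if (!is.null(sd_to_se)) {
    if (!sd_to_se %in% names(raw)) {
      stop("sample-size column not found: ", sd_to_se, call. = FALSE)
    }
    nsz <- as.integer(raw[[sd_to_se]])
  }
  experiment_observations(raw, sd_to_se = nsz)
}

#' Read a food-web specimen CSV
#'
#' Schema: `specimen_id`, `species`, `functional_group`, `d15n`, and
#' optional `d13c`, `length_cm`, `site`. Single site per file; non-numeric
#' isotope fields are reported with their row number.
#'
#' @param path Path to the CSV file.
#' @return A specimen tibble.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  required <- c("specimen_id", "species", "d15n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    if (!col %in% names(x)) return(rep(NA_real_, nrow(x)))
    suppressWarnings(v <- as.numeric(x[[col]]))
    bad <- which(!is.na(x[[col]]) & nzchar(x[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row(s) %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    v
  }
  d15n <- num("d15n")
  if (anyNA(d15n)) {
    stop("d15n missing at row(s) ", paste(which(is.na(d15n)), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    specimen_id = as.character(x$specimen_id),
    species = as.character(x$species),
    functional_group = if ("functional_group" %in% names(x)) {
      as.character(x$functional_group)
    } else NA_character_,
    d15n = d15n,
    d13c = num("d13c"),
    length_cm = num("length_cm"),
    site = if ("site" %in% names(x)) as.character(x$site) else NA_character_
  )
}

#' Write / read a trophic-position table
#'
#' CSV round trip in a fixed dialect (UTF-8, comma separator, dot decimal)
#' with doubles written at full round-trip precision, so a written table
#' parses back bitwise-identical.
#'
#' @param tp_table A TP table (e.g. from [estimate_foodweb_tp()]).
#' @param path Destination / source path.
#' @return `write_tp_table()` returns `path` invisibly; `read_tp_table()`
#'   returns the parsed tibble.
#' @export
write_tp_table <- function(tp_table, path) {
  out <- tibble::as_tibble(tp_table)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits guarantee an exact double round trip
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tp_table
#' @export
read_tp_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  # numeric conversion through strtod, which parses doubles exactly
  for (col in names(x)) {
    x[[col]] <- utils::type.convert(x[[col]], as.is = TRUE, na.strings = "")
  }
  x
}

#' Export a fitted meta-regression
#'
#' Writes the posterior draws to `draws.csv` (one column per parameter,
#' `.chain` included) and a JSON sidecar `diagnostics.json` with
#' convergence diagnostics, the sampler configuration, priors and package
#' version — the reproducibility block for the run.
#'
#' @param fit A `meta_fit`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(fit, dir) {
  stopifnot(inherits(fit, "meta_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(fit$draws, file.path(dir, "draws.csv"), progress = FALSE)
  meta <- list(
    diagnostics = fit$diagnostics,
    converged = fit$converged,
    n_studies = nrow(fit$data),
    covariates = fit$covariates,
    mcmc = unclass(fit$mcmc),
    priors = unclass(fit$priors),
    package_version = as.character(utils::packageVersion("troposcale"))
  )
  jsonlite::write_json(meta, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read posterior draws exported by [write_posterior()]
#'
#' @param dir Directory containing `draws.csv`.
#' @return A tibble of draws usable wherever a draw table is accepted.
#' @export
read_posterior <- function(dir) {
  path <- file.path(dir, "draws.csv")
  if (!file.exists(path)) stop("no draws.csv in ", dir, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
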