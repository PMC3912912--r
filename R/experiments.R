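#' Assemble and validate a table of controlled-feeding experiment records
#'
#' Each record is one experimental study reporting the mean dietary
#' \eqn{\delta^{15}N} fed to fish and either the consumer tissue
#' \eqn{\delta^{15}N} or the diet-tissue discrimination factor
#' \eqn{\Delta^{15}N} directly, together with study-level errors that the
#' meta-regression treats as known. Rows reporting only \eqn{\Delta^{15}N}
#' are normalised via the identity
#' \eqn{\delta^{15}N_{consumer} = \delta^{15}N_{diet} + \Delta^{15}N},
#' taking the reported discrimination error as the consumer-side error.
#'
#' Missing error values are imputed with the median of the reported values
#' in the same column (with a warning); missing categorical covariates stay
#' `NA` and simply exclude those rows from covariate models.
#'
#' @param x A data frame with columns `study_id`, `diet_d15n`, `diet_sigma`,
#'   and either (`consumer_d15n`, `consumer_sigma`) or (`discrimination`,
#'   `discrimination_sigma`) per row; optional columns `diet_source`
#'   ("artificial"/"natural"), `environment` ("marine"/"freshwater"),
#'   `equilibrium` (logical), `tissue` ("muscle"/"whole").
#' @param sd_to_se Optional integer vector of per-row sample sizes; when
#'   supplied, reported errors are interpreted as SDs and converted to
#'   standard errors by dividing by `sqrt(n)`. Default `NULL` stores errors
#'   as given.
#' @return A tibble of class `experiment_obs` with normalised columns
#'   `study_id`, `diet_d15n`, `diet_sigma`, `consumer_d15n`,
#'   `consumer_sigma`, `discrimination`, `diet_source`, `environment`,
#'   `equilibrium`, `tissue`.
#' @seealso [read_experiments()] for the CSV loader, [fit_meta_model()].
#' @export
experiment_observations <- function(x, sd_to_se = NULL) {
  x <- as.data.frame(x)
  required <- c("study_id", "diet_d15n", "diet_sigma")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(x)
  get_num <- function(col) {
    if (!col %in% names(x)) return(rep(NA_real_, n))
    v <- x[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    suppressWarnings(out <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row(s) %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out
  }
  diet <- get_num("diet_d15n")
  if (anyNA(diet)) {
    stop("diet_d15n missing at row(s) ",
         paste(which(is.na(diet)), collapse = ", "), call. = FALSE)
  }
  consumer <- get_num("consumer_d15n")
  disc <- get_num("discrimination")
  both <- !is.na(consumer) & !is.na(disc)
  if (any(both)) {
    incons <- both & abs(consumer - (diet + disc)) > 1e-6
    if (any(incons)) {
      stop("rows ", paste(which(incons), collapse = ", "),
           ": consumer_d15n and discrimination disagree with c = d + Delta",
           call. = FALSE)
    }
  }
  neither <- is.na(consumer) & is.na(disc)
  if (any(neither)) {
    stop("rows ", paste(which(neither), collapse = ", "),
         ": need consumer_d15n or discrimination", call. = FALSE)
  }

  diet_sigma <- get_num("diet_sigma")
  consumer_sigma <- get_num("consumer_sigma")
  disc_sigma <- get_num("discrimination_sigma")
  # delta-only rows: reported discrimination error stands in for the
  # consumer-side error
  delta_only <- is.na(consumer)
  consumer[delta_only] <- diet[delta_only] + disc[delta_only]
  consumer_sigma[delta_only & is.na(consumer_sigma)] <-
    disc_sigma[delta_only & is.na(consumer_sigma)]

  if (!is.null(sd_to_se)) {
    stopifnot(length(sd_to_se) == n, all(sd_to_se >= 1, na.rm = TRUE))
    diet_sigma <- diet_sigma / sqrt(sd_to_se)
    consumer_sigma <- consumer_sigma / sqrt(sd_to_se)
  }
  impute <- function(v, what) {
    if (anyNA(v)) {
      if (all(is.na(v))) {
        stop("no reported values in ", what, " to impute from", call. = FALSE)
      }
      med <- stats::median(v, na.rm = TRUE)
      warning(sprintf("imputed %d missing %s value(s) with column median %.3f",
                      sum(is.na(v)), what, med), call. = FALSE)
      v[is.na(v)] <- med
    }
    v
  }
  diet_sigma <- impute(diet_sigma, "diet_sigma")
  consumer_sigma <- impute(consumer_sigma, "consumer_sigma")
  if (any(diet_sigma < 0) || any(consumer_sigma < 0)) {
    stop("negative study-level error", call. = FALSE)
  }

  get_enum <- function(col, levels) {
    if (!col %in% names(x)) return(rep(NA_character_, n))
    v <- trimws(tolower(as.character(x[[col]])))
    v[!nzchar(v)] <- NA
    bad <- which(!is.na(v) & !v %in% levels)
    if (length(bad)) {
      stop(sprintf("column '%s' row(s) %s: expected one of %s", col,
                   paste(bad, collapse = ", "),
                   paste(levels, collapse = "/")), call. = FALSE)
    }
    v
  }
  eq <- if ("equilibrium" %in% names(x)) {
    v <- x[["equilibrium"]]
    if (!is.logical(v)) v <- as.logical(toupper(trimws(as.character(v))))
    v
  } else rep(NA, n)

  out <- tibble::tibble(
    study_id = as.character(x$study_id),
    diet_d15n = diet,
    diet_sigma = diet_sigma,
    consumer_d15n = consumer,
    consumer_sigma = consumer_sigma,
    discrimination = consumer - diet,
    diet_source = get_enum("diet_source", c("artificial", "natural")),
    environment = get_enum("environment", c("marine", "freshwater")),
    equilibrium = eq,
    tissue = get_enum("tissue", c("muscle", "whole"))
  )
  class(out) <- c("experiment_obs", class(out))
  out
}

#' Drop studies that did not report reaching isotopic equilibrium
#'
#' Feeding trials stopped before consumer tissue equilibrates with the
#' experimental diet can bias discrimination estimates; this filter retains
#' only rows with `equilibrium` reported `TRUE`. In the meta-analysis the
#' filter is a sensitivity check, off by default.
#'
#' @param observations An `experiment_obs` table.
#' @return The filtered table, with a message giving counts.
#' @export
filter_equilibrium <- function(observations) {
  stopifnot(inherits(observations, "experiment_obs"))
  keep <- !is.na(observations$equilibrium) & observations$equilibrium
  message(sprintf("equilibrium filter: kept %d of %d studies",
                  sum(keep), nrow(observations)))
  observations[keep, , drop = FALSE]
}
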