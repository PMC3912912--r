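#' Simulate a controlled-feeding experiment table with known ground truth
#'
#' Generates studies under the same model the meta-regression assumes: true
#' diet values uniform over `diet_range`; true discrimination
#' \eqn{\beta_0 + \beta_1 d + N(0, resid\_scale^2)}; observed diet and
#' consumer values add independent Gaussian measurement error with the
#' study-level SDs. Defaults emulate the fish feeding-trial literature the
#' meta-analysis draws on: 59 studies, intercept 5.92 per mil, slope -0.27,
#' diet values spanning 0-20 per mil, study errors of 0.3 per mil and
#' between-study heterogeneity of 0.5 per mil.
#'
#' Ground-truth columns (`true_diet`, `true_discrimination`) are emitted
#' alongside the observations and are never read by any estimator.
#'
#' @param n_studies Number of studies.
#' @param beta0,beta1 True intercept (per mil) and slope of the
#'   discrimination relation.
#' @param diet_range Range of true dietary \eqn{\delta^{15}N}, per mil.
#' @param resid_scale True between-study residual SD, per mil.
#' @param sigma_d,sigma_c Study-level measurement SDs, per mil; scalars or
#'   length-2 ranges from which per-study values are drawn uniformly.
#' @param covariate_effects Optional named list, e.g.
#'   `list(diet_source = c(natural = 2))`, adding a per-mil offset to the
#'   true discrimination for the named level; levels are assigned to
#'   studies with equal probability.
#' @param heavy_tails If `TRUE`, residuals are Student-t with 3 df
#'   (scaled to `resid_scale`) instead of Gaussian — for robustness checks
#'   only.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return An `experiment_obs` tibble with the observation columns of
#'   [experiment_observations()] plus `true_diet` and
#'   `true_discrimination`.
#' @export
simulate_experiments <- function(n_studies = 59, beta0 = 5.92,
                                 beta1 = -0.27, diet_range = c(0, 20),
                                 resid_scale = 0.5, sigma_d = 0.3,
                                 sigma_c = 0.3, covariate_effects = NULL,
                                 heavy_tails = FALSE, seed = 1L) {
  stopifnot(n_studies >= 1, diet_range[1] < diet_range[2], resid_scale >= 0,
            all(sigma_d >= 0), all(sigma_c >= 0))
  set.seed(seed)
  n <- n_studies
  draw_sigma <- function(s) {
    if (length(s) == 2L) stats::runif(n, s[1], s[2]) else rep(s, n)
  }
  sd_d <- draw_sigma(sigma_d)
  sd_c <- draw_sigma(sigma_c)
  true_diet <- stats::runif(n, diet_range[1], diet_range[2])
  eps <- if (heavy_tails) {
    resid_scale * stats::rt(n, df = 3) / sqrt(3)
  } else {
    stats::rnorm(n, 0, resid_scale)
  }
  true_disc <- beta0 + beta1 * true_diet + eps

  diet_source <- sample(c("artificial", "natural"), n, replace = TRUE)
  environment <- sample(c("marine", "freshwater"), n, replace = TRUE)
  tissue <- sample(c("muscle", "whole"), n, replace = TRUE)
  if (!is.null(covariate_effects)) {
    cov_cols <- list(diet_source = diet_source, environment = environment,
                     tissue = tissue)
    for (cv in names(covariate_effects)) {
      eff <- covariate_effects[[cv]]
      for (lev in names(eff)) {
        true_disc <- true_disc + eff[[lev]] * (cov_cols[[cv]] == lev)
      }
    }
  }

  obs <- tibble::tibble(
    study_id = sprintf("study_%02d", seq_len(n)),
    diet_d15n = true_diet + stats::rnorm(n, 0, sd_d),
    diet_sigma = sd_d,
    consumer_d15n = true_diet + true_disc + stats::rnorm(n, 0, sd_c),
    consumer_sigma = sd_c,
    diet_source = diet_source,
    environment = environment,
    equilibrium = TRUE,
    tissue = tissue
  )
  out <- experiment_observations(obs)
  out$true_diet <- true_diet
  out$true_discrimination <- true_disc
  out
}

#' Simulate a single-site food-web specimen table with known trophic positions
#'
#' Places each species on the scaled enrichment curve at its true trophic
#' position and adds individual Gaussian scatter, and generates baseline
#' specimens (labelled `"zooplankton"` when the baseline TL is 2) around the
#' baseline value. True TPs are emitted in a `true_tp` column that no
#' estimator reads.
#'
#' Defaults sketch a subtropical shelf web: baseline zooplankton at 5.2 per
#' mil (TL2, 16 individuals, SD 0.8) and consumer species from
#' zooplanktivores to tertiary piscivores, under the discrimination line
#' with intercept 5.92 per mil and slope -0.27.
#'
#' @param species A data frame with columns `species`, `functional_group`,
#'   `true_tp`, `n` (individuals per species); a default five-species web
#'   spanning TP 3-6 is used when omitted.
#' @param line A [discrimination_line()] defining the curve.
#' @param base A [baseline_spec()] giving the true baseline value and TL.
#' @param individual_sd Individual isotopic scatter, per mil.
#' @param baseline_n,baseline_sd Number and scatter of generated baseline
#'   specimens.
#' @param site Site label (baselines are never shared across sites).
#' @param seed Integer seed.
#' @return A specimen tibble: `specimen_id`, `species`, `functional_group`,
#'   `d15n`, `d13c` (NA pass-through), `length_cm` (NA), `site`, `true_tp`.
#' @export
simulate_foodweb <- function(species = NULL,
                             line = discrimination_line(5.92, -0.27),
                             base = baseline_spec(5.2, 2),
                             individual_sd = 0.4, baseline_n = 16L,
                             baseline_sd = 0.8, site = "site_1",
                             seed = 1L) {
  stopifnot(inherits(line, "discrimination_line"),
            inherits(base, "baseline_spec"), individual_sd >= 0,
            baseline_sd >= 0, baseline_n >= 1)
  params <- derive_scaled_params(line)
  if (is.null(species)) {
    species <- tibble::tibble(
      species = c("zooplanktivore_a", "primary_piscivore_a",
                  "primary_piscivore_b", "secondary_piscivore_a",
                  "tertiary_piscivore_a"),
      functional_group = c("zooplanktivore", "primary_piscivore",
                           "primary_piscivore", "secondary_piscivore",
                           "tertiary_piscivore"),
      true_tp = c(3, 3.8, 4.2, 5, 6),
      n = c(12L, 10L, 10L, 8L, 6L)
    )
  }
  species <- as.data.frame(species)
  stopifnot(all(c("species", "functional_group", "true_tp", "n") %in%
                  names(species)))
  if (any(species$true_tp < base$tl)) {
    stop("true TP below the baseline trophic level", call. = FALSE)
  }
  set.seed(seed)
  baseline_group <- if (base$tl == 2L) "zooplankton" else "zooplanktivore"
  base_tbl <- tibble::tibble(
    species = baseline_group,
    functional_group = baseline_group,
    d15n = stats::rnorm(baseline_n, base$delta15N, baseline_sd),
    true_tp = as.numeric(base$tl)
  )
  cons_tbl <- do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
    row <- species[i, ]
    mu <- delta15N_at_tp(params, base, row$true_tp)
    tibble::tibble(
      species = row$species,
      functional_group = row$functional_group,
      d15n = stats::rnorm(row$n, mu, individual_sd),
      true_tp = row$true_tp
    )
  }))
  out <- rbind(base_tbl, cons_tbl)
  if (any(out$d15n >= params$delta15N_lim)) {
    warning("individual scatter placed some specimens at or above the ",
            "saturating limit", call. = FALSE)
  }
  tibble::tibble(
    specimen_id = sprintf("sp_%03d", seq_len(nrow(out))),
    species = out$species,
    functional_group = out$functional_group,
    d15n = out$d15n,
    d13c = NA_real_,
    length_cm = NA_real_,
    site = site,
    true_tp = out$true_tp
  )
}
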