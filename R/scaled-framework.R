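#' Linear diet-tissue discrimination relationship
#'
#' Constructs the fitted line relating the nitrogen diet-tissue
#' discrimination factor (\eqn{\Delta^{15}N}, the per-mil enrichment of a
#' consumer's tissue over its diet) to the dietary \eqn{\delta^{15}N} value:
#' \deqn{\Delta^{15}N = \beta_0 + \beta_1\,\delta^{15}N_{diet}.}
#' A negative slope means discrimination narrows as food chains get heavier
#' in \eqn{^{15}N}; this is the empirical relationship that motivates the
#' scaled trophic-position framework.
#'
#' @param beta0 Intercept, per mil. Expected positive for a saturating
#'   framework.
#' @param beta1 Dimensionless slope. Expected in (-1, 0) for a saturating
#'   framework; validity is enforced only when deriving scaled parameters,
#'   so lines outside that range can still be inspected.
#' @return An object of class `discrimination_line`.
#' @seealso [derive_scaled_params()], [predict_discrimination()]
#' @examples
#' line <- discrimination_line(5.92, -0.27)
#' predict_discrimination(line, diet_delta15N = c(0, 10.2))
#' @export
discrimination_line <- function(beta0, beta1) {
  stopifnot(is.numeric(beta0), is.numeric(beta1),
            length(beta0) == 1L, length(beta1) == 1L,
            is.finite(beta0), is.finite(beta1))
  structure(list(beta0 = beta0, beta1 = beta1),
            class = "discrimination_line")
}

#' @export
print.discrimination_line <- function(x, ...) {
  cat(sprintf("<discrimination_line>  Delta15N = %.4f %+.4f * diet d15N\n",
              x$beta0, x$beta1))
  invisible(x)
}

#' Derive the saturating enrichment parameters from a discrimination line
#'
#' A linear decline of discrimination with dietary \eqn{\delta^{15}N} implies
#' that consumer \eqn{\delta^{15}N} follows the affine per-step recursion
#' \eqn{x_{t+1} = x_t + \beta_0 + \beta_1 x_t}, whose fixed point is the
#' saturating isotope limit and whose geometric contraction factor
#' \eqn{1+\beta_1 = e^{-k}} sets the approach rate:
#' \deqn{\delta^{15}N_{lim} = -\beta_0/\beta_1, \qquad k = -\log(1+\beta_1).}
#' Discrimination is exactly zero at \eqn{\delta^{15}N_{lim}}, the
#' asymptotic isotope value of an infinitely long food chain.
#'
#' @param line A [discrimination_line()].
#' @return An object of class `scaled_params` with fields `delta15N_lim`
#'   (per mil) and `k` (per trophic-level step).
#' @section Validity:
#' Requires `beta0 > 0` and `-1 < beta1 < 0`. A non-negative slope gives no
#' saturation (use the additive framework); a slope at or below -1 puts the
#' recursion in an overshooting regime where the curve is not monotone.
#' @examples
#' derive_scaled_params(discrimination_line(5.92, -0.27))
#' @export
derive_scaled_params <- function(line) {
  stopifnot(inherits(line, "discrimination_line"))
  if (line$beta1 >= 0) {
    stop("beta1 >= 0: discrimination does not narrow, so there is no ",
         "saturating limit; use the additive framework instead.",
         call. = FALSE)
  }
  if (line$beta1 <= -1) {
    stop("beta1 <= -1: per-step recursion overshoots the fixed point ",
         "(oscillatory regime); scaled framework invalid.", call. = FALSE)
  }
  if (line$beta0 <= 0) {
    stop("beta0 <= 0: discrimination non-positive at diet d15N = 0; ",
         "scaled framework invalid.", call. = FALSE)
  }
  structure(list(delta15N_lim = -line$beta0 / line$beta1,
                 k = -log1p(line$beta1)),
            class = "scaled_params")
}

#' @export
print.scaled_params <- function(x, ...) {
  cat(sprintf("<scaled_params>  delta15N_lim = %.4f permil, k = %.5f per TL step\n",
              x$delta15N_lim, x$k))
  invisible(x)
}

#' Predicted discrimination for a given dietary delta15N
#'
#' Evaluates \eqn{\beta_0 + \beta_1\,\delta^{15}N_{diet}}. Vectorised over
#' `diet_delta15N`.
#'
#' @param line A [discrimination_line()].
#' @param diet_delta15N Dietary \eqn{\delta^{15}N} values, per mil.
#' @return Predicted \eqn{\Delta^{15}N}, per mil.
#' @export
predict_discrimination <- function(line, diet_delta15N) {
  stopifnot(inherits(line, "discrimination_line"), is.numeric(diet_delta15N))
  line$beta0 + line$beta1 * diet_delta15N
}

#' Baseline definition for trophic-position calculations
#'
#' A baseline is a consumer of known trophic level whose pooled
#' \eqn{\delta^{15}N} anchors the food web: conventionally herbivorous
#' zooplankton at TL2 or zooplanktivores at TL3 (primary producers are TL1).
#'
#' @param delta15N Pooled baseline \eqn{\delta^{15}N}, per mil.
#' @param tl Known trophic level of the baseline organisms, 2 or 3.
#' @param species Optional character vector of baseline species names.
#' @param sd,n Optional standard deviation and specimen count of the pooled
#'   baseline, carried for reporting.
#' @return An object of class `baseline_spec`.
#' @seealso [pool_baseline()] to build one from specimen records.
#' @export
baseline_spec <- function(delta15N, tl, species = character(), sd = NA_real_,
                          n = NA_integer_) {
  stopifnot(is.numeric(delta15N), length(delta15N) == 1L, is.finite(delta15N))
  if (!tl %in% c(2L, 3L)) {
    stop("baseline tl must be 2 (zooplankton) or 3 (zooplanktivores)",
         call. = FALSE)
  }
  structure(list(delta15N = delta15N, tl = as.integer(tl),
                 species = as.character(species), sd = sd,
                 n = as.integer(n)),
            class = "baseline_spec")
}

#' @export
print.baseline_spec <- function(x, ...) {
  cat(sprintf("<baseline_spec>  %.2f permil at TL%d", x$delta15N, x$tl))
  if (!is.na(x$n)) cat(sprintf("  (SD %.2f, n = %d)", x$sd, x$n))
  if (length(x$species)) cat("\n  species:", paste(x$species, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Consumer delta15N at a given trophic position (forward curve)
#'
#' The scaled enrichment model has the form of a von Bertalanffy saturating
#' curve in trophic position:
#' \deqn{\delta^{15}N_{TP} = \delta^{15}N_{lim} -
#'   (\delta^{15}N_{lim} - \delta^{15}N_{base})\,
#'   e^{-k\,(TP - TL_{base})}.}
#' At integer steps it reproduces repeated application of the per-step
#' discrimination recursion; as \eqn{TP \to \infty} it approaches
#' \eqn{\delta^{15}N_{lim}}.
#'
#' @param params A [scaled_params] object.
#' @param base A [baseline_spec()]; its `delta15N` must lie below the
#'   saturating limit.
#' @param tp Trophic position(s), continuous. Values below the baseline TL
#'   are permitted (extrapolation) with a warning.
#' @return Consumer \eqn{\delta^{15}N}, per mil; vectorised over `tp`.
#' @export
delta15N_at_tp <- function(params, base, tp) {
  stopifnot(inherits(params, "scaled_params"),
            inherits(base, "baseline_spec"), is.numeric(tp))
  if (base$delta15N >= params$delta15N_lim) {
    stop(sprintf("baseline delta15N (%.3f) at or above the saturating limit (%.3f)",
                 base$delta15N, params$delta15N_lim), call. = FALSE)
  }
  if (any(tp < base$tl)) {
    warning("tp below the baseline trophic level: extrapolating the scaled ",
            "curve below its anchor", call. = FALSE)
  }
  params$delta15N_lim -
    (params$delta15N_lim - base$delta15N) * exp(-params$k * (tp - base$tl))
}

tp_estimate_tbl <- function(tp, framework, baseline_tl, lo = NA_real_,
                            hi = NA_real_, undefined_fraction = 0) {
  tibble::tibble(tp = tp, framework = framework,
                 baseline_tl = as.integer(baseline_tl),
                 tp_lo = lo, tp_hi = hi,
                 undefined_fraction = undefined_fraction)
}

#' Scaled trophic position from a consumer delta15N (inverse curve)
#'
#' Inverts the saturating enrichment curve:
#' \deqn{TP = TL_{base} + \frac{\log(\delta^{15}N_{lim} - \delta^{15}N_{base})
#'   - \log(\delta^{15}N_{lim} - \delta^{15}N_{TP})}{k}.}
#' Exact inverse of [delta15N_at_tp()]; monotone increasing in the consumer
#' value.
#'
#' @inheritParams delta15N_at_tp
#' @param consumer_delta15N Consumer \eqn{\delta^{15}N} value(s), per mil;
#'   each must lie strictly below the saturating limit.
#' @return A tibble with one row per consumer value: columns `tp`,
#'   `framework` (`"scaled"`), `baseline_tl`, `tp_lo`, `tp_hi` (NA for this
#'   point estimator) and `undefined_fraction` (0).
#' @seealso [tp_with_posterior()] for posterior-propagated estimates,
#'   [tp_additive()] for the constant-discrimination convention.
#' @export
tp_scaled <- function(params, base, consumer_delta15N) {
  stopifnot(inherits(params, "scaled_params"),
            inherits(base, "baseline_spec"), is.numeric(consumer_delta15N))
  if (base$delta15N >= params$delta15N_lim) {
    stop(sprintf("baseline delta15N (%.3f) at or above the saturating limit (%.3f)",
                 base$delta15N, params$delta15N_lim), call. = FALSE)
  }
  bad <- consumer_delta15N >= params$delta15N_lim
  if (any(bad)) {
    stop(sprintf(paste0(
      "consumer delta15N at or above the saturating limit (%.4f permil): %s; ",
      "trophic position undefined under these parameters"),
      params$delta15N_lim,
      paste(format(consumer_delta15N[bad]), collapse = ", ")),
      call. = FALSE)
  }
  tp <- base$tl + (log(params$delta15N_lim - base$delta15N) -
                     log(params$delta15N_lim - consumer_delta15N)) / params$k
  tp_estimate_tbl(tp, "scaled", base$tl)
}

#' Additive (constant-discrimination) trophic position
#'
#' The conventional estimator assuming a fixed per-step enrichment:
#' \deqn{TP = TL_{base} + (\delta^{15}N_{consumer} -
#'   \delta^{15}N_{base}) / \Delta_{const}.}
#'
#' @inheritParams tp_scaled
#' @param delta_const Constant discrimination per trophic step, per mil.
#'   Defaults to the conventional 3.4.
#' @return A tibble in the same shape as [tp_scaled()], with
#'   `framework = "additive"`.
#' @export
tp_additive <- function(consumer_delta15N, base, delta_const = 3.4) {
  stopifnot(inherits(base, "baseline_spec"), is.numeric(consumer_delta15N))
  if (!is.numeric(delta_const) || length(delta_const) != 1L ||
      delta_const <= 0) {
    stop("delta_const must be a single positive value (permil)", call. = FALSE)
  }
  tp <- base$tl + (consumer_delta15N - base$delta15N) / delta_const
  tp_estimate_tbl(tp, "additive", base$tl)
}

#' Posterior-propagated scaled trophic position
#'
#' Maps every posterior draw of the discrimination line through
#' [derive_scaled_params()] and the inverse curve, giving a full posterior
#' for the trophic position of each consumer value. Draws for which the
#' consumer value is at or above that draw's saturating limit (including
#' draws with a non-saturating slope) leave TP undefined; their proportion
#' is reported as `undefined_fraction` and, by default, quantiles are taken
#' over the defined draws only.
#'
#' @param draws A `meta_fit` object from [fit_meta_model()], or a data frame
#'   with columns `beta0` and `beta1`.
#' @param base A [baseline_spec()].
#' @param consumer_delta15N Consumer value(s), per mil.
#' @param level Probability mass of the central credible interval.
#' @param undefined How to treat undefined draws: `"drop"` (quantiles over
#'   defined draws; keeps medians finite while `undefined_fraction` exposes
#'   the tail mass) or `"inf"` (treat as +Inf, so heavy undefined mass pushes
#'   the upper quantile, and eventually the median, to Inf).
#' @return A tibble with one row per consumer value: posterior median `tp`,
#'   central interval `tp_lo`/`tp_hi` at `level`, and `undefined_fraction`.
#' @export
tp_with_posterior <- function(draws, base, consumer_delta15N, level = 0.95,
                              undefined = c("drop", "inf")) {
  undefined <- match.arg(undefined)
  stopifnot(inherits(base, "baseline_spec"), is.numeric(consumer_delta15N),
            is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (inherits(draws, "meta_fit")) draws <- draws$draws
  draws <- as.data.frame(draws)
  if (!all(c("beta0", "beta1") %in% names(draws))) {
    stop("draws must contain columns beta0 and beta1", call. = FALSE)
  }
  b0 <- draws$beta0
  b1 <- draws$beta1
  if (!length(b0)) stop("empty posterior draws", call. = FALSE)
  saturating <- b1 > -1 & b1 < 0 & b0 > 0
  lim <- ifelse(saturating, -b0 / b1, -Inf)
  k <- ifelse(saturating, -log1p(b1), NA_real_)
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  rows <- lapply(consumer_delta15N, function(x) {
    ok <- saturating & x < lim & base$delta15N < lim
    undef_frac <- 1 - mean(ok)
    tp <- base$tl + (log(lim[ok] - base$delta15N) - log(lim[ok] - x)) / k[ok]
    if (undefined == "inf") tp <- c(tp, rep(Inf, sum(!ok)))
    if (!length(tp)) {
      stop(sprintf(paste0("all posterior draws leave TP undefined for ",
                          "consumer delta15N = %.3f"), x), call. = FALSE)
    }
    q <- unname(stats::quantile(tp, probs, type = 7))
    tp_estimate_tbl(q[2], "scaled", base$tl, lo = q[1], hi = q[3],
                    undefined_fraction = undef_frac)
  })
  do.call(rbind, rows)
}
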