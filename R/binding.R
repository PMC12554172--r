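#' Reference-subtract a two-channel SPR isotherm
#'
#' Computes the specific equilibrium response at each analyte
#' concentration as measurement channel minus reference channel (the blank
#' flow cell carrying only nonspecific binding). Negative specific
#' responses are retained and flagged, never clipped, so downstream fits
#' see the data as measured.
#'
#' @param isotherm A tibble with strictly increasing `concentration_uM`
#'   and both `ru_reference` and `ru_measurement` columns (channels
#'   aligned row-wise by concentration).
#'
#' @return The isotherm with columns `ru_specific` and `negative_flag`
#'   added.
#' @export
reference_subtract <- function(isotherm) {
  isotherm <- as_tibble(isotherm)
  needed <- c("concentration_uM", "ru_reference", "ru_measurement")
  if (!all(needed %in% names(isotherm))) {
    abort(
      paste0(
        "Both channels are required: columns ",
        paste(needed, collapse = ", ")
      ),
      class = "degronmap_error_isotherm"
    )
  }
  if (any(is.na(isotherm$ru_reference)) || any(is.na(isotherm$ru_measurement))) {
    abort("Channels are misaligned: missing responses at some concentrations.",
      class = "degronmap_error_isotherm"
    )
  }
  if (is.unsorted(isotherm$concentration_uM, strictly = TRUE)) {
    abort("Concentrations must be strictly increasing.",
      class = "degronmap_error_isotherm"
    )
  }
  out <- isotherm |>
    mutate(
      ru_specific = .data$ru_measurement - .data$ru_reference,
      negative_flag = .data$ru_specific < 0
    )
  if (any(out$negative_flag)) {
    warn(sprintf(
      "%d specific response(s) are negative (retained, flagged).",
      sum(out$negative_flag)
    ))
  }
  out
}

#' Fit a one-site saturation binding model
#'
#' Fits the Langmuir isotherm `R(C) = Bmax * C / (Kd + C)` to specific
#' equilibrium responses by nonlinear least squares
#' (Levenberg-Marquardt). Unweighted by default; supply `weights` (e.g.
#' inverse replicate variances) for weighted fits. Confidence intervals
#' come from the asymptotic covariance of the fit.
#'
#' @param isotherm A tibble with `concentration_uM` and `ru_specific`; if
#'   `ru_specific` is absent but both raw channels are present,
#'   [reference_subtract()] is applied first.
#' @param weights Optional numeric vector of fit weights.
#' @param conf_level Confidence level for the intervals (default 0.95).
#'
#' @return An object of class `saturation_fit` with elements `kd`, `bmax`,
#'   `ci` (tibble of Wald intervals), `fit` (the underlying `nls` object),
#'   `data`, and `poorly_constrained` (TRUE when the Kd estimate falls
#'   outside \[min(C)/10, max(C)*10\], flagged with a warning). Methods:
#'   [tidy()], [glance()], [autoplot()], `predict()`.
#' @export
fit_saturation <- function(isotherm, weights = NULL, conf_level = 0.95) {
  isotherm <- as_tibble(isotherm)
  if (!"ru_specific" %in% names(isotherm)) {
    isotherm <- reference_subtract(isotherm)
  }
  conc <- isotherm$concentration_uM
  ru <- isotherm$ru_specific
  if (length(conc) < 4) {
    abort("At least 4 concentrations are required for a saturation fit.",
      class = "degronmap_error_fit"
    )
  }
  if (max(conc) / min(conc) < 10) {
    warn("Concentration series spans less than one decade; fit may be weak.")
  }
  bmax0 <- max(ru)
  kd0 <- conc[which.min(abs(ru - bmax0 / 2))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::quantile(conc, 0.5)
  args <- list(
    ru ~ bmax * conc / (kd + conc),
    start = list(bmax = max(bmax0, 1e-6), kd = kd0),
    lower = c(bmax = 1e-12, kd = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) {
      abort(
        paste0(
          "Saturation fit did not converge: ", conditionMessage(e),
          " (n = ", length(conc), ", response range ",
          signif(min(ru), 3), "..", signif(max(ru), 3), " RU)"
        ),
        class = "degronmap_error_convergence"
      )
    }
  )
  est <- coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  tcrit <- qt(1 - (1 - conf_level) / 2, df = sm$df[2])
  ci <- tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    conf_low = unname(est - tcrit * se),
    conf_high = unname(est + tcrit * se)
  )
  poorly <- est[["kd"]] < min(conc) / 10 || est[["kd"]] > max(conc) * 10
  if (poorly) {
    warn(sprintf(
      "Kd estimate (%.3g uM) lies outside the concentration span; poorly constrained.",
      est[["kd"]]
    ))
  }
  structure(
    list(
      kd = unname(est[["kd"]]),
      bmax = unname(est[["bmax"]]),
      ci = ci,
      fit = fit,
      data = isotherm,
      conf_level = conf_level,
      poorly_constrained = poorly
    ),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "<saturation_fit> Kd = %.4g uM, Bmax = %.4g RU (n = %d)\n",
    x$kd, x$bmax, nrow(x$data)
  ))
  invisible(x)
}

#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$data$concentration_uM
  } else if (is.data.frame(newdata)) {
    newdata$concentration_uM
  } else {
    newdata
  }
  object$bmax * conc / (object$kd + conc)
}

#' Check a dose series for a monotone response
#'
#' Rank-correlation screen for dose dependence, as applied to dot-blot
#' dilution series: Spearman's rho between amount and intensity with a
#' one-sided (increasing) test. The verdict is `"dose-dependent"` when the
#' one-sided p-value beats `alpha` or the ranking is perfect (small series
#' cannot reach conventional significance even when strictly increasing),
#' `"flat"` for constant input or non-positive correlation, and
#' `"ambiguous"` otherwise.
#'
#' @param data A data frame with the dose and intensity columns.
#' @param amount,intensity Column names (tidy-eval) holding the dose and
#'   the measured intensity. Defaults `amount`, `intensity`.
#' @param alpha Significance level for the verdict.
#'
#' @return A one-row tibble: `statistic` (rho), `p_value`, `n`, `verdict`.
#' @export
dose_response_check <- function(data, amount = "amount",
                                intensity = "intensity", alpha = 0.05) {
  x <- data[[amount]]
  y <- data[[intensity]]
  if (length(x) < 3) {
    abort("At least 3 dose levels are required.",
      class = "degronmap_error_argument"
    )
  }
  if (sd(y) == 0) {
    return(tibble(
      statistic = NA_real_, p_value = NA_real_, n = length(x),
      verdict = "flat"
    ))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = "greater", exact = FALSE)
  )
  rho <- unname(ct$estimate)
  verdict <- if (ct$p.value < alpha || isTRUE(all.equal(rho, 1))) {
    "dose-dependent"
  } else if (rho <= 0) {
    "flat"
  } else {
    "ambiguous"
  }
  tibble(
    statistic = rho, p_value = ct$p.value, n = length(x), verdict = verdict
  )
}
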