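#' Tidy a saturation binding fit
#'
#' @param x A `saturation_fit`.
#' @param ... Unused.
#' @return One row per parameter (`kd`, `bmax`) with estimate, standard
#'   error and Wald confidence bounds.
#' @method tidy saturation_fit
#' @export
tidy.saturation_fit <- function(x, ...) {
  x$ci |> rename(std.error = "std_error", conf.low = "conf_low",
    conf.high = "conf_high")
}

#' @rdname tidy.saturation_fit
#' @method glance saturation_fit
#' @export
glance.saturation_fit <- function(x, ...) {
  res <- stats::residuals(x$fit)
  ru <- x$data$ru_specific
  tibble(
    kd = x$kd,
    bmax = x$bmax,
    sigma = summary(x$fit)$sigma,
    r.squared = 1 - sum(res^2) / sum((ru - mean(ru))^2),
    AIC = stats::AIC(x$fit),
    nobs = length(ru),
    poorly_constrained = x$poorly_constrained
  )
}

#' Tidy a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return One row per parameter (`k`, `t_half`, and `plateau` when
#'   fitted) with estimates; the half-life row carries the confidence
#'   bounds.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  out <- tibble(
    term = c("k", "t_half"),
    estimate = c(x$k, x$t_half),
    conf.low = c(NA, x$ci$conf_low),
    conf.high = c(NA, x$ci$conf_high)
  )
  if (!is.na(x$plateau)) {
    out <- bind_rows(out, tibble(
      term = "plateau", estimate = x$plateau,
      conf.low = NA_real_, conf.high = NA_real_
    ))
  }
  out
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    t_half = x$t_half,
    k = x$k,
    r.squared = x$r_squared,
    method = x$method,
    nobs = nrow(x$data)
  )
}
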