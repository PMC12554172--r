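#' Normalize densitometry to a loading control and a reference condition
#'
#' Band intensities are divided by the loading-control intensity of the
#' same lane, then expressed as percent of a designated reference — by
#' default the zero timepoint of the reference condition, matched within
#' each replicate so that per-replicate global intensity scaling cancels
#' exactly.
#'
#' @param table A tibble with columns `condition`, `replicate`,
#'   `band_intensity`, `loading_intensity` and optionally `timepoint_min`.
#' @param ref_condition Condition used as the 100% reference; defaults to
#'   the single condition present, otherwise required.
#' @param ref_timepoint Timepoint of the reference (default 0 when a
#'   `timepoint_min` column exists).
#' @param scale_by `"replicate"` (default; each replicate scaled by its
#'   own reference lane) or `"pooled"` (scaled by the mean reference
#'   ratio).
#'
#' @return The table with `ratio` (band / loading) and `norm_pct` columns
#'   added.
#' @export
normalize_densitometry <- function(table, ref_condition = NULL,
                                   ref_timepoint = 0,
                                   scale_by = c("replicate", "pooled")) {
  scale_by <- match.arg(scale_by)
  table <- as_tibble(table)
  needed <- c("condition", "replicate", "band_intensity", "loading_intensity")
  stopifnot(all(needed %in% names(table)))
  zero <- which(table$loading_intensity <= 0)
  if (length(zero) > 0) {
    abort(
      paste0(
        "Zero or negative loading control in row(s): ",
        paste(zero, collapse = ", ")
      ),
      class = "degronmap_error_loading"
    )
  }
  if (any(table$band_intensity < 0)) {
    abort("Band intensities must be >= 0.", class = "degronmap_error_argument")
  }
  if (is.null(ref_condition)) {
    conds <- unique(table$condition)
    if (length(conds) > 1) {
      abort("Multiple conditions present; specify `ref_condition`.",
        class = "degronmap_error_argument"
      )
    }
    ref_condition <- conds
  }
  has_time <- "timepoint_min" %in% names(table)
  table <- table |> mutate(ratio = .data$band_intensity / .data$loading_intensity)
  is_ref <- table$condition == ref_condition &
    (!has_time | table$timepoint_min == ref_timepoint)
  if (!any(is_ref)) {
    abort("No rows match the reference condition/timepoint.",
      class = "degronmap_error_argument"
    )
  }
  if (scale_by == "replicate") {
    refs <- table[is_ref, ] |>
      group_by(.data$replicate) |>
      summarise(ref_ratio = mean(.data$ratio), .groups = "drop")
    out <- table |>
      left_join(refs, by = "replicate") |>
      mutate(norm_pct = 100 * .data$ratio / .data$ref_ratio) |>
      select(-"ref_ratio")
    if (any(is.na(out$norm_pct))) {
      abort("Some replicates lack a reference lane; cannot scale per replicate.",
        class = "degronmap_error_argument"
      )
    }
    out
  } else {
    table |> mutate(norm_pct = 100 * .data$ratio / mean(.data$ratio[is_ref]))
  }
}

#' Quantify co-immunoprecipitated association as percent of wild type
#'
#' Each sample's immunoprecipitated signal is normalized to its own input
#' level, and the resulting ratios are scaled so the wild-type mean equals
#' 100%. Negative-control lanes (e.g. nonimmune IgG pulldowns) are
#' reported on the same scale but excluded from the scaling.
#'
#' @param table A tibble with columns `condition`, `replicate`,
#'   `ip_intensity`, `input_intensity`.
#' @param wt Label of the wild-type condition (default `"WT"`); required
#'   in the data.
#' @param control Label(s) of negative-control lanes (default `"IgG"`).
#'
#' @return A tibble with `ratio`, `pct_of_wt`, `is_control` columns added.
#' @export
coip_association <- function(table, wt = "WT", control = "IgG") {
  table <- as_tibble(table)
  needed <- c("condition", "replicate", "ip_intensity", "input_intensity")
  stopifnot(all(needed %in% names(table)))
  if (any(table$input_intensity <= 0)) {
    abort("Input intensities must be > 0 for normalization.",
      class = "degronmap_error_loading"
    )
  }
  if (!wt %in% table$condition) {
    abort(paste0("Wild-type condition '", wt, "' is absent from the table."),
      class = "degronmap_error_argument"
    )
  }
  out <- table |>
    mutate(
      ratio = .data$ip_intensity / .data$input_intensity,
      is_control = .data$condition %in% control
    )
  wt_mean <- mean(out$ratio[out$condition == wt])
  out |> mutate(pct_of_wt = 100 * .data$ratio / wt_mean)
}

#' Fit a single-exponential decay to a translation-arrest course
#'
#' Fits `N(t) = 100 * 2^(-t / t_half)` to loading-normalized abundances.
#' The default fit is linear regression of log abundance on time through
#' the origin (t = 0 is pinned at 100% by the course's own normalization;
#' the log transform linearizes the model and stabilizes multiplicative
#' error). `method = "nls"` fits on the raw scale instead, and
#' `model = "plateau"` adds a non-degradable offset
#' `N(t) = c + (100 - c) * exp(-k t)`, reported with its AIC next to the
#' single-exponential's for model comparison.
#'
#' @param course A `decay_course` tibble (columns `timepoint_min`,
#'   `abundance_pct`; replicates pooled). Must hold a single condition.
#' @param method `"log-linear"` (default) or `"nls"`.
#' @param model `"single"` (default) or `"plateau"` (forces `method =
#'   "nls"`).
#' @param conf_level Confidence level for the half-life interval.
#'
#' @return An object of class `decay_fit`: `k` (min^-1), `t_half` (min),
#'   `ci` (half-life interval), `plateau` (offset, when fitted), `aic`
#'   (named vector when models are compared), `r_squared` (on the fitted
#'   scale), `fit`, `data`. Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_decay <- function(course, method = c("log-linear", "nls"),
                      model = c("single", "plateau"), conf_level = 0.95) {
  method <- match.arg(method)
  model <- match.arg(model)
  course <- as_tibble(course)
  stopifnot(all(c("timepoint_min", "abundance_pct") %in% names(course)))
  if ("condition" %in% names(course) &&
    length(unique(course$condition)) > 1) {
    abort("`course` holds multiple conditions; fit them separately.",
      class = "degronmap_error_argument"
    )
  }
  if (length(unique(course$timepoint_min)) < 3) {
    abort("At least 3 timepoints are required.",
      class = "degronmap_error_fit"
    )
  }
  t <- course$timepoint_min
  ab <- course$abundance_pct
  plateau <- NA_real_
  aic <- NULL

  if (model == "plateau") method <- "nls"
  if (method == "log-linear") {
    pos <- ab > 0
    if (!all(pos)) {
      warn(sprintf("%d non-positive abundance value(s) dropped from log fit.",
        sum(!pos)))
    }
    lfit <- lm(log(ab[pos] / 100) ~ 0 + t[pos])
    k <- -unname(coef(lfit)[1])
    if (!is.finite(k) || k <= 0) {
      abort("No decay detected: estimated rate is not positive.",
        class = "degronmap_error_no_decay"
      )
    }
    # suppressed: summary.lm warns on exactly noiseless (zero-residual) input
    kci <- sort(-suppressWarnings(confint(lfit, level = conf_level))[1, ])
    r2 <- cor(lfit$fitted.values, log(ab[pos] / 100))^2
    fit_obj <- lfit
  } else {
    single <- minpack.lm::nlsLM(
      ab ~ 100 * exp(-k * t),
      start = list(k = log(2) / max(max(t) / 4, 1))
    )
    fit_obj <- single
    if (model == "plateau") {
      pl <- tryCatch(
        minpack.lm::nlsLM(
          ab ~ cc + (100 - cc) * exp(-k * t),
          start = list(cc = min(ab) / 2, k = unname(coef(single)["k"]))
        ),
        error = function(e) NULL
      )
      if (!is.null(pl)) {
        aic <- c(single = stats::AIC(single), plateau = stats::AIC(pl))
        fit_obj <- pl
        plateau <- unname(coef(pl)["cc"])
      } else {
        warn("Plateau model failed to converge; reporting single exponential.")
      }
    }
    k <- unname(coef(fit_obj)["k"])
    if (!is.finite(k) || k <= 0) {
      abort("No decay detected: estimated rate is not positive.",
        class = "degronmap_error_no_decay"
      )
    }
    sm <- summary(fit_obj)
    se <- sm$coefficients["k", "Std. Error"]
    tc <- qt(1 - (1 - conf_level) / 2, df = sm$df[2])
    kci <- sort(c(k - tc * se, k + tc * se))
    r2 <- cor(predict(fit_obj), ab)^2
  }

  kci <- pmax(kci, .Machine$double.eps)
  structure(
    list(
      k = k,
      t_half = log(2) / k,
      ci = tibble(
        term = "t_half",
        conf_low = log(2) / kci[2],
        conf_high = log(2) / kci[1]
      ),
      plateau = plateau,
      aic = aic,
      r_squared = r2,
      method = method,
      fit = fit_obj,
      data = course,
      conf_level = conf_level
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> t1/2 = %.3g min (k = %.3g /min, %s fit, n = %d)\n",
    x$t_half, x$k, x$method, nrow(x$data)
  ))
  invisible(x)
}

#' Compare protein stabilization across genotype and treatment
#'
#' Two-way ANOVA (genotype x treatment) on normalized protein levels,
#' with adjusted pairwise comparisons restricted to the interpretable
#' contrasts (cells sharing a genotype or a treatment). Tukey adjustment
#' (default) uses the studentized range over the full set of cell means,
#' matching `TukeyHSD` on the interaction; Bonferroni multiplies by the
#' number of selected contrasts. A design that reduces to two groups
#' falls back to Student's unpaired t test.
#'
#' @param data A data frame of normalized values.
#' @param value,genotype,treatment Column names (strings) holding the
#'   response and the two factors.
#' @param adjust `"tukey"` (default) or `"bonferroni"`.
#' @param alpha Significance level for the flags.
#'
#' @return A list of class `stabilization_test` with `anova` (term table
#'   with p-values; `NULL` for the two-group fallback), `pairwise`
#'   (selected contrasts with adjusted p-values and flags) and `method`.
#' @export
compare_stabilization <- function(data, value = "value",
                                  genotype = "genotype",
                                  treatment = "treatment",
                                  adjust = c("tukey", "bonferroni"),
                                  alpha = 0.05) {
  adjust <- match.arg(adjust)
  data <- as_tibble(data)
  stopifnot(all(c(value, genotype, treatment) %in% names(data)))
  d <- tibble(
    y = data[[value]],
    g = factor(data[[genotype]]),
    t = factor(data[[treatment]])
  )
  cells <- d |>
    group_by(.data$g, .data$t) |>
    summarise(
      n = dplyr::n(), mean = mean(.data$y),
      ss = sum((.data$y - mean(.data$y))^2), .groups = "drop"
    )
  full <- expand_grid(g = levels(d$g), t = levels(d$t))
  missing_cells <- dplyr::anti_join(
    full, cells |> mutate(g = as.character(.data$g), t = as.character(.data$t)),
    by = c("g", "t")
  )
  if (nrow(missing_cells) > 0) {
    abort(
      paste0(
        "Empty design cell(s): ",
        paste(missing_cells$g, missing_cells$t, sep = ":", collapse = ", ")
      ),
      class = "degronmap_error_design"
    )
  }
  if (any(cells$n < 2)) {
    abort("Every design cell needs at least 2 replicates.",
      class = "degronmap_error_design"
    )
  }

  if (nrow(cells) == 2) {
    tt <- stats::t.test(y ~ interaction(g, t, drop = TRUE),
      data = d, var.equal = TRUE
    )
    pw <- tibble(
      contrast = paste(
        levels(interaction(d$g, d$t, drop = TRUE)),
        collapse = " - "
      ),
      estimate = unname(diff(rev(tt$estimate))),
      p_adj = tt$p.value,
      significant = tt$p.value < alpha
    )
    return(structure(
      list(anova = NULL, pairwise = pw, method = "t-test"),
      class = "stabilization_test"
    ))
  }

  fit <- aov(y ~ g * t, data = d)
  an <- as.data.frame(summary(fit)[[1]])
  anova_tbl <- tibble(
    term = c("genotype", "treatment", "interaction", "residuals"),
    df = an$Df,
    statistic = an$`F value`,
    p_value = an$`Pr(>F)`
  ) |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)

  n_cells <- nrow(cells)
  df_res <- sum(cells$n) - n_cells
  mse <- sum(cells$ss) / df_res
  cells <- cells |> mutate(label = paste(.data$g, .data$t, sep = ":"))
  idx <- utils::combn(seq_len(n_cells), 2, simplify = FALSE)
  share <- vapply(
    idx,
    function(ij) {
      cells$g[ij[1]] == cells$g[ij[2]] || cells$t[ij[1]] == cells$t[ij[2]]
    },
    logical(1)
  )
  idx <- idx[share]
  pw <- map(idx, function(ij) {
    a <- cells[ij[1], ]
    b <- cells[ij[2], ]
    est <- b$mean - a$mean
    se <- sqrt(mse * (1 / a$n + 1 / b$n))
    tibble(
      contrast = paste(b$label, "-", a$label),
      estimate = est,
      se = se
    )
  }) |> list_rbind()
  if (adjust == "tukey") {
    q <- sqrt(2) * abs(pw$estimate) / pw$se
    pw$p_adj <- ptukey(q, nmeans = n_cells, df = df_res, lower.tail = FALSE)
  } else {
    p_raw <- 2 * pt(abs(pw$estimate) / pw$se, df = df_res, lower.tail = FALSE)
    pw$p_adj <- pmin(1, p_raw * nrow(pw))
  }
  pw$significant <- pw$p_adj < alpha

  structure(
    list(anova = anova_tbl, pairwise = pw, method = adjust),
    class = "stabilization_test"
  )
}

#' @export
print.stabilization_test <- function(x, ...) {
  cat("<stabilization_test>", x$method, "\n")
  if (!is.null(x$anova)) print(x$anova)
  print(x$pairwise)
  invisible(x)
}
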