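#' Configuration for the synthetic-data generators
#'
#' Bundles the seed, noise model and replicate structure shared by all
#' generators. The same seed and configuration always reproduce the same
#' dataset; each generator draws from its own substream of the seed so the
#' four assays are mutually independent but jointly reproducible.
#'
#' @param seed Integer seed, or `NULL` to use the ambient RNG state.
#' @param noise_model One of `"none"`, `"multiplicative-lognormal"` (mean-one
#'   lognormal factors; the default model for fluorescence and densitometry,
#'   which are positive and right-skewed) or `"additive-gaussian"` (zero-mean
#'   normal deviates in the units of the signal; the default model for SPR
#'   response units).
#' @param noise_scale Dimensionless coefficient of variation for the
#'   lognormal model, or the absolute standard deviation for the additive
#'   model. Must be >= 0.
#' @param n_replicates Number of replicate measurements per condition.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = NULL,
                             noise_model = c(
                               "none",
                               "multiplicative-lognormal",
                               "additive-gaussian"
                             ),
                             noise_scale = 0,
                             n_replicates = 3) {
  noise_model <- match.arg(noise_model)
  check_number(noise_scale, "noise_scale", non_negative = TRUE)
  check_number(n_replicates, "n_replicates", positive = TRUE)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(
      seed = if (is.null(seed)) NULL else as.integer(seed),
      noise_model = noise_model,
      noise_scale = noise_scale,
      n_replicates = as.integer(n_replicates)
    ),
    class = "generator_config"
  )
}

apply_noise <- function(expected, config) {
  switch(config$noise_model,
    "none" = expected,
    "multiplicative-lognormal" =
      expected * lognormal_factor(length(expected), config$noise_scale),
    "additive-gaussian" =
      expected + rnorm(length(expected), 0, config$noise_scale)
  )
}

#' Positional effect profile for a substitution/truncation array
#'
#' An effect profile is the ground truth behind a synthetic substitution
#' array: a multiplicative factor on the parent signal for every
#' (position, substituted residue) cell, plus a factor for every C-terminal
#' truncation. The factor at the parent residue of each position is 1 by
#' definition (the parent peptide is its own reference).
#'
#' @param parent_sequence Parent peptide as a string of one-letter codes.
#' @param position_offset Residue number of the first parent position
#'   (5 for the RGS2 degron, whose peptide spans residues 5-16).
#' @param effects Optional tibble/data frame with columns `position`,
#'   `residue`, `factor` overriding the default factor of 1. Factors must be
#'   finite and >= 0. Entries at a parent residue are forced back to 1 (with
#'   a warning if they differed).
#' @param truncation_effects Optional named numeric vector: names are the
#'   last retained position of each C-terminal truncation, values the
#'   multiplicative factor on the full-length signal.
#'
#' @return A list of class `effect_profile` with elements `parent_sequence`,
#'   `position_offset`, `positions`, `effect` (full position x residue
#'   tibble) and `truncation` (tibble with `last_retained`, `factor`).
#' @export
effect_profile <- function(parent_sequence,
                           position_offset = 5,
                           effects = NULL,
                           truncation_effects = NULL) {
  if (!is.character(parent_sequence) || length(parent_sequence) != 1 ||
    nchar(parent_sequence) == 0) {
    abort("`parent_sequence` must be a non-empty string.",
      class = "degronmap_error_argument"
    )
  }
  check_degron_spelling(parent_sequence)
  residues <- split_residues(parent_sequence)
  check_residues(residues, "parent_sequence")
  positions <- seq_along(residues) + position_offset - 1L
  parent_at <- setNames(residues, positions)

  grid <- expand_grid(position = positions, residue = amino_acids) |>
    mutate(factor = 1)
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    stopifnot(all(c("position", "residue", "factor") %in% names(effects)))
    check_residues(effects$residue, "effects")
    if (!all(effects$position %in% positions)) {
      abort("`effects` refers to positions outside the parent sequence.",
        class = "degronmap_error_argument"
      )
    }
    if (any(!is.finite(effects$factor)) || any(effects$factor < 0)) {
      abort("Effect factors must be finite and >= 0.",
        class = "degronmap_error_argument"
      )
    }
    grid <- grid |>
      left_join(
        effects |> rename(user_factor = "factor"),
        by = c("position", "residue")
      ) |>
      mutate(factor = dplyr::coalesce(.data$user_factor, .data$factor)) |>
      select(-"user_factor")
    is_parent <- grid$residue == parent_at[as.character(grid$position)]
    if (any(grid$factor[is_parent] != 1)) {
      warn("Parent-residue effect factors are fixed at 1; overriding.")
      grid$factor[is_parent] <- 1
    }
  }

  trunc <- tibble(last_retained = integer(), factor = double())
  if (!is.null(truncation_effects)) {
    lr <- as.integer(names(truncation_effects))
    if (any(is.na(lr)) || !all(lr %in% positions)) {
      abort("`truncation_effects` names must be parent positions.",
        class = "degronmap_error_argument"
      )
    }
    if (any(!is.finite(truncation_effects)) || any(truncation_effects < 0)) {
      abort("Truncation factors must be finite and >= 0.",
        class = "degronmap_error_argument"
      )
    }
    trunc <- tibble(
      last_retained = lr,
      factor = unname(truncation_effects)
    ) |>
      arrange(desc(.data$last_retained))
  }

  structure(
    list(
      parent_sequence = parent_sequence,
      position_offset = as.integer(position_offset),
      positions = positions,
      parent_at = parent_at,
      effect = grid,
      truncation = trunc
    ),
    class = "effect_profile"
  )
}

#' @export
print.effect_profile <- function(x, ...) {
  cat(
    "<effect_profile> parent", x$parent_sequence,
    sprintf(
      "(positions %d-%d), %d truncations\n",
      min(x$positions), max(x$positions), nrow(x$truncation)
    )
  )
  invisible(x)
}

#' Reference effect profile for the RGS2 degron
#'
#' Encodes the qualitative binding pattern of the RGS2 degron toward the
#' FBXO44 FBA domain as a ground-truth profile for simulation: positions
#' 5-10 (the hydrophobic N-terminal half) are inert; Cys13 is essential
#' (every substitution near-abolishes binding except Arg/Lys, which are
#' tolerated or enhancing, and the bulky Tyr/Trp, which are partially
#' tolerated); Asp12 substitutions all enhance binding, most strongly with
#' Arg/Lys; His11, Pro15 and Met16 show the milder mixed/charge effects;
#' and C-terminal truncations retain most signal down to Cys13 and lose
#' essentially all of it once Cys13 is removed.
#'
#' @return An [effect_profile()].
#' @export
rgs2_degron_profile <- function() {
  eff <- bind_rows(
    # Cys13: essential, except positive charges; Tyr/Trp partially tolerated
    tibble(
      position = 13L, residue = setdiff(amino_acids, c("C", "R", "K", "W", "Y")),
      factor = 0.02
    ),
    tibble(position = 13L, residue = c("R", "K"), factor = c(1.5, 1.3)),
    tibble(position = 13L, residue = c("W", "Y"), factor = 0.8),
    # Asp12: every substitution enhances, positive charges most
    tibble(
      position = 12L, residue = setdiff(amino_acids, c("D", "R", "K")),
      factor = 1.6
    ),
    tibble(position = 12L, residue = c("R", "K"), factor = 2.0),
    # His11: modest, H11R enhancement only
    tibble(position = 11L, residue = "R", factor = 1.5),
    # Arg14: A and W substitutions impair
    tibble(position = 14L, residue = c("A", "W"), factor = 0.6),
    # Pro15: flexible substitutions impair, Arg enhances
    tibble(position = 15L, residue = c("A", "G"), factor = 0.7),
    tibble(position = 15L, residue = "R", factor = 1.5),
    # Met16: positive charges enhance
    tibble(position = 16L, residue = c("R", "K"), factor = 1.4)
  )
  trunc <- setNames(
    c(1.0, 0.95, 0.92, 0.90, rep(0.02, 8)),
    as.character(16:5)
  )
  effect_profile(RGS2_DEGRON,
    position_offset = 5,
    effects = eff, truncation_effects = trunc
  )
}

#' Simulate a substitution/truncation peptide-array dataset
#'
#' Generates replicated fluorescence signals for every peptide of a
#' positional substitution scan (each position replaced by each of the 20
#' natural amino acids, the parent residue included as the in-cell
#' reference) plus every C-terminal truncation listed in the profile. The
#' expected signal of a peptide is `parent_signal` times its effect factor;
#' noise is applied per replicate according to `config`.
#'
#' @param profile An [effect_profile()].
#' @param parent_signal Expected fluorescence of the unmodified parent
#'   peptide, arbitrary units.
#' @param config A [generator_config()]. Additive-gaussian noise is clipped
#'   at zero, since fluorescence is non-negative.
#'
#' @return A tibble of class `substitution_array` with one row per replicate
#'   per peptide: `peptide_id`, `type` (`"substitution"`/`"truncation"`),
#'   `position`, `residue`, `last_retained`, `sequence`, `replicate`,
#'   `signal`. The array design is attached as attribute `design`.
#' @export
gen_array_signals <- function(profile, parent_signal = 1000,
                              config = generator_config()) {
  stopifnot(inherits(profile, "effect_profile"))
  check_number(parent_signal, "parent_signal", positive = TRUE)
  design <- array_design(
    parent_sequence = profile$parent_sequence,
    position_offset = profile$position_offset,
    truncations = profile$truncation$last_retained,
    warn_spelling = FALSE
  )
  peptides <- enumerate_peptides(design)
  subs <- peptides |>
    filter(.data$type == "substitution") |>
    left_join(profile$effect, by = c("position", "residue"))
  truncs <- peptides |>
    filter(.data$type == "truncation") |>
    left_join(profile$truncation, by = "last_retained")
  all_peps <- bind_rows(subs, truncs) |>
    mutate(expected = parent_signal * .data$factor)

  out <- with_substream(config$seed, 1L, {
    expand_grid(
      all_peps |> select(-"factor"),
      replicate = seq_len(config$n_replicates)
    ) |>
      mutate(signal = pmax(0, apply_noise(.data$expected, config))) |>
      select(-"expected")
  })
  new_substitution_array(out, design)
}

new_substitution_array <- function(data, design) {
  structure(
    as_tibble(data),
    design = design,
    class = c("substitution_array", class(as_tibble(data)))
  )
}

#' Default SPR analyte concentration series
#'
#' Two-fold dilution series of nine concentrations starting at 0.29 uM,
#' reaching ~75 uM at the top, matching the span over which the degron
#' peptide/FBA-domain interaction was titrated.
#'
#' @return Numeric vector (uM), strictly increasing.
#' @export
spr_concentration_series <- function() 0.29 * 2^(0:8)

#' Simulate a two-channel SPR equilibrium binding isotherm
#'
#' Emulates equilibrium response units from a two-flow-cell SPR experiment:
#' the reference channel (Fc1, blank surface) sees only linear nonspecific
#' binding, the measurement channel (Fc2, ligand-coupled surface) sees a
#' one-site Langmuir isotherm on top of the same nonspecific term:
#' `R(C) = Bmax * C / (Kd + C) + slope * C`.
#'
#' @param kd Equilibrium dissociation constant, uM. Must be > 0.
#' @param bmax Saturating specific response, RU. Must be > 0.
#' @param conc_series Analyte concentrations, uM, strictly positive;
#'   defaults to [spr_concentration_series()].
#' @param nonspecific_slope Linear nonspecific response, RU per uM.
#' @param config A [generator_config()]; additive-gaussian `noise_scale` is
#'   in RU, lognormal is relative.
#'
#' @return A tibble of class `binding_isotherm` with columns
#'   `concentration_uM`, `ru_reference`, `ru_measurement`.
#' @export
gen_isotherm <- function(kd, bmax, conc_series = spr_concentration_series(),
                         nonspecific_slope = 0,
                         config = generator_config()) {
  check_number(kd, "kd", positive = TRUE)
  check_number(bmax, "bmax", positive = TRUE)
  check_number(nonspecific_slope, "nonspecific_slope", non_negative = TRUE)
  if (any(!is.finite(conc_series)) || any(conc_series <= 0)) {
    abort("All concentrations must be positive and finite.",
      class = "degronmap_error_argument"
    )
  }
  conc_series <- sort(conc_series)
  specific <- bmax * conc_series / (kd + conc_series)
  nonspecific <- nonspecific_slope * conc_series
  out <- with_substream(config$seed, 3L, {
    tibble(
      concentration_uM = conc_series,
      ru_reference = apply_noise(nonspecific, config),
      ru_measurement = apply_noise(specific + nonspecific, config)
    )
  })
  structure(out, class = c("binding_isotherm", class(out)))
}

#' Simulate a translation-arrest (cycloheximide chase) decay course
#'
#' Protein abundance after blocking translation decays as a single
#' exponential, `N(t) = 100 * 2^(-t / t_half)` percent of the starting
#' level. Noise is applied per replicate and timepoint, after which each
#' replicate is renormalized so that its t = 0 value is exactly 100%
#' (mirroring how densitometry courses are anchored to their own zero-time
#' band).
#'
#' @param t_half Half-life in minutes. Must be > 0.
#' @param timepoints Chase timepoints in minutes; must include 0.
#' @param config A [generator_config()].
#' @param condition Condition label carried through to the output.
#'
#' @return A tibble of class `decay_course` with columns `condition`,
#'   `timepoint_min`, `replicate`, `abundance_pct`.
#' @export
gen_chase <- function(t_half, timepoints = c(0, 10, 20, 30, 45, 60),
                      config = generator_config(), condition = "WT") {
  check_number(t_half, "t_half", positive = TRUE)
  if (!0 %in% timepoints) {
    abort("`timepoints` must include 0 (the normalization anchor).",
      class = "degronmap_error_argument"
    )
  }
  timepoints <- sort(unique(timepoints))
  out <- with_substream(config$seed, 4L, {
    expand_grid(
      replicate = seq_len(config$n_replicates),
      timepoint_min = timepoints
    ) |>
      mutate(
        expected = 100 * 2^(-.data$timepoint_min / t_half),
        raw = pmax(.Machine$double.eps, apply_noise(.data$expected, config))
      ) |>
      group_by(.data$replicate) |>
      mutate(
        abundance_pct =
          100 * .data$raw / .data$raw[.data$timepoint_min == 0]
      ) |>
      ungroup() |>
      mutate(condition = condition) |>
      select("condition", "timepoint_min", "replicate", "abundance_pct")
  })
  structure(out, class = c("decay_course", class(out)))
}
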