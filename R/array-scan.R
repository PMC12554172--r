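#' Design of a positional substitution/truncation peptide array
#'
#' Describes the layout of a substitution-scan array: the parent peptide,
#' its residue numbering, the 20-letter substitution alphabet and the list
#' of C-terminal truncations printed on the array.
#'
#' @param parent_sequence Parent peptide, one-letter codes.
#' @param position_offset Residue number of the first parent position.
#' @param alphabet Substitution alphabet; must be the 20 natural amino
#'   acids (subsets are rejected so every position carries a full column).
#' @param truncations Last retained positions of the C-terminal truncation
#'   series, in any order; stored strictly decreasing from full length.
#' @param warn_spelling Internal; set `FALSE` to skip the degron-spelling
#'   check when the sequence was already validated upstream.
#'
#' @return A list of class `array_design`.
#' @export
array_design <- function(parent_sequence, position_offset = 5,
                         alphabet = amino_acids, truncations = integer(),
                         warn_spelling = TRUE) {
  if (!is.character(parent_sequence) || length(parent_sequence) != 1 ||
    nchar(parent_sequence) == 0) {
    abort("`parent_sequence` must be a non-empty string.",
      class = "degronmap_error_argument"
    )
  }
  if (warn_spelling) check_degron_spelling(parent_sequence)
  residues <- split_residues(parent_sequence)
  check_residues(residues, "parent_sequence")
  if (!setequal(alphabet, amino_acids)) {
    abort("`alphabet` must be exactly the 20 natural amino acids.",
      class = "degronmap_error_residue"
    )
  }
  positions <- seq_along(residues) + as.integer(position_offset) - 1L
  truncations <- sort(unique(as.integer(truncations)), decreasing = TRUE)
  if (length(truncations) > 0 &&
    (any(!truncations %in% positions))) {
    abort("`truncations` must be last-retained positions within the parent.",
      class = "degronmap_error_argument"
    )
  }
  structure(
    list(
      parent_sequence = parent_sequence,
      position_offset = as.integer(position_offset),
      positions = positions,
      parent_at = setNames(residues, positions),
      alphabet = amino_acids,
      truncations = truncations
    ),
    class = "array_design"
  )
}

#' @export
print.array_design <- function(x, ...) {
  cat(
    "<array_design>", x$parent_sequence,
    sprintf(
      "positions %d-%d, %d truncations\n",
      min(x$positions), max(x$positions), length(x$truncations)
    )
  )
  invisible(x)
}

design_of <- function(data, what = "dataset") {
  design <- attr(data, "design")
  if (is.null(design)) {
    abort(
      paste0(
        "The ", what, " carries no array design; attach one with ",
        "`array_design()` via the `design` attribute."
      ),
      class = "degronmap_error_argument"
    )
  }
  design
}

#' Enumerate the peptides printed on a substitution/truncation array
#'
#' Expands an [array_design()] into one row per peptide: a substitution
#' peptide for every (position, residue) pair of the alphabet — the parent
#' residue included, since the unmodified parent peptide is repeated as the
#' in-cell reference of each column — plus one truncated peptide per entry
#' of the truncation series.
#'
#' @param design An [array_design()].
#' @return A tibble with columns `peptide_id`, `type`, `position`,
#'   `residue`, `last_retained`, `sequence`.
#' @export
enumerate_peptides <- function(design) {
  stopifnot(inherits(design, "array_design"))
  parent <- split_residues(design$parent_sequence)
  off <- design$position_offset

  subs <- expand_grid(
    position = design$positions,
    residue = design$alphabet
  ) |>
    mutate(
      parent_residue = parent[.data$position - off + 1],
      sequence = map2(
        .data$position, .data$residue,
        function(p, r) {
          s <- parent
          s[p - off + 1] <- r
          paste(s, collapse = "")
        }
      ) |> unlist(),
      peptide_id = paste0(.data$parent_residue, .data$position, .data$residue),
      type = "substitution",
      last_retained = NA_integer_
    ) |>
    select(
      "peptide_id", "type", "position", "residue", "last_retained", "sequence"
    )

  truncs <- tibble(last_retained = design$truncations) |>
    mutate(
      sequence = map_dbl(.data$last_retained, ~ .x - off + 1) |>
        vapply(function(k) paste(parent[seq_len(k)], collapse = ""), ""),
      peptide_id = paste0("trunc", .data$last_retained),
      type = "truncation",
      position = NA_integer_,
      residue = NA_character_
    ) |>
    select(
      "peptide_id", "type", "position", "residue", "last_retained", "sequence"
    )

  bind_rows(subs, truncs)
}

validate_array <- function(data) {
  needed <- c("type", "position", "residue", "replicate", "signal")
  if (!all(needed %in% names(data))) {
    abort(
      paste0(
        "A substitution array dataset needs columns: ",
        paste(needed, collapse = ", ")
      ),
      class = "degronmap_error_array"
    )
  }
  if (any(data$signal < 0, na.rm = TRUE)) {
    abort("Array signals must be >= 0.", class = "degronmap_error_array")
  }
  invisible(data)
}

# Per-replicate parent-normalized substitution values (percent of parent).
normalized_values <- function(data, design) {
  parents <- data |>
    filter(.data$type == "substitution") |>
    filter(.data$residue == unname(design$parent_at[as.character(.data$position)])) |>
    select("position", "replicate", parent_signal = "signal")
  data |>
    filter(.data$type == "substitution") |>
    left_join(parents, by = c("position", "replicate")) |>
    mutate(norm_pct = 100 * .data$signal / .data$parent_signal)
}

#' Normalize array signals to the parent residue of each position
#'
#' Converts replicated fluorescence signals into percent-of-parent values,
#' position by position. The default `"replicate"` method divides each
#' replicate by the parent-peptide signal of the same replicate at that
#' position before averaging, which makes the result invariant to global
#' per-replicate intensity scaling and pins the parent cell at exactly
#' 100% (sd 0). The `"pooled"` method takes the ratio of cell mean to
#' parent mean instead, so the parent cell's sd reflects its own replicate
#' scatter but scale invariance is lost.
#'
#' @param data A `substitution_array` tibble (see [gen_array_signals()]);
#'   must carry an `array_design` attribute.
#' @param method `"replicate"` (default) or `"pooled"`; see Details.
#' @param parent_floor Positions whose mean parent signal is at or below
#'   this floor are rejected with a named error (division by a vanishing
#'   reference).
#'
#' @return A tibble of class `normalized_matrix` with one row per
#'   (position, residue): `mean_pct`, `sd_pct`, `n`. The design is carried
#'   in the `design` attribute.
#' @export
normalize_to_parent <- function(data, method = c("replicate", "pooled"),
                                parent_floor = 0) {
  method <- match.arg(method)
  validate_array(data)
  design <- design_of(data)

  parent_means <- data |>
    filter(.data$type == "substitution") |>
    filter(.data$residue == unname(design$parent_at[as.character(.data$position)])) |>
    group_by(.data$position) |>
    summarise(parent_mean = mean(.data$signal), .groups = "drop")
  low <- parent_means |> filter(.data$parent_mean <= parent_floor)
  if (nrow(low) > 0) {
    abort(
      paste0(
        "Parent signal at or below the floor (", parent_floor,
        ") at position(s): ", paste(low$position, collapse = ", "),
        "; cannot normalize."
      ),
      class = "degronmap_error_parent_signal"
    )
  }

  out <- if (method == "replicate") {
    normalized_values(data, design) |>
      group_by(.data$position, .data$residue) |>
      summarise(
        mean_pct = mean(.data$norm_pct),
        sd_pct = sd(.data$norm_pct),
        n = dplyr::n(),
        .groups = "drop"
      )
  } else {
    data |>
      filter(.data$type == "substitution") |>
      left_join(parent_means, by = "position") |>
      group_by(.data$position, .data$residue) |>
      summarise(
        mean_pct = 100 * mean(.data$signal) / first(.data$parent_mean),
        sd_pct = sd(100 * .data$signal / .data$parent_mean),
        n = dplyr::n(),
        .groups = "drop"
      )
  }
  out <- out |> mutate(sd_pct = dplyr::coalesce(.data$sd_pct, 0))
  structure(out,
    design = design,
    class = c("normalized_matrix", class(out))
  )
}

#' Test substitution effects against the parent residue
#'
#' Two-way (position x substituted residue) analysis of the
#' parent-normalized replicate values, followed by Tukey-adjusted simple
#' effects within each position: every substitution is compared with the
#' parent residue of its column. The Tukey correction uses the full
#' 20-mean family of each position, and the pooled within-cell mean square
#' of the two-way cell-means model, so the calls match a standard two-way
#' ANOVA with Tukey's post hoc restricted to parent contrasts.
#'
#' With fewer than two replicates in any cell the test is refused: a
#' descriptive table (estimates only, no p-values) is returned with a
#' warning.
#'
#' @param data A `substitution_array` tibble.
#' @param alpha Significance level; default 0.05.
#' @param on `"normalized"` (default; percent-of-parent replicate values)
#'   or `"raw"` fluorescence.
#'
#' @return A tibble of class `significance_table` with one row per
#'   (position, residue): `estimate` (mean difference from parent, in the
#'   units analysed), `direction` (`"increase"`/`"decrease"`; `NA` at the
#'   parent), `p_adj`, `significant`. Attribute `alpha` records the level.
#' @export
test_substitution_effects <- function(data, alpha = 0.05,
                                      on = c("normalized", "raw")) {
  on <- match.arg(on)
  validate_array(data)
  design <- design_of(data)

  values <- if (on == "normalized") {
    normalized_values(data, design) |> mutate(value = .data$norm_pct)
  } else {
    data |>
      filter(.data$type == "substitution") |>
      mutate(value = .data$signal)
  }

  cells <- values |>
    group_by(.data$position, .data$residue) |>
    summarise(
      mean = mean(.data$value),
      ss = sum((.data$value - mean(.data$value))^2),
      n = dplyr::n(),
      .groups = "drop"
    )

  parent_cells <- cells |>
    filter(.data$residue == unname(design$parent_at[as.character(.data$position)])) |>
    select("position", parent_mean = "mean", parent_n = "n")
  out <- cells |>
    left_join(parent_cells, by = "position") |>
    mutate(
      is_parent =
        .data$residue == unname(design$parent_at[as.character(.data$position)]),
      estimate = .data$mean - .data$parent_mean,
      direction = dplyr::case_when(
        is_parent ~ NA_character_,
        estimate >= 0 ~ "increase",
        TRUE ~ "decrease"
      )
    )

  if (any(cells$n < 2)) {
    warn(paste(
      "At least one cell has a single replicate;",
      "significance testing refused, returning descriptive table."
    ))
    out <- out |>
      mutate(p_adj = NA_real_, significant = NA)
  } else {
    n_total <- sum(cells$n)
    df <- n_total - nrow(cells)
    mse <- sum(cells$ss) / df
    k <- length(design$alphabet)
    se <- sqrt(mse * (1 / out$n + 1 / out$parent_n))
    q <- sqrt(2) * abs(out$estimate) / se
    p <- ifelse(
      out$estimate == 0,
      1,
      ifelse(
        se == 0,
        0, # zero residual variance but a real difference
        ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      )
    )
    out <- out |>
      mutate(
        p_adj = ifelse(.data$is_parent, NA_real_, p),
        significant = !.data$is_parent & !is.na(p) & p < alpha
      )
  }

  out <- out |>
    select(
      "position", "residue", "estimate", "direction", "p_adj", "significant"
    ) |>
    arrange(.data$position, .data$residue)
  structure(out,
    design = design, alpha = alpha, on = on,
    class = c("significance_table", class(out))
  )
}

#' Classify array positions by their substitution tolerance
#'
#' Applies the field's reading of a substitution scan to each position:
#'
#' * **essential** — at least `essential_fraction` of the non-parent
#'   substitutions (Arg and Lys exempted, since positive charges can rescue
#'   binding through unrelated electrostatics) fall below `essential_floor`
#'   percent of parent *and* are significant decreases;
#' * **charge-enhanced** — Arg and/or Lys substitutions are significant
#'   increases and no substitution is a significant decrease;
#' * **mixed** — significant effects in both directions (or significant
#'   decreases short of the essential rule);
#' * **tolerant** — no significant effects.
#'
#' @param matrix A `normalized_matrix` from [normalize_to_parent()].
#' @param table A `significance_table` from [test_substitution_effects()]
#'   computed on the same design.
#' @param essential_floor Percent-of-parent threshold under which a
#'   substitution counts as abolishing binding (default 20).
#' @param essential_fraction Fraction of countable substitutions that must
#'   fall below the floor for an essential call (default 0.8).
#'
#' @return A tibble with one row per position: `position`,
#'   `parent_residue`, `category`, `frac_below_floor`,
#'   `n_flagged_decrease`, `n_flagged_increase`.
#' @export
classify_positions <- function(matrix, table, essential_floor = 20,
                               essential_fraction = 0.8) {
  d1 <- design_of(matrix, "normalized matrix")
  d2 <- design_of(table, "significance table")
  if (!identical(d1$parent_sequence, d2$parent_sequence) ||
    !identical(d1$position_offset, d2$position_offset)) {
    abort("Matrix and significance table come from different designs.",
      class = "degronmap_error_argument"
    )
  }
  joined <- as_tibble(matrix) |>
    left_join(
      as_tibble(table) |> select(-dplyr::any_of("estimate")),
      by = c("position", "residue")
    ) |>
    mutate(
      parent_residue = unname(d1$parent_at[as.character(.data$position)]),
      is_parent = .data$residue == .data$parent_residue,
      charged = .data$residue %in% c("R", "K")
    )

  joined |>
    filter(!.data$is_parent) |>
    group_by(.data$position, .data$parent_residue) |>
    summarise(
      frac_below_floor = {
        countable <- !.data$charged
        sum(countable & .data$mean_pct < essential_floor &
          .data$significant & .data$direction == "decrease", na.rm = TRUE) /
          sum(countable)
      },
      n_flagged_decrease = sum(
        .data$significant & .data$direction == "decrease",
        na.rm = TRUE
      ),
      n_flagged_increase = sum(
        .data$significant & .data$direction == "increase",
        na.rm = TRUE
      ),
      charge_enhanced = any(
        .data$charged & .data$significant & .data$direction == "increase",
        na.rm = TRUE
      ),
      .groups = "drop"
    ) |>
    mutate(
      category = dplyr::case_when(
        frac_below_floor >= essential_fraction ~ "essential",
        charge_enhanced & n_flagged_decrease == 0 ~ "charge-enhanced",
        n_flagged_decrease + n_flagged_increase > 0 ~ "mixed",
        TRUE ~ "tolerant"
      )
    ) |>
    select(
      "position", "parent_residue", "category", "frac_below_floor",
      "n_flagged_decrease", "n_flagged_increase"
    ) |>
    arrange(.data$position)
}

#' Locate the truncation boundary of a degron
#'
#' Scans the C-terminal truncation series from the full-length peptide
#' downwards and returns the most C-terminal position whose removal drops
#' the mean signal below `loss_threshold` percent of the full-length
#' (parent) signal: the boundary is `last_retained + 1` of the first
#' below-threshold truncation.
#'
#' @param data A `substitution_array` tibble containing truncation peptides.
#' @param loss_threshold Percent of full-length signal; default 20.
#'
#' @return A list of class `truncation_scan` with `boundary` (integer
#'   position, or `NA` if no truncation crosses the threshold),
#'   `loss_threshold`, and `profile`, a tibble of per-truncation mean
#'   signals and percent of full length.
#' @export
truncation_boundary <- function(data, loss_threshold = 20) {
  validate_array(data)
  design <- design_of(data)
  truncs <- data |> filter(.data$type == "truncation")
  if (nrow(truncs) == 0) {
    abort("No truncation peptides present in the dataset.",
      class = "degronmap_error_argument"
    )
  }
  full_ref <- data |>
    filter(
      .data$type == "substitution",
      .data$residue == unname(design$parent_at[as.character(.data$position)])
    ) |>
    pull(.data$signal) |>
    mean()

  profile <- truncs |>
    group_by(.data$last_retained) |>
    summarise(mean_signal = mean(.data$signal), .groups = "drop") |>
    mutate(pct_of_full = 100 * .data$mean_signal / full_ref) |>
    arrange(desc(.data$last_retained))

  below <- profile |> filter(.data$pct_of_full < loss_threshold)
  boundary <- if (nrow(below) == 0) {
    NA_integer_
  } else {
    max(below$last_retained) + 1L
  }
  structure(
    list(
      boundary = boundary,
      loss_threshold = loss_threshold,
      profile = profile
    ),
    class = "truncation_scan"
  )
}

#' @export
print.truncation_scan <- function(x, ...) {
  if (is.na(x$boundary)) {
    cat(
      "<truncation_scan> no boundary in range (no truncation fell below",
      paste0(x$loss_threshold, "% of full-length signal)\n")
    )
  } else {
    cat(
      "<truncation_scan> boundary at position", x$boundary,
      sprintf("(signal lost below %g%% once removed)\n", x$loss_threshold)
    )
  }
  print(x$profile)
  invisible(x)
}
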