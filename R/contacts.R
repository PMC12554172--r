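#' Parameters for trajectory contact analysis
#'
#' @param cutoff_nm C-alpha/C-alpha distance below which two residues are
#'   in contact. The comparison is strict: a pair at exactly the cutoff is
#'   *not* in contact. Default 0.8 nm.
#' @param burn_in Number of initial frames discarded from every trial
#'   before contact counting, while the system relaxes from its starting
#'   conformation. Default 500 frames; must be smaller than the trial
#'   length at analysis time.
#'
#' @return A list of class `contact_params`.
#' @export
contact_params <- function(cutoff_nm = 0.8, burn_in = 500) {
  check_number(cutoff_nm, "cutoff_nm", positive = TRUE)
  check_number(burn_in, "burn_in", non_negative = TRUE)
  structure(
    list(cutoff_nm = cutoff_nm, burn_in = as.integer(burn_in)),
    class = "contact_params"
  )
}

#' Trial-averaged residue contact-frequency map
#'
#' For every cross-chain residue pair, the fraction of retained frames in
#' which the two C-alpha atoms lie within the cutoff is computed per trial
#' and then averaged over trials, giving a score normalized from 0 (never
#' in contact) to 1 (in contact continuously over all trials). With equal
#' frame counts per trial this trial-then-average order equals pooling all
#' frames directly.
#'
#' @param ensemble A `trajectory_ensemble` tibble.
#' @param pose Which pose to analyse.
#' @param params A [contact_params()]. `burn_in` must be smaller than the
#'   number of frames in every trial.
#'
#' @return A tibble of class `contact_map` with columns `receptor_resno`,
#'   `peptide_resno`, `frequency`.
#' @export
contact_frequency <- function(ensemble, pose = 1, params = contact_params()) {
  validate_ensemble(ensemble)
  sub <- ensemble |> filter(.data$pose == !!pose)
  if (nrow(sub) == 0) {
    abort("No frames for the requested pose.",
      class = "degronmap_error_argument"
    )
  }
  trials <- sort(unique(sub$trial))
  per_trial <- map(trials, function(tr) {
    d <- sub |> filter(.data$trial == tr)
    frames <- sort(unique(d$frame))
    if (params$burn_in >= length(frames)) {
      abort(
        sprintf(
          "burn_in (%d) must be smaller than the trial length (%d frames).",
          params$burn_in, length(frames)
        ),
        class = "degronmap_error_burnin"
      )
    }
    keep <- frames[(params$burn_in + 1):length(frames)]
    d <- d |> filter(.data$frame %in% keep)
    chain_mats <- function(ch) {
      cd <- d |>
        filter(.data$chain == ch) |>
        arrange(.data$resno, .data$frame)
      res <- sort(unique(cd$resno))
      nf <- length(keep)
      list(
        res = res,
        x = matrix(cd$x, nrow = nf),
        y = matrix(cd$y, nrow = nf),
        z = matrix(cd$z, nrow = nf)
      )
    }
    rec <- chain_mats("receptor")
    pep <- chain_mats("peptide")
    grid <- expand_grid(
      receptor_resno = rec$res,
      peptide_resno = pep$res
    )
    grid$frequency <- pmap(
      list(
        match(grid$receptor_resno, rec$res),
        match(grid$peptide_resno, pep$res)
      ),
      function(i, j) {
        d2 <- (rec$x[, i] - pep$x[, j])^2 +
          (rec$y[, i] - pep$y[, j])^2 +
          (rec$z[, i] - pep$z[, j])^2
        mean(d2 < params$cutoff_nm^2)
      }
    ) |> unlist()
    grid
  })
  out <- list_rbind(per_trial) |>
    group_by(.data$receptor_resno, .data$peptide_resno) |>
    summarise(frequency = mean(.data$frequency), .groups = "drop")
  structure(out,
    pose = pose, params = params,
    class = c("contact_map", class(out))
  )
}

#' Convert a contact map to a receptor x peptide matrix
#'
#' @param cmap A `contact_map` from [contact_frequency()].
#' @return A numeric matrix, receptor residues in rows, peptide residues
#'   in columns.
#' @export
contact_matrix <- function(cmap) {
  wide <- cmap |>
    pivot_wider(
      names_from = "peptide_resno", values_from = "frequency",
      names_sort = TRUE
    ) |>
    arrange(.data$receptor_resno)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$receptor_resno
  m
}

#' Detect the burn-in plateau of an RMSD series
#'
#' Optional alternative to a fixed burn-in: the first frame at which a
#' rolling mean of the RMSD changes by less than a relative tolerance over
#' one window. The fixed discard remains the default throughout the
#' package because it is reproducible across ensembles.
#'
#' @param series An `rmsd_series` tibble.
#' @param window Rolling-window width in frames (default 50).
#' @param tol Relative change threshold (default 0.05).
#' @return Integer frame index (a burn-in length), or the window width if
#'   no plateau is found.
#' @export
detect_burn_in <- function(series, window = 50, tol = 0.05) {
  x <- series$rmsd_nm
  if (length(x) <= 2 * window) {
    return(as.integer(min(window, length(x) - 1)))
  }
  roll <- vapply(
    seq_len(length(x) - window + 1),
    function(i) mean(x[i:(i + window - 1)]),
    numeric(1)
  )
  rel <- abs(diff(roll, lag = window)) / pmax(abs(roll[seq_along(diff(roll, lag = window))]), 1e-12)
  idx <- which(rel < tol)
  if (length(idx) == 0) as.integer(window) else as.integer(idx[1])
}

#' Rank docked poses by trajectory stability
#'
#' Scores each pose of an ensemble by the time-mean of its trial-averaged
#' peptide RMSD (drift from the starting conformation) and the time-mean
#' of the across-trial RMSD variance, ranking ascending lexicographically
#' (smallest drift first, variance breaking drift ties). Remaining ties
#' are broken by the largest contact-map entry, descending, then by pose
#' label.
#'
#' @param ensemble A `trajectory_ensemble` tibble.
#' @param selection Atom selection for the RMSD (default `"peptide"`, the
#'   binding-stability readout).
#' @param burn_in Frames discarded before averaging (both RMSD and
#'   contacts); default 0, since the synthetic ensembles start relaxed.
#' @param cutoff_nm Contact cutoff for the tie-break statistic.
#'
#' @return A tibble with one row per pose, ranked: `rank`, `pose`,
#'   `drift_nm` (time-mean RMSD), `variance_nm2`, `max_contact`.
#' @export
rank_pose_stability <- function(ensemble, selection = "peptide",
                                burn_in = 0, cutoff_nm = 0.8) {
  validate_ensemble(ensemble)
  poses <- sort(unique(ensemble$pose))
  stats <- map(poses, function(p) {
    trials <- sort(unique(ensemble$trial[ensemble$pose == p]))
    series <- map(
      trials,
      ~ rmsd_series(ensemble, pose = p, trial = .x, selection = selection)
    )
    agg <- suppressWarnings(aggregate_rmsd(series))
    if (burn_in > 0) agg <- agg |> filter(.data$frame > burn_in)
    cmap <- contact_frequency(
      ensemble,
      pose = p,
      params = contact_params(cutoff_nm = cutoff_nm, burn_in = burn_in)
    )
    tibble(
      pose = p,
      drift_nm = mean(agg$mean_rmsd_nm),
      variance_nm2 = mean(agg$var_rmsd_nm2),
      max_contact = if (nrow(cmap) > 0) max(cmap$frequency) else 0
    )
  }) |> list_rbind()
  rank_pose_table(stats)
}

#' Rank a table of per-pose stability statistics
#'
#' The ordering applied by [rank_pose_stability()], exposed for
#' precomputed summaries: ascending lexicographic on
#' (`drift_nm`, `variance_nm2`), remaining ties broken by `max_contact`
#' descending, then by pose label.
#'
#' @param stats A tibble with columns `pose`, `drift_nm`, `variance_nm2`
#'   and optionally `max_contact` (taken as 0 when absent).
#' @return The table ranked, with a `rank` column first.
#' @export
rank_pose_table <- function(stats) {
  stats <- as_tibble(stats)
  stopifnot(all(c("pose", "drift_nm", "variance_nm2") %in% names(stats)))
  if (!"max_contact" %in% names(stats)) stats$max_contact <- 0
  stats |>
    arrange(.data$drift_nm, .data$variance_nm2, desc(.data$max_contact),
      .data$pose) |>
    mutate(rank = row_number(), .before = 1)
}
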