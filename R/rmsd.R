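#' Per-frame RMSD of a trajectory against its starting conformation
#'
#' Computes the root-mean-square deviation of each frame from the first
#' frame of the trial (the conformation at the start of the production
#' run), after optimal superposition on the selected C-alpha atoms. The
#' selection itself is both fit and measured: `"peptide"` superposes and
#' scores the peptide chain, `"complex"` both chains pooled.
#'
#' @param ensemble A `trajectory_ensemble` tibble (see
#'   [gen_trajectories()] or the readers in [read_frames_table()]).
#' @param pose,trial Which pose and trial to extract.
#' @param selection `"peptide"` or `"complex"`.
#'
#' @return A tibble of class `rmsd_series` with columns `frame`, `time_ps`
#'   (from the ensemble's frame spacing) and `rmsd_nm`.
#' @export
rmsd_series <- function(ensemble, pose = 1, trial = 1,
                        selection = c("peptide", "complex")) {
  selection <- match.arg(selection)
  validate_ensemble(ensemble)
  chains <- if (selection == "peptide") "peptide" else c("receptor", "peptide")
  sel <- ensemble |>
    filter(
      .data$pose == !!pose, .data$trial == !!trial,
      .data$chain %in% chains
    ) |>
    arrange(.data$frame, .data$chain, .data$resno)
  if (nrow(sel) == 0) {
    abort("No frames for the requested pose/trial.",
      class = "degronmap_error_argument"
    )
  }
  frames <- sort(unique(sel$frame))
  n_atoms <- nrow(sel) / length(frames)
  coords <- array(
    t(as.matrix(sel[, c("x", "y", "z")])),
    dim = c(3, n_atoms, length(frames))
  )
  ref <- t(coords[, , 1])
  rmsd <- vapply(
    seq_along(frames),
    function(i) kabsch_rmsd(t(coords[, , i]), ref),
    numeric(1)
  )
  spacing <- attr(ensemble, "frame_spacing_ps") %||% NA_real_
  out <- tibble(
    frame = frames,
    time_ps = (frames - frames[1]) * spacing,
    rmsd_nm = rmsd
  )
  structure(out,
    selection = selection, pose = pose, trial = trial,
    class = c("rmsd_series", class(out))
  )
}

#' Aggregate RMSD series over simulation trials
#'
#' Pointwise mean and variance of per-trial RMSD series, as plotted for
#' trajectory stability summaries (mean line, variance band). The variance
#' is the population variance across trials (divide by the number of
#' trials), so a single trial yields zero variance.
#'
#' @param series A list of `rmsd_series` tibbles (one per trial), or a
#'   single tibble with a `trial` column and `frame`/`rmsd_nm` columns.
#'   Series of unequal length are truncated to the shortest with a
#'   warning.
#'
#' @return A tibble with columns `frame`, `mean_rmsd_nm`, `var_rmsd_nm2`,
#'   `n_trials`.
#' @export
aggregate_rmsd <- function(series) {
  if (is.data.frame(series)) {
    if (!"trial" %in% names(series)) {
      series <- list(series)
    } else {
      series <- split(series, series$trial)
    }
  }
  if (length(series) == 0) {
    abort("At least one RMSD series is required.",
      class = "degronmap_error_argument"
    )
  }
  lens <- vapply(series, nrow, integer(1))
  if (length(unique(lens)) > 1) {
    warn("RMSD series have unequal lengths; truncating to the shortest.")
    series <- map(series, ~ head(.x, min(lens)))
  }
  if (length(series) == 1) {
    warn("Single trial: variance is identically zero.")
  }
  m <- vapply(series, function(s) s$rmsd_nm, numeric(min(lens)))
  m <- matrix(m, nrow = min(lens))
  tibble(
    frame = series[[1]]$frame[seq_len(min(lens))],
    mean_rmsd_nm = rowMeans(m),
    var_rmsd_nm2 = apply(m, 1, function(x) mean((x - mean(x))^2)),
    n_trials = length(series)
  )
}
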