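#' Simulate a multi-pose, multi-trial two-chain trajectory ensemble
#'
#' Builds kinematic C-alpha trajectories of a receptor/peptide complex with
#' prescribed per-residue-pair contact occupancies and, optionally, a
#' planted per-pose conformational drift. These are not physical
#' simulations: the receptor stays rigid, each listed peptide residue
#' toggles between an in-contact placement (0.5 nm from its receptor
#' partner) and an out-of-contact placement (1.5 nm), and every unlisted
#' cross-chain pair stays at least 1.2 nm apart by construction.
#'
#' Contact realization: with `noise_model = "none"` the first
#' `ceiling(f * n_frames)` frames of each trial are in contact (so the
#' realized pooled fraction matches the target within `1/n_frames`);
#' otherwise the in-contact frames are a random subset of size
#' `round(f * n_frames)` per trial.
#'
#' Drift realization: `drift` (nm, recycled over poses) plants a non-rigid
#' radial dilation of the peptide about its centroid that grows linearly
#' over frames, calibrated so the superposition RMSD of the peptide against
#' frame 1 equals exactly `drift` at the final frame. (A rigid displacement
#' would vanish under superposition, so drift must deform the chain.) With
#' lognormal noise the per-trial drift magnitude is scattered around the
#' pose value, giving trial-to-trial RMSD variance. Contact-occupancy
#' guarantees hold exactly only at `drift = 0`, since the dilation moves
#' peptide residues relative to the receptor.
#'
#' @param n_poses,n_trials,n_frames Ensemble dimensions; `n_frames >= 1`.
#' @param occupancy Optional tibble with columns `receptor_resno`,
#'   `peptide_resno`, `occupancy` (each in `[0, 1]`). Each peptide residue
#'   may appear in at most one pair (a limitation of the default geometry).
#' @param geometry Optional baseline coordinates: a tibble with columns
#'   `chain` (`"receptor"`/`"peptide"`), `resno`, `x`, `y`, `z` in nm.
#'   Defaults to a rigid receptor zig-zag (residues 225-244, 3 nm spacing)
#'   and a peptide arc (residues 5-16) offset 3 nm away, extended to cover
#'   any residues named in `occupancy`.
#' @param config A [generator_config()].
#' @param drift Planted final-frame peptide RMSD in nm; scalar or one value
#'   per pose.
#' @param frame_spacing_ps Time between saved frames, picoseconds
#'   (metadata).
#'
#' @return A tibble of class `trajectory_ensemble` with columns `pose`,
#'   `trial`, `frame`, `chain`, `resno`, `x`, `y`, `z` (nm) and attribute
#'   `frame_spacing_ps`.
#' @export
gen_trajectories <- function(n_poses = 1, n_trials = 4, n_frames = 200,
                             occupancy = NULL, geometry = NULL,
                             config = generator_config(), drift = 0,
                             frame_spacing_ps = 10) {
  check_number(n_poses, "n_poses", positive = TRUE)
  check_number(n_trials, "n_trials", positive = TRUE)
  check_number(n_frames, "n_frames", positive = TRUE)
  n_poses <- as.integer(n_poses)
  n_trials <- as.integer(n_trials)
  n_frames <- as.integer(n_frames)
  if (length(drift) == 1) drift <- rep(drift, n_poses)
  if (length(drift) != n_poses || any(drift < 0)) {
    abort("`drift` must be a non-negative scalar or one value per pose.",
      class = "degronmap_error_argument"
    )
  }

  if (!is.null(occupancy)) {
    occupancy <- as_tibble(occupancy)
    stopifnot(all(
      c("receptor_resno", "peptide_resno", "occupancy") %in% names(occupancy)
    ))
    if (any(occupancy$occupancy < 0 | occupancy$occupancy > 1)) {
      abort("Contact occupancies must lie in [0, 1].",
        class = "degronmap_error_occupancy"
      )
    }
    if (anyDuplicated(occupancy$peptide_resno)) {
      abort(
        paste(
          "Each peptide residue may appear in at most one occupancy pair",
          "under the default geometry."
        ),
        class = "degronmap_error_occupancy"
      )
    }
  } else {
    occupancy <- tibble(
      receptor_resno = integer(), peptide_resno = integer(),
      occupancy = double()
    )
  }

  if (is.null(geometry)) {
    geometry <- default_geometry(occupancy)
  } else {
    geometry <- as_tibble(geometry)
    stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(geometry)))
  }
  rec <- geometry |> filter(.data$chain == "receptor") |> arrange(.data$resno)
  pep <- geometry |> filter(.data$chain == "peptide") |> arrange(.data$resno)
  if (!all(occupancy$receptor_resno %in% rec$resno) ||
    !all(occupancy$peptide_resno %in% pep$resno)) {
    abort("Occupancy pairs must reference residues present in the geometry.",
      class = "degronmap_error_occupancy"
    )
  }

  noiseless <- config$noise_model == "none"
  out <- with_substream(config$seed, 2L, {
    pieces <- vector("list", n_poses * n_trials)
    k <- 0L
    for (pose in seq_len(n_poses)) {
      for (trial in seq_len(n_trials)) {
        drift_t <- if (noiseless || drift[pose] == 0) {
          drift[pose]
        } else {
          drift[pose] * lognormal_factor(1, config$noise_scale)
        }
        pieces[[k <- k + 1L]] <- build_trial(
          rec, pep, occupancy, n_frames, drift_t, noiseless
        ) |>
          mutate(pose = pose, trial = trial, .before = 1)
      }
    }
    list_rbind(pieces)
  })
  structure(
    out,
    frame_spacing_ps = frame_spacing_ps,
    class = c("trajectory_ensemble", class(out))
  )
}

default_geometry <- function(occupancy) {
  rec_res <- sort(unique(c(225:244, occupancy$receptor_resno)))
  pep_res <- sort(unique(c(5:16, occupancy$peptide_resno)))
  i <- seq_along(rec_res)
  j <- seq_along(pep_res)
  bind_rows(
    tibble(
      chain = "receptor", resno = rec_res,
      x = 3 * (i - 1), y = 0.5 * (i %% 2), z = 0.3 * ((i %% 3) - 1)
    ),
    tibble(
      chain = "peptide", resno = pep_res,
      x = 0.35 * (j - 1), y = 3 + 0.2 * sin(j), z = 0.2 * cos(j)
    )
  )
}

# One trial: contact schedule, then peptide dilation for planted drift.
build_trial <- function(rec, pep, occupancy, n_frames, drift_t, noiseless) {
  frames <- seq_len(n_frames)
  pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])

  # peptide coordinates per frame, starting from the baseline
  coords <- array(rep(t(pep_xyz), n_frames), dim = c(3, nrow(pep), n_frames))
  if (nrow(occupancy) > 0) {
    for (r in seq_len(nrow(occupancy))) {
      f <- occupancy$occupancy[r]
      in_contact <- rep(FALSE, n_frames)
      if (noiseless) {
        n_in <- ceiling(f * n_frames)
        if (n_in > 0) in_contact[seq_len(min(n_in, n_frames))] <- TRUE
      } else {
        n_in <- round(f * n_frames)
        if (n_in > 0) in_contact[sample.int(n_frames, n_in)] <- TRUE
      }
      pj <- match(occupancy$peptide_resno[r], pep$resno)
      rj <- match(occupancy$receptor_resno[r], rec$resno)
      offset <- ifelse(in_contact, 0.5, 1.5)
      coords[1, pj, ] <- rec_xyz[rj, 1]
      coords[2, pj, ] <- rec_xyz[rj, 2] + offset
      coords[3, pj, ] <- rec_xyz[rj, 3]
    }
  }
  if (drift_t > 0 && n_frames > 1) {
    for (fr in frames[-1]) {
      p <- t(coords[, , fr])
      cen <- colMeans(p)
      rad <- sweep(p, 2, cen)
      rg <- sqrt(mean(rowSums(rad^2)))
      d_f <- drift_t * (fr - 1) / (n_frames - 1)
      coords[, , fr] <- t(sweep(rad * (1 + d_f / rg), 2, cen, `+`))
    }
  }

  pep_tbl <- tibble(
    frame = rep(frames, each = nrow(pep)),
    chain = "peptide",
    resno = rep(pep$resno, n_frames),
    x = as.vector(coords[1, , ]),
    y = as.vector(coords[2, , ]),
    z = as.vector(coords[3, , ])
  )
  rec_tbl <- tibble(
    frame = rep(frames, each = nrow(rec)),
    chain = "receptor",
    resno = rep(rec$resno, n_frames),
    x = rep(rec_xyz[, 1], n_frames),
    y = rep(rec_xyz[, 2], n_frames),
    z = rep(rec_xyz[, 3], n_frames)
  )
  bind_rows(rec_tbl, pep_tbl) |> arrange(.data$frame, .data$chain, .data$resno)
}

validate_ensemble <- function(ensemble) {
  needed <- c("pose", "trial", "frame", "chain", "resno", "x", "y", "z")
  if (!all(needed %in% names(ensemble))) {
    abort(
      paste0(
        "A trajectory ensemble needs columns: ",
        paste(needed, collapse = ", ")
      ),
      class = "degronmap_error_ensemble"
    )
  }
  if (!all(ensemble$chain %in% c("receptor", "peptide"))) {
    abort("`chain` must be 'receptor' or 'peptide'.",
      class = "degronmap_error_ensemble"
    )
  }
  counts <- ensemble |>
    group_by(.data$pose, .data$trial, .data$frame) |>
    summarise(n_atoms = dplyr::n(), .groups = "drop_last") |>
    summarise(n_sizes = dplyr::n_distinct(.data$n_atoms), .groups = "drop")
  if (any(counts$n_sizes > 1)) {
    abort("All frames of a trial must share the same atom count.",
      class = "degronmap_error_ensemble"
    )
  }
  invisible(ensemble)
}
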