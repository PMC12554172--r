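#' Write and read trajectory ensembles as plain coordinate tables
#'
#' The plain per-frame coordinate table (TSV with columns `pose`, `trial`,
#' `frame`, `chain`, `resno`, `x`, `y`, `z`, coordinates in nm) is the
#' contract of record for exchanging synthetic trajectories.
#'
#' @param ensemble A `trajectory_ensemble` tibble.
#' @param file Path to a TSV file.
#' @return `read_frames_table()` returns a `trajectory_ensemble`;
#'   `write_frames_table()` returns `file` invisibly.
#' @export
write_frames_table <- function(ensemble, file) {
  validate_ensemble(ensemble)
  readr::write_tsv(as_tibble(ensemble), file)
  invisible(file)
}

#' @rdname write_frames_table
#' @param frame_spacing_ps Frame spacing metadata to attach on read.
#' @export
read_frames_table <- function(file, frame_spacing_ps = 10) {
  out <- readr::read_tsv(file, show_col_types = FALSE)
  validate_ensemble(out)
  structure(out,
    frame_spacing_ps = frame_spacing_ps,
    class = c("trajectory_ensemble", class(out))
  )
}

#' Write one pose/trial as a multi-model PDB
#'
#' Emits one MODEL per frame with C-alpha atom records, chain A holding
#' the receptor and chain B the peptide. Coordinates are converted from nm
#' to Angstrom, the native unit of the PDB format.
#'
#' @param ensemble A `trajectory_ensemble` tibble.
#' @param file Output path.
#' @param pose,trial Which trajectory to write.
#' @return `file`, invisibly.
#' @export
write_frames_pdb <- function(ensemble, file, pose = 1, trial = 1) {
  validate_ensemble(ensemble)
  d <- ensemble |>
    filter(.data$pose == !!pose, .data$trial == !!trial) |>
    arrange(.data$frame, desc(.data$chain), .data$resno)
  if (nrow(d) == 0) {
    abort("No frames for the requested pose/trial.",
      class = "degronmap_error_argument"
    )
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in sort(unique(d$frame))) {
    fd <- d |> filter(.data$frame == fr)
    writeLines(sprintf("MODEL     %4d", fr), con)
    chain_id <- ifelse(fd$chain == "receptor", "A", "B")
    lines <- sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(fd)), chain_id, fd$resno,
      fd$x * 10, fd$y * 10, fd$z * 10
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB trajectory into an ensemble
#'
#' Reads C-alpha coordinates from a multi-model PDB (one MODEL per frame)
#' through `bio3d::read.pdb()`, mapping chain A to the receptor and chain
#' B to the peptide and converting Angstrom to nm.
#'
#' @param file Path to a multi-model PDB file.
#' @param pose,trial Labels to assign to the single trajectory read.
#' @param frame_spacing_ps Frame spacing metadata.
#' @return A `trajectory_ensemble` tibble.
#' @export
read_frames_pdb <- function(file, pose = 1, trial = 1,
                            frame_spacing_ps = 10) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  ca <- bio3d::atom.select(pdb, elety = "CA")
  at <- pdb$atom[ca$atom, ]
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  n_frames <- nrow(xyz)
  per_frame <- map(seq_len(n_frames), function(fr) {
    m <- matrix(xyz[fr, ], ncol = 3, byrow = TRUE)
    tibble(
      pose = pose, trial = trial, frame = fr,
      chain = ifelse(at$chain == "A", "receptor", "peptide"),
      resno = at$resno,
      x = m[, 1] / 10, y = m[, 2] / 10, z = m[, 3] / 10
    )
  })
  out <- list_rbind(per_frame) |>
    arrange(.data$frame, .data$chain, .data$resno)
  structure(out,
    frame_spacing_ps = frame_spacing_ps,
    class = c("trajectory_ensemble", class(out))
  )
}

#' Read a substitution-array TSV
#'
#' Reads an array signal table (as written by [write_array_tsv()] or
#' exported from quantification software) and attaches the design needed
#' by the analysis functions.
#'
#' @param file Path to a TSV with columns `peptide_id`, `type`, `position`,
#'   `residue`, `last_retained`, `replicate`, `signal` (extra columns are
#'   kept).
#' @param design An [array_design()] describing the array.
#' @return A `substitution_array` tibble.
#' @export
read_array_tsv <- function(file, design) {
  stopifnot(inherits(design, "array_design"))
  out <- readr::read_tsv(file, show_col_types = FALSE)
  validate_array(out)
  new_substitution_array(out, design)
}

#' @rdname read_array_tsv
#' @param data A `substitution_array` tibble.
#' @export
write_array_tsv <- function(data, file) {
  validate_array(data)
  readr::write_tsv(as_tibble(data), file)
  invisible(file)
}
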