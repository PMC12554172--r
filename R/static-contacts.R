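#' van der Waals radii of common protein elements
#'
#' Bondi-style van der Waals radii (Angstrom) for the elements routinely
#' present in protein structures, used by [static_contacts()]:
#' H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, plus halogens and
#' selenium (F 1.47, Cl 1.75, Br 1.85, I 1.98, Se 1.90).
#'
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
  )
}

#' Read a static structure into an atom table
#'
#' Thin wrapper around `bio3d::read.pdb()` that returns the atom records
#' as a tibble in the layout [static_contacts()] expects. The element is
#' taken from the PDB element column when present, otherwise derived from
#' the first letter of the atom name.
#'
#' @param file Path to a PDB file.
#' @return A tibble with columns `chain`, `resno`, `resname`, `element`,
#'   `x`, `y`, `z` (Angstrom).
#' @export
read_static_structure <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  tibble(
    chain = at$chain,
    resno = at$resno,
    resname = at$resid,
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z
  )
}

#' Cross-chain residue contacts by van der Waals overlap
#'
#' Two atoms in different chains are in contact when their van der Waals
#' overlap, `r_i + r_j - d_ij`, is at least `overlap_cutoff` (so with the
#' default -0.40 Angstrom, surfaces may be up to 0.4 A apart and still
#' count). Residue pairs are reported when any of their atom pairs
#' qualifies. Pairs overlapping by 0.6 A or more are flagged as clashes
#' with a warning, coincident atoms included.
#'
#' @param structure An atom tibble as returned by
#'   [read_static_structure()]: columns `chain`, `resno`, `resname`,
#'   `element`, `x`, `y`, `z` in Angstrom.
#' @param overlap_cutoff Minimum vdW overlap in Angstrom (default -0.40).
#' @param radii Named radius table, Angstrom; defaults to [vdw_radii()].
#'   A missing element is a named error.
#'
#' @return A tibble with one row per contacting cross-chain residue pair:
#'   `chain_a`, `resno_a`, `resname_a`, `chain_b`, `resno_b`, `resname_b`,
#'   `n_atom_pairs`, `max_overlap`.
#' @export
static_contacts <- function(structure, overlap_cutoff = -0.40,
                            radii = vdw_radii()) {
  structure <- as_tibble(structure)
  needed <- c("chain", "resno", "element", "x", "y", "z")
  stopifnot(all(needed %in% names(structure)))
  if (!"resname" %in% names(structure)) structure$resname <- NA_character_
  if (any(!is.finite(structure$x + structure$y + structure$z))) {
    abort("Coordinates must be finite.", class = "degronmap_error_coords")
  }
  structure$element <- toupper(trimws(structure$element))
  missing_el <- setdiff(unique(structure$element), names(radii))
  if (length(missing_el) > 0) {
    abort(
      paste0(
        "No van der Waals radius for element(s): ",
        paste(missing_el, collapse = ", ")
      ),
      class = "degronmap_error_radius"
    )
  }
  structure$radius <- unname(radii[structure$element])

  chains <- unique(structure$chain)
  if (length(chains) < 2) {
    abort("At least two chains are required for cross-chain contacts.",
      class = "degronmap_error_argument"
    )
  }
  pairs <- utils::combn(chains, 2, simplify = FALSE)
  res <- map(pairs, function(ch) {
    a <- structure |> filter(.data$chain == ch[1])
    b <- structure |> filter(.data$chain == ch[2])
    ax <- as.matrix(a[, c("x", "y", "z")])
    bx <- as.matrix(b[, c("x", "y", "z")])
    d <- sqrt(outer(rowSums(ax^2), rowSums(bx^2), `+`) - 2 * ax %*% t(bx))
    d[!is.finite(d) | d < 0] <- 0
    overlap <- outer(a$radius, b$radius, `+`) - d
    hit <- which(overlap >= overlap_cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) {
      return(NULL)
    }
    if (any(overlap[hit] >= 0.6)) {
      warn(sprintf(
        "%d atom pair(s) between chains %s and %s overlap by >= 0.6 A (clash).",
        sum(overlap[hit] >= 0.6), ch[1], ch[2]
      ))
    }
    tibble(
      chain_a = ch[1],
      resno_a = a$resno[hit[, 1]],
      resname_a = a$resname[hit[, 1]],
      chain_b = ch[2],
      resno_b = b$resno[hit[, 2]],
      resname_b = b$resname[hit[, 2]],
      overlap = overlap[hit]
    )
  })
  found <- list_rbind(purrr::compact(res))
  if (nrow(found) == 0) {
    return(tibble(
      chain_a = character(), resno_a = integer(), resname_a = character(),
      chain_b = character(), resno_b = integer(), resname_b = character(),
      n_atom_pairs = integer(), max_overlap = double()
    ))
  }
  found |>
    group_by(
      .data$chain_a, .data$resno_a, .data$resname_a,
      .data$chain_b, .data$resno_b, .data$resname_b
    ) |>
    summarise(
      n_atom_pairs = dplyr::n(),
      max_overlap = max(.data$overlap),
      .groups = "drop"
    )
}
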