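#' The 20 natural eukaryotic amino acids
#'
#' One-letter codes in alphabetical order. This is the substitution alphabet
#' used by array designs and effect profiles.
#'
#' @format Character vector of length 20.
#' @export
amino_acids <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Canonical parent sequence of the RGS2 N-terminal degron (residues 5-16).
# A common transposed spelling (C and R at positions 13/14 swapped) is
# accepted by the constructors with a warning; see check_degron_spelling().
RGS2_DEGRON <- "MFLAVQHDCRPM"
RGS2_DEGRON_VARIANT <- "MFLAVQHDRCPM"

#' Canonical RGS2 degron sequence
#'
#' Returns the twelve-residue RGS2 N-terminal degron (Met5-Met16,
#' `MFLAVQHDCRPM`) recognized by the FBXO44 FBA domain. Position numbering
#' throughout the package follows the full-length protein, so the first
#' residue of this peptide is position 5.
#'
#' @return A single string.
#' @export
rgs2_degron_sequence <- function() RGS2_DEGRON

check_degron_spelling <- function(sequence) {
  if (identical(sequence, RGS2_DEGRON_VARIANT)) {
    warn(paste0(
      "Sequence '", RGS2_DEGRON_VARIANT, "' looks like the transposed ",
      "spelling of the RGS2 degron (Cys13/Arg14 swapped); the canonical ",
      "sequence is '", RGS2_DEGRON, "'. Proceeding with the sequence as given."
    ))
  }
  invisible(sequence)
}

split_residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

check_residues <- function(residues, what = "sequence") {
  bad <- setdiff(unique(residues), amino_acids)
  if (length(bad) > 0) {
    abort(
      paste0(
        "Unknown residue letter(s) in ", what, ": ",
        paste(bad, collapse = ", "),
        ". Allowed letters are the 20 natural amino acids."
      ),
      class = "degronmap_error_residue"
    )
  }
  invisible(residues)
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."),
      class = "degronmap_error_argument"
    )
  }
  if (positive && x <= 0) {
    abort(paste0("`", name, "` must be > 0 (got ", x, ")."),
      class = "degronmap_error_argument"
    )
  }
  if (non_negative && x < 0) {
    abort(paste0("`", name, "` must be >= 0 (got ", x, ")."),
      class = "degronmap_error_argument"
    )
  }
  invisible(x)
}

# Evaluate `code` under a seeded RNG substream derived from `seed` and a
# per-generator offset, restoring the caller's RNG state afterwards. With a
# NULL seed the code runs on the ambient RNG stream.
with_substream <- function(seed, offset, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    },
    add = TRUE
  )
  set.seed((as.integer(seed) + 97L * as.integer(offset)) %% 2147483647L)
  force(code)
}

# Mean-one multiplicative lognormal noise factors.
lognormal_factor <- function(n, scale) {
  if (scale == 0) {
    return(rep(1, n))
  }
  rlnorm(n, meanlog = -scale^2 / 2, sdlog = scale)
}
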