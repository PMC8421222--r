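#' Per-position primer editing efficiency profile
#'
#' Describes how efficiently a polymerase's 3'->5' exonuclease edits a
#' template:primer mismatch at each primer position, counted 1-based from
#' the 3' end.  `block_after` models phosphorothioate protection: only the
#' `block_after` 3'-terminal positions remain editable (a bond between the
#' 4th- and 3rd-to-last bases corresponds to `block_after = 3`); the
#' default `Inf` places no block.
#'
#' @param efficiencies Named or unnamed numeric vector in `[0, 1]`.
#'   Unnamed vectors are taken as positions `1..length`; names are
#'   3'-distance positions.  Positions not listed have efficiency 0.
#' @param block_after Number of 3'-terminal positions that remain editable;
#'   `Inf` for no block, 0 for a fully blocked primer.
#' @param label Free-text label (polymerase, concentration, ...).
#' @return An object of class `editing_profile`.
#' @export
#' @examples
#' # near-complete editing of the last 6 positions
#' editing_profile(rep(1, 6), label = "proofreading, high activity")
editing_profile <- function(efficiencies = numeric(0), block_after = Inf,
                            label = "custom") {
  if (length(efficiencies)) {
    if (any(efficiencies < 0 | efficiencies > 1)) {
      abort("editing efficiencies must lie in [0, 1]")
    }
    if (is.null(names(efficiencies))) {
      names(efficiencies) <- seq_along(efficiencies)
    }
  }
  if (!(is.infinite(block_after) || (block_after >= 0 &&
        block_after == as.integer(block_after)))) {
    abort("`block_after` must be a non-negative integer or Inf")
  }
  structure(
    list(efficiencies = efficiencies, block_after = block_after, label = label),
    class = "editing_profile"
  )
}

#' @export
print.editing_profile <- function(x, ...) {
  cat(sprintf("<editing_profile> %s\n", x$label))
  if (length(x$efficiencies)) {
    cat("  e[pos from 3' end]:",
        paste(sprintf("%s=%.3g", names(x$efficiencies), x$efficiencies),
              collapse = " "), "\n")
  } else {
    cat("  no editing at any position\n")
  }
  if (is.finite(x$block_after)) {
    cat(sprintf("  exonuclease block: only last %d positions editable\n",
                x$block_after))
  }
  invisible(x)
}

# Effective per-position efficiency honoring the exonuclease block.
effective_efficiency <- function(profile, positions) {
  e <- rep(0, length(positions))
  hit <- match(as.character(positions), names(profile$efficiencies))
  e[!is.na(hit)] <- profile$efficiencies[hit[!is.na(hit)]]
  e[positions > profile$block_after] <- 0
  e
}

#' Per-position amplification penalty profile
#'
#' Relative amplification efficiency of a template:primer mismatch at each
#' position when the mismatch is *not* edited; 1 everywhere by default
#' (no penalty), matched sites always amplify at 1.
#'
#' @param penalties Named or unnamed numeric vector in `[0, 1]`; unnamed
#'   vectors are positions `1..length` from the 3' end.  Unlisted positions
#'   default to 1.
#' @return An object of class `penalty_profile`.
#' @export
penalty_profile <- function(penalties = numeric(0)) {
  if (length(penalties)) {
    if (any(penalties < 0 | penalties > 1)) {
      abort("penalties must lie in [0, 1]")
    }
    if (is.null(names(penalties))) names(penalties) <- seq_along(penalties)
  }
  structure(list(penalties = penalties), class = "penalty_profile")
}

#' @export
print.penalty_profile <- function(x, ...) {
  cat("<penalty_profile>\n")
  if (length(x$penalties)) {
    cat("  a[pos from 3' end]:",
        paste(sprintf("%s=%.3g", names(x$penalties), x$penalties),
              collapse = " "), "\n")
  } else cat("  no amplification penalty at any position\n")
  invisible(x)
}

effective_penalty <- function(profile, positions) {
  a <- rep(1, length(positions))
  hit <- match(as.character(positions), names(profile$penalties))
  a[!is.na(hit)] <- profile$penalties[hit[!is.na(hit)]]
  a
}

#' Mismatch amplification penalties measured for Taq polymerase
#'
#' Relative amplification efficiencies of unedited single mismatches in the
#' last five positions of the V4 forward primer, as measured with a
#' non-proofreading Taq polymerase in the reciprocal variant-primer
#' experiment: 0.189, 0.318, 0.404, 0.774 and 0.922-fold of expected at
#' positions 1-5 from the 3' end; positions beyond 5 are permissive (1.0).
#'
#' @return A [penalty_profile()].
#' @export
taq_penalty_profile <- function() {
  penalty_profile(c(`1` = 0.189, `2` = 0.318, `3` = 0.404,
                    `4` = 0.774, `5` = 0.922))
}

#' Simulation run configuration
#'
#' @param n_reads Number of read pairs.
#' @param error_rate Uniform per-base substitution probability in
#'   `[0, 0.25]`.
#' @param read_length Read length; `NULL` covers the amplicon end-to-end
#'   from each side.
#' @param seed Integer seed; the read stream is deterministic given the
#'   seed and configuration.
#' @param quality_char Constant Phred symbol written to FASTQ.
#' @param annealing_temp Annealing temperature in degrees Celsius; accepted
#'   for provenance and ignored by the generative model (editing is
#'   insensitive to annealing temperature in the 50-60 C range).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 50000, error_rate = 0, read_length = NULL,
                       seed = 1, quality_char = "I", annealing_temp = NULL) {
  if (n_reads < 1) abort("`n_reads` must be >= 1")
  if (error_rate < 0 || error_rate > 0.25) {
    abort("`error_rate` must lie in [0, 0.25]")
  }
  if (nchar(quality_char) != 1) abort("`quality_char` must be one character")
  structure(
    list(n_reads = as.integer(n_reads), error_rate = error_rate,
         read_length = read_length, seed = as.integer(seed),
         quality_char = quality_char, annealing_temp = annealing_temp),
    class = "sim_config"
  )
}
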