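#' Amplicon primer scheme
#'
#' Bundles the locus-specific portions of a forward/reverse amplification
#' primer pair together with their sequencing adapter tails.  The default is
#' the *E. coli*-specific 16S rRNA V4 scheme (515F/806R, Nextera-tailed) with
#' a 19-base forward and 20-base reverse locus-specific portion and no
#' degenerate bases.
#'
#' @param fwd_locus,rev_locus Locus-specific primer portions, 5'->3',
#'   uppercase IUPAC.
#' @param fwd_tail,rev_tail Adapter tails preceding the locus-specific
#'   portions.
#' @return An object of class `primer_scheme`.
#' @export
#' @examples
#' primer_scheme()
primer_scheme <- function(fwd_locus = "GTGCCAGCAGCCGCGGTAA",
                          rev_locus = "GGACTACCAGGGTATCTAAT",
                          fwd_tail = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                          rev_tail = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG") {
  for (nm in c("fwd_locus", "rev_locus")) {
    x <- get(nm)
    if (!is.character(x) || length(x) != 1 || nchar(x) == 0) {
      abort(sprintf("`%s` must be a non-empty DNA string", nm))
    }
    if (!is_dna(x)) abort(sprintf("`%s` contains non-IUPAC characters", nm))
  }
  for (nm in c("fwd_tail", "rev_tail")) {
    x <- get(nm)
    if (nchar(x) > 0 && !is_dna(x)) {
      abort(sprintf("`%s` contains non-IUPAC characters", nm))
    }
  }
  structure(
    list(fwd_locus = fwd_locus, rev_locus = rev_locus,
         fwd_tail = fwd_tail, rev_tail = rev_tail),
    class = "primer_scheme"
  )
}

#' @export
print.primer_scheme <- function(x, ...) {
  cat("<primer_scheme>\n")
  cat(sprintf("  fwd: %s[%s]  (%d nt locus)\n", x$fwd_tail, x$fwd_locus,
              nchar(x$fwd_locus)))
  cat(sprintf("  rev: %s[%s]  (%d nt locus)\n", x$rev_tail, x$rev_locus,
              nchar(x$rev_locus)))
  invisible(x)
}

#' Adapter sequences as they appear read-through on read 3' ends
#'
#' A fragment shorter than the read length lets the sequencer run past the
#' amplicon end into the opposite primer's tail; the read-through is the
#' reverse complement of that tail.  Use these as the `adapter` argument of
#' [trim_adapters()] for read 1 and read 2 respectively.
#'
#' @param scheme A [primer_scheme()].
#' @return Named list with elements `r1` and `r2`.
#' @export
readthrough_adapters <- function(scheme = primer_scheme()) {
  stopifnot(inherits(scheme, "primer_scheme"))
  list(r1 = revcomp(scheme$rev_tail), r2 = revcomp(scheme$fwd_tail))
}
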