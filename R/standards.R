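#' Enumerate single-base variants of a primer binding site
#'
#' Lists the wild-type site plus every single-base substitution within the
#' `window` 3'-terminal positions — the construct scheme behind a
#' primer-editing standards pool (3 * window + 1 members).  Positions are
#' counted from the primer 3' end, 1-based: position 1 is the terminal base,
#' and `variant_pos = 0` marks the wild type.
#'
#' @param primer_site DNA string of the primer binding site, 5'->3'.
#' @param window Number of 3'-terminal positions to mutagenize; must not
#'   exceed the site length, and the windowed positions must be
#'   non-degenerate (A/C/G/T).
#' @return A tibble with columns `variant_pos` (0 = wild type),
#'   `variant_base` (`NA` for wild type) and `site` (the full mutated site).
#'   Ordering is deterministic: wild type first, then positions from the 3'
#'   terminus outward, variant bases alphabetical.
#' @export
#' @examples
#' nrow(enumerate_variants("GTGCCAGCAGCCGCGGTAA", 10))  # 31
enumerate_variants <- function(primer_site, window) {
  stopifnot(is.character(primer_site), length(primer_site) == 1)
  primer_site <- toupper(primer_site)
  L <- nchar(primer_site)
  if (!is_dna(primer_site)) abort("`primer_site` contains non-IUPAC characters")
  if (window < 0 || window > L) {
    abort(sprintf("`window` (%d) must lie in [0, %d], the primer length", window, L))
  }
  chars <- strsplit(primer_site, "")[[1]]
  if (window > 0) {
    win_chars <- chars[(L - window + 1):L]
    if (!all(win_chars %in% c("A", "C", "G", "T"))) {
      abort("degenerate bases inside the mutagenized window are not supported")
    }
  }
  out <- tibble(variant_pos = 0L, variant_base = NA_character_, site = primer_site)
  if (window == 0) return(out)
  rows <- purrr::map_dfr(seq_len(window), function(p) {
    i <- L - p + 1L  # 5'-based index of 3'-distance p
    ref <- chars[i]
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    tibble(
      variant_pos = p,
      variant_base = alts,
      site = vapply(alts, function(b) subchar(primer_site, i, b), character(1))
    )
  })
  bind_rows(out, rows)
}

#' Generate quantification barcodes at a minimum pairwise Hamming distance
#'
#' Greedy rejection sampler for a set of fixed-length DNA barcodes whose
#' pairwise Hamming distance is at least `min_dist`.  A minimum distance of
#' 5 guarantees unambiguous read assignment under the <=2-mismatch
#' tolerance used for barcode quantification.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases (default 20, the mapped prefix).
#' @param min_dist Minimum pairwise Hamming distance (default 5).
#' @param seed Integer seed; the set is deterministic for a fixed seed.
#' @param max_tries Bounded rejection attempts before declaring the request
#'   infeasible.
#' @return Character vector of `n` distinct barcodes.
#' @export
#' @examples
#' bc <- generate_barcodes(5, seed = 1)
generate_barcodes <- function(n, length = 20, min_dist = 5, seed = NULL,
                              max_tries = 2000 * n) {
  stopifnot(n >= 1, length >= 1, min_dist >= 0)
  if (n > 1 && min_dist > length) {
    abort(sprintf(
      "cannot place %d barcodes of length %d at pairwise distance >= %d",
      n, length, min_dist))
  }
  # Singleton bound on q-ary codes: |C| <= q^(n - d + 1)
  if (n > 1 && 4^(length - min_dist + 1) < n) {
    abort("requested barcode set exceeds code capacity for this min_dist")
  }
  gen <- function() {
    acc <- character(0)
    tries <- 0
    while (base::length(acc) < n) {
      tries <- tries + 1
      if (tries > max_tries) {
        abort("could not satisfy barcode distance constraint within bounded attempts")
      }
      cand <- random_dna(1, length)
      if (base::length(acc) == 0 ||
          min(cpp_hamming(rep(cand, base::length(acc)), acc)) >= min_dist) {
        acc <- c(acc, cand)
      }
    }
    acc
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthetic amplicon template region
#'
#' Builds a V4-like template region for synthetic runs: the forward primer
#' binding site, a randomly generated core, and the reverse complement of
#' the reverse primer binding site.  The default total length of 332 bases
#' mirrors a 16S V4 amplicon spanned by the default scheme.  This is a
#' synthetic stand-in sequence, not the *E. coli* 16S rRNA gene.
#'
#' @param scheme A [primer_scheme()].
#' @param total_len Total template length (>= sum of the two site lengths).
#' @param seed Integer seed for the random core.
#' @param gc Core GC fraction.
#' @return DNA string containing each primer site exactly once.
#' @export
synthetic_template <- function(scheme = primer_scheme(), total_len = 332,
                               seed = 101, gc = 0.54) {
  stopifnot(inherits(scheme, "primer_scheme"))
  fwd <- scheme$fwd_locus
  rev_rc <- revcomp(scheme$rev_locus)
  core_len <- total_len - nchar(fwd) - nchar(rev_rc)
  if (core_len < 0) abort("`total_len` shorter than the two primer sites")
  withr::with_seed(seed, {
    repeat {
      core <- random_dna(1, core_len, gc = gc)
      tpl <- paste0(fwd, core, rev_rc)
      # primer sites must stay unique within the template
      if (stringr::str_count(tpl, stringr::fixed(fwd)) == 1 &&
          stringr::str_count(tpl, stringr::fixed(rev_rc)) == 1) {
        return(tpl)
      }
    }
  })
}

#' Build the primer-editing standards construct set
#'
#' Emits one construct per [enumerate_variants()] entry: the template region
#' with the single substitution applied inside the forward primer binding
#' site, flanked on each side by `flank_len` bases of shared random flank,
#' plus a unique quantification barcode per construct.  For the printed V4
#' scheme and a 10-base window this is the 31-member standards pool.
#'
#' @param template_region DNA string containing the forward primer binding
#'   site and the reverse complement of the reverse site exactly once each.
#' @param scheme A [primer_scheme()].
#' @param window Number of 3'-terminal forward-primer positions mutagenized.
#' @param flank_len Bases of flanking sequence on each side of the template.
#' @param seed Integer seed governing flanks and barcodes.
#' @return A tibble of class `construct_set` with columns `construct_id`,
#'   `variant_pos`, `variant_base`, `barcode`, `insert_seq`,
#'   `insert_length`, and attributes `scheme`, `window`, `flank_len`,
#'   `template_region`, `amplicon_start`.
#' @export
#' @examples
#' cs <- build_construct_set(synthetic_template(), window = 10)
#' nrow(cs)  # 31
build_construct_set <- function(template_region, scheme = primer_scheme(),
                                window = 10, flank_len = 20, seed = 1) {
  stopifnot(inherits(scheme, "primer_scheme"))
  template_region <- toupper(template_region)
  fwd <- scheme$fwd_locus
  rev_rc <- revcomp(scheme$rev_locus)
  n_fwd <- stringr::str_count(template_region, stringr::fixed(fwd))
  n_rev <- stringr::str_count(template_region, stringr::fixed(rev_rc))
  if (n_fwd != 1 || n_rev != 1) {
    abort(sprintf(
      "template must contain each primer site exactly once (found fwd: %d, rev: %d)",
      n_fwd, n_rev))
  }
  fwd_at <- as.integer(stringr::str_locate(template_region,
                                           stringr::fixed(fwd))[1, "start"])
  rev_end <- as.integer(stringr::str_locate(template_region,
                                            stringr::fixed(rev_rc))[1, "end"])
  if (rev_end < fwd_at + nchar(fwd)) {
    abort("reverse primer site must lie downstream of the forward site")
  }
  variants <- enumerate_variants(fwd, window)
  flanks <- withr::with_seed(seed, random_dna(2, flank_len))
  barcodes <- generate_barcodes(nrow(variants), length = 20, min_dist = 5,
                                seed = seed + 1L)
  L <- nchar(fwd)
  inserts <- vapply(seq_len(nrow(variants)), function(i) {
    tpl <- template_region
    p <- variants$variant_pos[i]
    if (p > 0) {
      tpl <- subchar(tpl, fwd_at + (L - p), variants$variant_base[i])
    }
    paste0(flanks[1], tpl, flanks[2])
  }, character(1))
  ids <- ifelse(
    variants$variant_pos == 0, "WT",
    sprintf("P%02d_%s", variants$variant_pos, variants$variant_base)
  )
  out <- tibble(
    construct_id = ids,
    variant_pos = variants$variant_pos,
    variant_base = variants$variant_base,
    barcode = barcodes,
    insert_seq = inserts,
    insert_length = nchar(inserts)
  )
  structure(
    out,
    class = c("construct_set", class(out)),
    scheme = scheme,
    window = as.integer(window),
    flank_len = as.integer(flank_len),
    template_region = template_region,
    amplicon_start = flank_len + fwd_at,
    amplicon_len = rev_end - fwd_at + 1L
  )
}

#' Even pool abundance for a construct set
#'
#' @param constructs A `construct_set` (or any tibble with `construct_id`).
#' @return A tibble `construct_id`, `proportion` summing to one.
#' @export
even_abundance <- function(constructs) {
  tibble(construct_id = constructs$construct_id,
         proportion = 1 / nrow(constructs))
}

check_abundance <- function(abundance, constructs) {
  if (!all(c("construct_id", "proportion") %in% names(abundance))) {
    abort("`abundance` needs columns construct_id, proportion")
  }
  missing <- setdiff(constructs$construct_id, abundance$construct_id)
  extra <- setdiff(abundance$construct_id, constructs$construct_id)
  if (length(missing) || length(extra)) {
    abort("`abundance` and the construct set do not describe the same pool")
  }
  if (any(abundance$proportion < 0) ||
      abs(sum(abundance$proportion) - 1) > 1e-9) {
    abort("abundance proportions must be non-negative and sum to 1")
  }
  abundance[match(constructs$construct_id, abundance$construct_id), ]
}

#' Write a construct set to disk
#'
#' Emits `constructs.fasta` (insert sequences), `barcodes.fasta` (the
#' barcode reference: first 20 bases of each entry are the barcode) and
#' `metadata.tsv`.
#'
#' @param constructs A `construct_set`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_construct_set <- function(constructs, dir) {
  stopifnot(inherits(constructs, "construct_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(constructs$construct_id, constructs$insert_seq,
              file.path(dir, "constructs.fasta"))
  write_fasta(constructs$construct_id, constructs$barcode,
              file.path(dir, "barcodes.fasta"))
  readr::write_tsv(
    constructs[, c("construct_id", "variant_pos", "variant_base",
                   "barcode", "insert_length")],
    file.path(dir, "metadata.tsv")
  )
  invisible(dir)
}
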