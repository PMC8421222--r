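#' Trim 3' adapter read-through
#'
#' Removes adapter read-through from read 3' ends by suffix/prefix overlap
#' matching: the longest overlap of at least `min_overlap` bases with a
#' mismatch fraction of at most `max_mismatch_frac` is cut.  Reads without
#' an admissible match pass unchanged; reads are never lengthened.
#'
#' @param reads A FASTQ path or read tibble (`id`, `seq`, `qual`).
#' @param adapter Adapter sequence 5'->3' as it appears read-through on the
#'   3' end (see [readthrough_adapters()]).
#' @param min_overlap Minimum adapter overlap (default 3).
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap
#'   (default 0.1).
#' @return The read tibble with trimmed `seq`/`qual` and a `trimmed`
#'   column (bases removed).
#' @export
trim_adapters <- function(reads, adapter, min_overlap = 3,
                          max_mismatch_frac = 0.1) {
  reads <- as_read_tbl(reads)
  res <- cpp_trim_adapter(reads$seq, reads$qual, toupper(adapter),
                          as.integer(min_overlap), max_mismatch_frac)
  reads |>
    mutate(seq = res$seq, qual = res$qual, trimmed = res$trimmed)
}

#' Merge read pairs by overlap consensus
#'
#' Reverse-complements read 2 and finds the best ungapped overlap with
#' read 1: candidates need at least `min_overlap` bases and a mismatch
#' fraction of at most `max_mismatch_frac`; the minimal mismatch fraction
#' wins, ties going to the longest overlap.  The consensus takes the
#' higher-quality base at conflicts, and the merged length is
#' `len1 + len2 - overlap`.
#'
#' @param reads1,reads2 FASTQ paths or read tibbles of equal length.
#' @param min_overlap Minimum admissible overlap (default 20).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return A tibble `id`, `seq`, `qual`, `overlap`, `merged`; unmergeable
#'   pairs keep their row with `merged = FALSE` and `NA` sequence.
#' @export
merge_pairs <- function(reads1, reads2, min_overlap = 20,
                        max_mismatch_frac = 0.1) {
  reads1 <- as_read_tbl(reads1, "reads1")
  reads2 <- as_read_tbl(reads2, "reads2")
  if (nrow(reads1) != nrow(reads2)) abort("read tibbles must pair up")
  r2rc <- revcomp(reads2$seq)
  q2r <- vapply(strsplit(reads2$qual, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  res <- cpp_merge_pairs(reads1$seq, r2rc, reads1$qual, q2r,
                         as.integer(min_overlap), max_mismatch_frac)
  tibble(id = reads1$id, seq = res$seq, qual = res$qual,
         overlap = res$overlap, merged = res$merged)
}

#' Profile base composition of the primer region
#'
#' Compares the first `nchar(reference_primer)` bases of each merged read
#' to the reference primer and counts each base at each position.  Reads
#' with more than `max_mm` mismatches over the region are excluded from
#' all counts (a proxy filter against indel noise); shorter reads are
#' skipped.  IUPAC-degenerate reference positions match any compatible
#' base and are never counted as mismatches.
#'
#' @param merged Merged reads: a tibble with a `seq` column (rows with
#'   `merged == FALSE` are dropped first), a character vector, or a FASTQ
#'   path.
#' @param reference_primer Reference primer sequence (e.g. the 19-base
#'   locus-specific forward portion).
#' @param max_mm Maximum mismatches per read (default 3).
#' @return An `edit_matrix`: tibble with `position` (1-based from the
#'   primer 5' end), `distance_from_3prime`, counts `A`, `C`, `G`, `T`,
#'   `N`, and `nonref_prop` (`NA` at degenerate reference positions).
#'   Attributes carry the reference and the read tallies
#'   (`reads_total`, `reads_pass_filter`, `reads_failed_filter`,
#'   `reads_short`).
#' @export
profile_primer_region <- function(merged, reference_primer, max_mm = 3) {
  seqs <- extract_seqs(merged)
  ref <- toupper(reference_primer)
  if (!is_dna(ref)) abort("`reference_primer` contains non-IUPAC characters")
  L <- nchar(ref)
  mm <- cpp_mismatch_counts(toupper(seqs), ref)
  short <- sum(is.na(mm))
  pass <- !is.na(mm) & mm <= max_mm
  fail <- sum(!is.na(mm) & mm > max_mm)
  counts <- cpp_base_counts(toupper(seqs[pass]), L)
  rc <- strsplit(ref, "")[[1]]
  degenerate <- !rc %in% c("A", "C", "G", "T")
  npass <- sum(pass)
  ref_row <- match(rc, c("A", "C", "G", "T"))
  ref_count <- vapply(seq_len(L), function(k) {
    if (degenerate[k]) NA_integer_ else counts[ref_row[k], k]
  }, integer(1))
  out <- tibble(
    position = seq_len(L),
    distance_from_3prime = L - seq_len(L) + 1L,
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    N = counts[5, ],
    nonref_prop = if (npass > 0) (npass - ref_count) / npass else NA_real_
  )
  structure(
    out,
    class = c("edit_matrix", class(out)),
    reference = ref,
    reads_total = length(seqs),
    reads_pass_filter = npass,
    reads_failed_filter = fail,
    reads_short = short,
    max_mm = max_mm
  )
}

extract_seqs <- function(merged) {
  if (is.character(merged) && length(merged) == 1 && file.exists(merged)) {
    merged <- read_fastq_tbl(merged)
  }
  if (is.data.frame(merged)) {
    if ("merged" %in% names(merged)) merged <- merged[merged$merged %in% TRUE, ]
    if (!"seq" %in% names(merged)) abort("merged reads need a `seq` column")
    merged$seq
  } else if (is.character(merged)) {
    merged
  } else {
    abort("`merged` must be a read tibble, character vector or FASTQ path")
  }
}

#' @export
#' @rdname profile_primer_region
#' @param x An `edit_matrix`.
#' @param ... Unused.
glance.edit_matrix <- function(x, ...) {
  tibble(
    reads_total = attr(x, "reads_total"),
    reads_pass_filter = attr(x, "reads_pass_filter"),
    reads_failed_filter = attr(x, "reads_failed_filter"),
    reads_short = attr(x, "reads_short"),
    max_mm = attr(x, "max_mm"),
    reference = attr(x, "reference")
  )
}

#' @export
#' @rdname profile_primer_region
tidy.edit_matrix <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("A", "C", "G", "T", "N"),
                        names_to = "base", values_to = "count")
}

#' Expected per-position variant proportions of a pool
#'
#' The expected edited proportion at 3'-distance `p` is the summed pool
#' abundance of constructs carrying their variant at `p` (3/31 each
#' position for the even 31-member pool).
#'
#' @param constructs A `construct_set` (or tibble with `construct_id`,
#'   `variant_pos`).
#' @param abundance Pool composition; defaults to the even pool.
#' @param positions 3'-distance positions to report (default `1:window`).
#' @return A tibble `distance_from_3prime`, `expected`.
#' @export
expected_edit_proportions <- function(constructs,
                                      abundance = even_abundance(constructs),
                                      positions = NULL) {
  meta <- tibble(construct_id = constructs$construct_id,
                 variant_pos = constructs$variant_pos) |>
    left_join(abundance, by = "construct_id")
  if (anyNA(meta$proportion)) abort("`abundance` is missing constructs")
  if (is.null(positions)) positions <- seq_len(max(meta$variant_pos, 0))
  exp_by_pos <- meta |>
    filter(.data$variant_pos > 0) |>
    group_by(.data$variant_pos) |>
    summarise(expected = sum(.data$proportion), .groups = "drop")
  tibble(distance_from_3prime = as.integer(positions)) |>
    left_join(exp_by_pos, by = c(distance_from_3prime = "variant_pos")) |>
    mutate(expected = tidyr::replace_na(.data$expected, 0))
}

#' Observed/expected edits metric
#'
#' Divides the observed per-position non-reference proportion by the
#' expected variant proportion of the template pool, position by position
#' from the primer 3' end.  A ratio near 1 indicates complete editing at
#' that position, near 0 none.  Positions where the pool expects no
#' variants are reported with ratio `NA` (undefined), not 0.
#'
#' @param matrix An `edit_matrix` from [profile_primer_region()].
#' @param constructs A `construct_set` describing the pool.
#' @param abundance Pool composition (e.g. [as_abundance()] of a barcode
#'   quantification); defaults to the even pool.
#' @return A tibble of class `obs_exp`: `distance_from_3prime`,
#'   `observed`, `expected`, `ratio`.
#' @export
observed_over_expected <- function(matrix, constructs,
                                   abundance = even_abundance(constructs)) {
  stopifnot(inherits(matrix, "edit_matrix"))
  L <- nrow(matrix)
  if (max(constructs$variant_pos) > L) {
    abort("construct window extends beyond the profiled primer region")
  }
  expected <- expected_edit_proportions(constructs, abundance,
                                        positions = seq_len(L))
  out <- as_tibble(matrix) |>
    select("distance_from_3prime", observed = "nonref_prop") |>
    left_join(expected, by = "distance_from_3prime") |>
    mutate(ratio = ifelse(.data$expected > 0,
                          .data$observed / .data$expected, NA_real_)) |>
    arrange(.data$distance_from_3prime)
  structure(out, class = c("obs_exp", class(out)))
}

#' Amplification-penalty analysis of a variant-primer run
#'
#' Classifies each merged read's primer region as wild type, one of the
#' `3 * window` single-base variants, or other (more than one mismatch, or
#' a single mismatch outside the window), and reports each variant's
#' fold-of-expected abundance.  `anchor = "wild_type"` computes
#' `(count_v / count_WT) / (expected_v / expected_WT)`, which recovers the
#' per-position relative amplification efficiency independent of pool-mean
#' yield; `anchor = "whole_pool"` computes `observed_prop / expected_prop`
#' over classified reads.
#'
#' @param merged Merged reads (tibble, character vector or FASTQ path).
#' @param scheme A [primer_scheme()]; its forward locus is the reference.
#' @param window Mutagenized window of the primer pool (default 10).
#' @param expected Expected pool proportions: tibble `variant_pos`,
#'   `variant_base`, `proportion` including a wild-type row
#'   (`variant_pos = 0`); `NULL` for the even pool.
#' @param anchor Normalization anchor, `"wild_type"` (default) or
#'   `"whole_pool"`.
#' @return A `penalty_table`: list with `variants` (per-variant tibble
#'   `position`, `base`, `count`, `expected`, `fold`), `positions`
#'   (per-position aggregate over the 3 variant bases) and `tallies`.
#'   [tidy()] returns the per-variant table, [glance()] the tallies.
#' @export
penalty_analysis <- function(merged, scheme = primer_scheme(), window = 10,
                             expected = NULL,
                             anchor = c("wild_type", "whole_pool")) {
  anchor <- match.arg(anchor)
  seqs <- extract_seqs(merged)
  ref <- scheme$fwd_locus
  L <- nchar(ref)
  variants <- enumerate_variants(ref, window)
  if (is.null(expected)) {
    expected <- variants |>
      select("variant_pos", "variant_base") |>
      mutate(proportion = 1 / nrow(variants))
  }
  cls <- cpp_classify_single(toupper(seqs), toupper(ref))
  short <- sum(is.na(cls$n_mismatch))
  is_wt <- !is.na(cls$n_mismatch) & cls$n_mismatch == 0
  single <- !is.na(cls$n_mismatch) & cls$n_mismatch == 1
  dist3 <- L - cls$pos + 1L
  in_pool <- single & dist3 <= window & cls$base %in% c("A", "C", "G", "T")
  n_wt <- sum(is_wt)
  obs <- tibble(variant_pos = dist3[in_pool], variant_base = cls$base[in_pool]) |>
    count(.data$variant_pos, .data$variant_base, name = "count")
  tab <- variants |>
    filter(.data$variant_pos > 0) |>
    select("variant_pos", "variant_base") |>
    left_join(obs, by = c("variant_pos", "variant_base")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    left_join(expected, by = c("variant_pos", "variant_base"))
  if (anyNA(tab$proportion)) abort("`expected` is missing pool variants")
  exp_wt <- expected$proportion[expected$variant_pos == 0]
  if (length(exp_wt) != 1) abort("`expected` needs one wild-type row (variant_pos = 0)")
  n_classified <- n_wt + sum(tab$count)
  if (anchor == "wild_type" && n_wt == 0) {
    warn("no wild-type reads; folds undefined under wild_type anchoring")
  }
  fold_of <- function(count, exp_prop) {
    if (anchor == "wild_type") {
      if (n_wt == 0) return(rep(NA_real_, length(count)))
      (count / n_wt) / (exp_prop / exp_wt)
    } else {
      (count / n_classified) / exp_prop
    }
  }
  variants_tab <- tab |>
    mutate(position = .data$variant_pos, base = .data$variant_base,
           expected = .data$proportion,
           fold = fold_of(.data$count, .data$proportion)) |>
    select("position", "base", "count", "expected", "fold") |>
    arrange(.data$position, .data$base)
  positions_tab <- tab |>
    group_by(position = .data$variant_pos) |>
    summarise(count = sum(.data$count), expected = sum(.data$proportion),
              .groups = "drop") |>
    mutate(fold = fold_of(.data$count, .data$expected)) |>
    arrange(.data$position)
  tallies <- tibble(
    reads_total = length(seqs),
    wild_type = n_wt,
    pool_variants = sum(tab$count),
    other = length(seqs) - short - n_wt - sum(tab$count),
    short = short,
    anchor = anchor
  )
  structure(list(variants = variants_tab, positions = positions_tab,
                 tallies = tallies),
            class = "penalty_table")
}

#' @export
print.penalty_table <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(
    "<penalty_table> %d reads: %d wild type, %d pool variants, %d other, %d short (anchor=%s)\n",
    t$reads_total, t$wild_type, t$pool_variants, t$other, t$short, t$anchor))
  print(x$positions)
  invisible(x)
}

#' @rdname penalty_analysis
#' @param x A `penalty_table`.
#' @param ... Unused.
#' @export
tidy.penalty_table <- function(x, ...) x$variants

#' @rdname penalty_analysis
#' @export
glance.penalty_table <- function(x, ...) x$tallies

#' Estimate the sequencing-error floor of an edit matrix
#'
#' Mean non-reference proportion at non-degenerate positions outside the
#' mutagenized window, a background estimate that reports sequencing error
#' rather than editing.  Reported alongside the metric, never subtracted
#' from it.
#'
#' @param matrix An `edit_matrix`.
#' @param window Mutagenized window (default 10).
#' @return A single proportion (NA when no positions qualify).
#' @export
error_floor <- function(matrix, window = 10) {
  stopifnot(inherits(matrix, "edit_matrix"))
  out <- matrix$nonref_prop[matrix$distance_from_3prime > window]
  if (all(is.na(out))) NA_real_ else mean(out, na.rm = TRUE)
}
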