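#' Load a barcode reference
#'
#' The first 20 bases of each FASTA entry (or `barcode` column) form the
#' barcode; entry names are construct ids.  Warns when the minimum pairwise
#' Hamming distance falls below 5, the separation that guarantees
#' unambiguous assignment at the 2-mismatch tolerance.
#'
#' @param ref A FASTA path, a tibble with `construct_id` and `barcode`
#'   columns, or a `construct_set`.
#' @param barcode_len Barcode length (default 20, the mapped read prefix).
#' @return A tibble `construct_id`, `barcode` of class `barcode_ref`.
#' @export
barcode_ref <- function(ref, barcode_len = 20) {
  if (is.character(ref) && length(ref) == 1) {
    fa <- read_fasta_tbl(ref)
    ref <- tibble(construct_id = fa$id, barcode = substr(fa$seq, 1, barcode_len))
  } else if (is.data.frame(ref)) {
    if (!all(c("construct_id", "barcode") %in% names(ref))) {
      abort("`ref` needs columns construct_id and barcode")
    }
    ref <- tibble(construct_id = ref$construct_id,
                  barcode = substr(ref$barcode, 1, barcode_len))
  } else {
    abort("`ref` must be a FASTA path or a data frame")
  }
  if (any(nchar(ref$barcode) != barcode_len)) {
    abort(sprintf("all barcodes must be %d bases long", barcode_len))
  }
  if (anyDuplicated(ref$barcode)) abort("barcode sequences must be unique")
  if (nrow(ref) > 1 && cpp_min_pairwise_dist(ref$barcode) < 5) {
    warn("minimum pairwise barcode distance < 5; assignments may be ambiguous")
  }
  structure(ref, class = c("barcode_ref", class(ref)))
}

#' Assign read prefixes to reference barcodes
#'
#' Each prefix is assigned to the unique reference barcode within `max_mm`
#' mismatches (Hamming distance; N bases count as mismatches).  Two
#' references tying at the minimal admissible distance give `ambiguous`;
#' none within `max_mm` gives `unassigned`.
#'
#' @param prefix Character vector of read prefixes, each exactly the
#'   barcode length.
#' @param ref A [barcode_ref()] (or anything it accepts).
#' @param max_mm Maximum mismatches allowed (default 2).
#' @return A tibble `prefix`, `construct_id` (`NA` unless assigned),
#'   `status` (`assigned` / `unassigned` / `ambiguous`).
#' @export
#' @examples
#' ref <- barcode_ref(tibble::tibble(
#'   construct_id = c("a", "b"),
#'   barcode = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA")
#' ))
#' assign_barcode("ACGTACGTACGTACGTACGA", ref)$status
assign_barcode <- function(prefix, ref, max_mm = 2) {
  if (!inherits(ref, "barcode_ref")) ref <- barcode_ref(ref)
  bl <- nchar(ref$barcode[1])
  if (any(nchar(prefix) != bl)) {
    abort(sprintf("prefixes must be exactly %d bases (truncated read?)", bl))
  }
  code <- cpp_assign_barcodes(toupper(prefix), ref$barcode, as.integer(max_mm))
  tibble(
    prefix = prefix,
    construct_id = ifelse(code > 0, ref$construct_id[pmax(code, 1)], NA_character_),
    status = dplyr::case_when(
      code > 0 ~ "assigned",
      code == -1 ~ "ambiguous",
      TRUE ~ "unassigned"
    )
  )
}

#' Quantify pool composition from barcode reads
#'
#' Maps the first `barcode_len` bases of every read against the barcode
#' reference with a `max_mm`-mismatch tolerance and reports per-construct
#' counts and percent abundance — the "expected" denominator for the
#' observed/expected edits metric.  Proportions are taken over assigned
#' reads only; unassigned, ambiguous and truncated reads are tallied
#' separately.
#'
#' @param reads A FASTQ path or read tibble (column `seq`).
#' @param ref A [barcode_ref()] (or anything it accepts).
#' @param max_mm Maximum mismatches allowed (default 2).
#' @param barcode_len Barcode length (default 20).
#' @return An object of class `barcode_counts`: list with `counts` (tibble
#'   `construct_id`, `count`, `proportion`, `percent`) and `summary`
#'   (totals by category).  [tidy()] returns the counts, [glance()] the
#'   summary; [as_abundance()] converts to an abundance table.
#' @export
quantify_barcodes <- function(reads, ref, max_mm = 2, barcode_len = 20) {
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0) abort("no reads to quantify")
  if (!inherits(ref, "barcode_ref")) ref <- barcode_ref(ref, barcode_len)
  if (nchar(ref$barcode[1]) != barcode_len) {
    abort("reference barcode length does not match `barcode_len`")
  }
  len_ok <- nchar(reads$seq) >= barcode_len
  truncated <- sum(!len_ok)
  asg <- assign_barcode(substr(reads$seq[len_ok], 1, barcode_len), ref,
                        max_mm = max_mm)
  counts <- tibble(construct_id = ref$construct_id) |>
    left_join(
      asg |> filter(.data$status == "assigned") |> count(.data$construct_id),
      by = "construct_id"
    ) |>
    mutate(count = tidyr::replace_na(.data$n, 0L), n = NULL)
  assigned <- sum(counts$count)
  counts <- counts |>
    mutate(proportion = if (assigned > 0) .data$count / assigned else NA_real_,
           percent = 100 * .data$proportion)
  summary <- tibble(
    total = nrow(reads),
    assigned = assigned,
    unassigned = sum(asg$status == "unassigned"),
    ambiguous = sum(asg$status == "ambiguous"),
    truncated = truncated
  )
  structure(list(counts = counts, summary = summary, max_mm = max_mm),
            class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<barcode_counts> %d reads: %d assigned, %d unassigned, %d ambiguous, %d truncated\n",
    s$total, s$assigned, s$unassigned, s$ambiguous, s$truncated))
  print(x$counts, n = 10)
  invisible(x)
}

#' @rdname quantify_barcodes
#' @param x A `barcode_counts` object.
#' @param ... Unused.
#' @export
tidy.barcode_counts <- function(x, ...) x$counts

#' @rdname quantify_barcodes
#' @export
glance.barcode_counts <- function(x, ...) x$summary

#' Convert barcode counts to an abundance table
#'
#' @param x A `barcode_counts` object.
#' @return A tibble `construct_id`, `proportion` usable as the expected
#'   pool composition in [observed_over_expected()].
#' @export
as_abundance <- function(x) {
  stopifnot(inherits(x, "barcode_counts"))
  x$counts |> select("construct_id", "proportion")
}

#' Write barcode quantification results
#'
#' @param x A `barcode_counts` object.
#' @param dir Output directory; writes `barcode_counts.tsv` and
#'   `barcode_summary.tsv`.
#' @return `dir`, invisibly.
#' @export
write_barcode_counts <- function(x, dir) {
  stopifnot(inherits(x, "barcode_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$counts, file.path(dir, "barcode_counts.tsv"))
  readr::write_tsv(x$summary, file.path(dir, "barcode_summary.tsv"))
  invisible(dir)
}
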