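IUPAC_CHARS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")

is_dna <- function(x, strict = FALSE) {
  chars <- if (strict) c("A", "C", "G", "T") else IUPAC_CHARS
  all(strsplit(x, "")[[1]] %in% chars)
}

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()],
#' IUPAC-aware.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GGACTACCAGGGTATCTAAT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

subchar <- function(x, pos, ch) {
  substr(x, pos, pos) <- ch
  x
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to a FASTQ file (gzip accepted).
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq_tbl <- function(path) {
  # the quality extraction drops (empty) metadata columns; not informative
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(
    s, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = unname(as.character(x)))
}

write_fasta <- function(ids, seqs, path) {
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- ids
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

as_read_tbl <- function(reads, arg = "reads") {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq_tbl(reads)
  if (!is.data.frame(reads) || !"seq" %in% names(reads)) {
    abort(sprintf("`%s` must be a FASTQ path or a tibble with a `seq` column", arg))
  }
  if (!"id" %in% names(reads)) reads$id <- sprintf("read_%d", seq_len(nrow(reads)))
  if (!"qual" %in% names(reads)) reads$qual <- strrep("I", nchar(reads$seq))
  as_tibble(reads)
}
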