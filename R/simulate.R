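#' @title Generative model of a primer-editing amplicon run
#' @description
#' Both simulated experiments share one aggregate two-factor model.  A
#' template (or primer) class carrying a single mismatch at 3'-distance
#' `p` amplifies with relative yield
#' \deqn{y = e_p + (1 - e_p) a_p}
#' where `e_p` is the per-position editing efficiency and `a_p` the
#' relative amplification efficiency of the unedited mismatch; matched
#' classes have yield 1.  Reads are sampled with probability proportional
#' to `abundance * yield`, and conditional on the class a read reflects the
#' edited outcome with probability `e_p / y`.  Uniform substitution errors
#' are applied afterward.
#' @name editing-model
#' @keywords internal
NULL

# Shared sampling core.  `classes` carries one row per template/primer
# class: id, abundance, variant_pos, seq_edited, seq_unedited (full
# amplicon sequences).
sim_core <- function(classes, editing, penalty, cfg, scheme, id_col) {
  p <- classes$variant_pos
  e <- ifelse(p == 0, 0, effective_efficiency(editing, p))
  a <- ifelse(p == 0, 1, effective_penalty(penalty, p))
  yield <- ifelse(p == 0, 1, e + (1 - e) * a)
  w <- classes$abundance * yield
  if (all(w == 0)) abort("every class has zero sampling weight")
  p_edit <- ifelse(yield > 0, e / pmax(yield, .Machine$double.eps), 0)

  n <- cfg$n_reads
  idx <- sample.int(nrow(classes), n, replace = TRUE, prob = w)
  edited <- runif(n) < p_edit[idx]
  molecule <- ifelse(edited, classes$seq_edited[idx], classes$seq_unedited[idx])

  amp_len <- nchar(classes$seq_unedited[1])
  rl <- cfg$read_length %||% amp_len
  full1 <- paste0(molecule, revcomp(scheme$rev_tail))
  full2 <- paste0(revcomp(molecule), revcomp(scheme$fwd_tail))
  r1 <- substr(full1, 1, rl)
  r2 <- substr(full2, 1, rl)
  e1 <- cpp_add_errors(r1, cfg$error_rate)
  e2 <- cpp_add_errors(r2, cfg$error_rate)
  ids <- sprintf("read_%06d", seq_len(n))
  q1 <- strrep(cfg$quality_char, nchar(e1$seq))
  q2 <- strrep(cfg$quality_char, nchar(e2$seq))
  join_pos <- function(l) {
    vapply(l, function(v) paste(v, collapse = ","), character(1))
  }
  truth <- tibble(
    read_id = ids,
    !!id_col := classes$id[idx],
    variant_pos = classes$variant_pos[idx],
    edited = edited,
    error_positions_r1 = join_pos(e1$error_positions),
    error_positions_r2 = join_pos(e2$error_positions)
  )
  list(
    reads1 = tibble(id = ids, seq = e1$seq, qual = q1),
    reads2 = tibble(id = ids, seq = e2$seq, qual = q2),
    truth = truth
  )
}

new_sim_run <- function(core, type, cfg, extra = list()) {
  structure(
    c(list(reads1 = core$reads1, reads2 = core$reads2, truth = core$truth,
           type = type, config = cfg), extra),
    class = "sim_run"
  )
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run:%s> %d read pairs, error_rate=%g, seed=%d\n",
              x$type, nrow(x$reads1), x$config$error_rate, x$config$seed))
  invisible(x)
}

#' Simulate an amplicon run on the standards pool
#'
#' Wild-type primers amplify the standards pool, whose members each carry a
#' single mismatch in the forward primer binding site.  Under the
#' generative model (see the package vignette) a read from the construct
#' with a variant at 3'-distance `p` shows the variant (template) base at
#' `p` with probability `e_p / (e_p + (1 - e_p) a_p)`, and constructs are
#' sampled proportionally to `abundance * yield`.  The reverse primer
#' region always matches its reference before sequencing error.
#'
#' @param constructs A `construct_set` from [build_construct_set()].
#' @param abundance Pool composition tibble (`construct_id`, `proportion`);
#'   defaults to the even pool.
#' @param editing An [editing_profile()].
#' @param penalty A [penalty_profile()].
#' @param cfg A [sim_config()].
#' @return A `sim_run` object holding `reads1`/`reads2` read tibbles and a
#'   per-read ground-truth tibble (`read_id`, `construct_id`, `edited`,
#'   error positions).  Deterministic for a fixed seed.
#' @export
simulate_standards_run <- function(constructs,
                                   abundance = even_abundance(constructs),
                                   editing = editing_profile(),
                                   penalty = penalty_profile(),
                                   cfg = sim_config()) {
  stopifnot(inherits(constructs, "construct_set"))
  abundance <- check_abundance(abundance, constructs)
  scheme <- attr(constructs, "scheme")
  a0 <- attr(constructs, "amplicon_start")
  alen <- attr(constructs, "amplicon_len")
  L <- nchar(scheme$fwd_locus)
  amp_variant <- substr(constructs$insert_seq, a0, a0 + alen - 1)
  wt_amp <- amp_variant[constructs$variant_pos == 0][1]
  classes <- tibble(
    id = constructs$construct_id,
    abundance = abundance$proportion,
    variant_pos = constructs$variant_pos,
    seq_edited = amp_variant,   # primer edited to match the template variant
    seq_unedited = wt_amp       # primer base retained at the mismatch
  )
  core <- withr::with_seed(cfg$seed,
    sim_core(classes, editing, penalty, cfg, scheme, "construct_id"))
  new_sim_run(core, "standards", cfg,
              list(scheme = scheme, primer_len = L))
}

#' Simulate the reciprocal variant-primer run
#'
#' An even pool of primers mirroring the standards pool (wild type plus
#' every single-base substitution in the 3' window) amplifies a wild-type
#' template.  The model mirrors [simulate_standards_run()]: a variant
#' primer at 3'-distance `p` is edited back to the template base with
#' probability `e_p`, unedited variant primers amplify at relative
#' efficiency `a_p`, and the read primer region records the final primer
#' sequence.
#'
#' @param wt_template DNA string containing both primer binding sites
#'   exactly once (e.g. [synthetic_template()]).
#' @param scheme A [primer_scheme()].
#' @param window Number of 3'-terminal positions mutagenized in the pool.
#' @param editing An [editing_profile()].
#' @param penalty A [penalty_profile()].
#' @param cfg A [sim_config()].
#' @return A `sim_run` with truth column `primer_id`.
#' @export
simulate_variant_primer_run <- function(wt_template, scheme = primer_scheme(),
                                        window = 10,
                                        editing = editing_profile(),
                                        penalty = penalty_profile(),
                                        cfg = sim_config()) {
  wt_template <- toupper(wt_template)
  fwd <- scheme$fwd_locus
  rev_rc <- revcomp(scheme$rev_locus)
  if (stringr::str_count(wt_template, stringr::fixed(fwd)) != 1 ||
      stringr::str_count(wt_template, stringr::fixed(rev_rc)) != 1) {
    abort("template must contain each primer site exactly once")
  }
  fwd_at <- as.integer(stringr::str_locate(wt_template,
                                           stringr::fixed(fwd))[1, "start"])
  rev_end <- as.integer(stringr::str_locate(wt_template,
                                            stringr::fixed(rev_rc))[1, "end"])
  wt_amp <- substr(wt_template, fwd_at, rev_end)
  L <- nchar(fwd)
  variants <- enumerate_variants(fwd, window)
  amp_variant <- vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$variant_pos[i]
    if (p == 0) wt_amp else subchar(wt_amp, L - p + 1, variants$variant_base[i])
  }, character(1))
  ids <- ifelse(variants$variant_pos == 0, "WT",
                sprintf("P%02d_%s", variants$variant_pos, variants$variant_base))
  classes <- tibble(
    id = ids,
    abundance = 1 / nrow(variants),
    variant_pos = variants$variant_pos,
    seq_edited = wt_amp,        # primer excised back to the template base
    seq_unedited = amp_variant  # unedited variant primer carried through
  )
  core <- withr::with_seed(cfg$seed,
    sim_core(classes, editing, penalty, cfg, scheme, "primer_id"))
  new_sim_run(core, "variant_primer", cfg,
              list(scheme = scheme, primer_len = L))
}

#' Simulate PCR-free barcode quantification reads
#'
#' Reads begin with the 20-base quantification barcode (as liberated by
#' restriction digest) followed by a constant downstream cassette spacer.
#' Counts are multinomial in the pool abundance; uniform substitution
#' errors are applied.
#'
#' @param constructs A `construct_set`.
#' @param abundance Pool composition; defaults to the even pool.
#' @param cfg A [sim_config()]; `read_length = NULL` gives 50-base reads.
#' @return A `sim_run` with single-end `reads1` and truth (`read_id`,
#'   `construct_id`).
#' @export
simulate_barcode_reads <- function(constructs,
                                   abundance = even_abundance(constructs),
                                   cfg = sim_config()) {
  stopifnot(inherits(constructs, "construct_set"))
  abundance <- check_abundance(abundance, constructs)
  bl <- nchar(constructs$barcode[1])
  rl <- cfg$read_length %||% 50L
  out <- withr::with_seed(cfg$seed, {
    spacer <- random_dna(1, max(rl - bl, 0))
    n <- cfg$n_reads
    idx <- sample.int(nrow(constructs), n, replace = TRUE,
                      prob = abundance$proportion)
    reads <- substr(paste0(constructs$barcode[idx], spacer), 1, rl)
    er <- cpp_add_errors(reads, cfg$error_rate)
    ids <- sprintf("bc_%06d", seq_len(n))
    list(
      reads1 = tibble(id = ids, seq = er$seq,
                      qual = strrep(cfg$quality_char, nchar(er$seq))),
      reads2 = NULL,
      truth = tibble(
        read_id = ids, construct_id = constructs$construct_id[idx],
        error_positions = vapply(er$error_positions,
                                 function(v) paste(v, collapse = ","),
                                 character(1))
      )
    )
  })
  new_sim_run(out, "barcode", cfg)
}

#' Write a simulated run to disk
#'
#' Emits `<prefix>_R1.fastq[.gz]` (and `_R2` for paired runs), a
#' ground-truth TSV and a YAML echo of the configuration.
#'
#' @param run A `sim_run`.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix (defaults to the run type).
#' @param gzip Compress FASTQ output.
#' @return Named list of written paths, invisibly.
#' @export
write_sim_run <- function(run, dir, prefix = run$type, gzip = FALSE) {
  stopifnot(inherits(run, "sim_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- list()
  paths$r1 <- file.path(dir, paste0(prefix, "_R1", ext))
  write_fastq(run$reads1, paths$r1)
  if (!is.null(run$reads2)) {
    paths$r2 <- file.path(dir, paste0(prefix, "_R2", ext))
    write_fastq(run$reads2, paths$r2)
  }
  paths$truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  readr::write_tsv(run$truth, paths$truth)
  paths$config <- file.path(dir, paste0(prefix, "_config.yaml"))
  cfgl <- run$config
  class(cfgl) <- NULL
  yaml::write_yaml(c(list(type = run$type), cfgl), paths$config)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
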