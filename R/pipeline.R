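#' Run the full standards pipeline
#'
#' End-to-end run: design the construct set, simulate barcode reads and
#' quantify pool composition, simulate the standards amplicon run, trim,
#' merge and profile the primer region, compute the observed/expected
#' table, and run the reciprocal variant-primer penalty analysis.  All
#' randomness flows from the single `seed` through fixed per-stage
#' substreams, so reruns with the same configuration are byte-identical.
#'
#' @param config A YAML path or nested list.  Recognised fields (all
#'   optional, defaults in parentheses): `seed` (1), `outdir` (required
#'   unless `write = FALSE`), `design`: `window` (10), `flank_len` (20),
#'   `template_len` (332); `sim`: `n_reads` (50000), `error_rate` (0),
#'   `editing`: `efficiencies`, `block_after`, `label`; `penalty`:
#'   `penalties`; `barcode`: `n_reads` (31000), `error_rate` (0);
#'   `analysis`: `max_mm` (3), `anchor` ("wild_type").
#' @param write Write artifacts under `config$outdir` (default `TRUE`).
#' @return Invisibly, a list with the constructs, barcode counts, edit
#'   matrix, obs/exp table, penalty table and output paths.
#' @export
run_pipeline <- function(config, write = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path")
  if (write && is.null(config$outdir)) {
    abort("`config$outdir` is required when write = TRUE")
  }
  seed <- as.integer(config$seed %||% 1L)
  des <- config$design %||% list()
  sim <- config$sim %||% list()
  bcfg <- config$barcode %||% list()
  ana <- config$analysis %||% list()

  window <- as.integer(des$window %||% 10L)
  flank_len <- as.integer(des$flank_len %||% 20L)
  template_len <- as.integer(des$template_len %||% 332L)
  scheme <- primer_scheme()
  # distinct, fixed substream offsets per stage (all well below 2^31)
  s_design <- seed * 13L + 1L
  s_barcode <- seed * 13L + 3L
  s_standards <- seed * 13L + 5L
  s_penalty <- seed * 13L + 7L

  template <- synthetic_template(scheme, total_len = template_len,
                                 seed = s_design)
  constructs <- build_construct_set(template, scheme, window = window,
                                    flank_len = flank_len, seed = s_design)

  editing <- editing_profile(
    efficiencies = unlist(sim$editing$efficiencies %||% rep(1, 6)),
    block_after = sim$editing$block_after %||% Inf,
    label = sim$editing$label %||% "configured"
  )
  penalty <- penalty_profile(unlist(sim$penalty$penalties %||% numeric(0)))

  bc_run <- simulate_barcode_reads(
    constructs,
    cfg = sim_config(n_reads = bcfg$n_reads %||% 31000,
                     error_rate = bcfg$error_rate %||% 0, seed = s_barcode)
  )
  bc <- quantify_barcodes(bc_run$reads1, barcode_ref(constructs))
  abundance <- as_abundance(bc)

  std_cfg <- sim_config(n_reads = sim$n_reads %||% 50000,
                        error_rate = sim$error_rate %||% 0,
                        seed = s_standards)
  std <- simulate_standards_run(constructs, abundance = even_abundance(constructs),
                                editing = editing, penalty = penalty,
                                cfg = std_cfg)
  ad <- readthrough_adapters(scheme)
  r1 <- trim_adapters(std$reads1, ad$r1)
  r2 <- trim_adapters(std$reads2, ad$r2)
  merged <- merge_pairs(r1, r2)
  max_mm <- ana$max_mm %||% 3
  em <- profile_primer_region(merged, scheme$fwd_locus, max_mm = max_mm)
  oe <- observed_over_expected(em, constructs, abundance = abundance)

  pen_cfg <- sim_config(n_reads = sim$n_reads %||% 50000,
                        error_rate = sim$error_rate %||% 0, seed = s_penalty)
  pen_run <- simulate_variant_primer_run(template, scheme, window = window,
                                         editing = editing, penalty = penalty,
                                         cfg = pen_cfg)
  pen_merged <- merge_pairs(trim_adapters(pen_run$reads1, ad$r1),
                            trim_adapters(pen_run$reads2, ad$r2))
  pen <- penalty_analysis(pen_merged, scheme, window = window,
                          anchor = ana$anchor %||% "wild_type")

  paths <- NULL
  if (write) {
    outdir <- config$outdir
    if (is.null(outdir)) abort("`config$outdir` is required when write = TRUE")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_construct_set(constructs, outdir)
    write_sim_run(std, outdir, prefix = "standards")
    write_sim_run(bc_run, outdir, prefix = "barcode")
    write_barcode_counts(bc, outdir)
    readr::write_tsv(as_tibble(em), file.path(outdir, "edit_matrix.tsv"))
    readr::write_tsv(as_tibble(oe), file.path(outdir, "obs_exp.tsv"))
    readr::write_tsv(pen$variants, file.path(outdir, "penalty.tsv"))
    readr::write_tsv(pen$positions, file.path(outdir, "penalty_positions.tsv"))
    summary <- c(
      as.list(glance(em)),
      list(merge_rate = mean(merged$merged),
           error_floor = error_floor(em, window))
    )
    writeLines(yaml::as.yaml(summary), file.path(outdir, "summary.yaml"))
    yaml::write_yaml(config, file.path(outdir, "config.yaml"))
    paths <- outdir
  }
  invisible(list(constructs = constructs, barcode_counts = bc,
                 edit_matrix = em, obs_exp = oe, penalty = pen,
                 merged = merged, outdir = paths))
}

#' Summarise a pipeline run directory as markdown
#'
#' Reads the tables written by [run_pipeline()] and renders a plain-text
#' summary: a per-position observed/expected table with an edited call
#' (ratio >= 0.5) and the per-position penalty folds from the reciprocal
#' experiment.  Missing tables are listed and skipped.
#'
#' @param dir A [run_pipeline()] output directory.
#' @return Character vector of markdown lines, invisibly; also printed.
#' @export
report_run <- function(dir) {
  lines <- character(0)
  oe_path <- file.path(dir, "obs_exp.tsv")
  pen_path <- file.path(dir, "penalty_positions.tsv")
  found <- FALSE
  if (file.exists(oe_path)) {
    found <- TRUE
    oe <- readr::read_tsv(oe_path, show_col_types = FALSE)
    lines <- c(lines, "## Observed/expected edits by distance from 3' end", "",
               "| position | observed | expected | obs/exp | call |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(oe))) {
      r <- oe$ratio[i]
      call <- if (is.na(r)) "undefined" else if (r >= 0.5) "edited" else "not edited"
      lines <- c(lines, sprintf(
        "| %d | %.4f | %.4f | %s | %s |",
        oe$distance_from_3prime[i], oe$observed[i], oe$expected[i],
        ifelse(is.na(r), "NA", sprintf("%.3f", r)), call))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, sprintf("missing: %s (skipped)", oe_path))
  }
  if (file.exists(pen_path)) {
    found <- TRUE
    pen <- readr::read_tsv(pen_path, show_col_types = FALSE)
    lines <- c(lines, "## Variant-primer fold of expected by position", "",
               "| position | count | expected | fold |", "|---|---|---|---|")
    for (i in seq_len(nrow(pen))) {
      lines <- c(lines, sprintf(
        "| %d | %d | %.4f | %s |", pen$position[i], pen$count[i],
        pen$expected[i],
        ifelse(is.na(pen$fold[i]), "NA", sprintf("%.3f", pen$fold[i]))))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, sprintf("missing: %s (skipped)", pen_path))
  }
  if (!found) lines <- c("no analyses found", lines)
  cat(lines, sep = "\n")
  invisible(lines)
}
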