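#' @keywords internal
.config_template <- function() {
  list(
    seed = NA_integer_,
    output_dir = NA_character_,
    insertions = NA_character_,
    simulate = list(
      catalog = list(n_genes = NA, chrom_lengths = list(),
                     gene_length = c(NA, NA), n_exons = c(NA, NA)),
      screen = list(n_tumours = list(), background_rate = NA,
                    hopping_factor = NA, donor_chrom = list(),
                    drivers = list()),
      reads = list(enabled = NA, error_rate = NA, contaminant_fraction = NA,
                   read_length = NA, flank = c(NA, NA))
    ),
    cis = list(alpha = NA, theta = NA, upstream = NA, exclude_donor = NA),
    classify = list(alpha = NA, cluster_min = NA, min_insertions = NA,
                    window_frac = NA),
    breakpoint = list(enabled = NA, exon_lengths = list(), breakpoint_exon = NA,
                      fold = NA, depth = NA, n_trapped = NA, n_control = NA,
                      min_fold = NA),
    correlate = list(enabled = NA, n_patients = NA, k = NA, alpha = NA,
                     base_tnbc_rate = NA, effect_genes = list())
  )
}

.config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("sbdrivers_config_error", "error")))
}
.data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("sbdrivers_data_error", "error")))
}

# reject unknown keys anywhere in the config tree
.check_config_keys <- function(config, template = .config_template(), path = "") {
  if (!is.list(config)) return(invisible(TRUE))
  leaf_lists <- c("chrom_lengths", "n_tumours", "donor_chrom", "drivers",
                  "effect_genes", "exon_lengths", "gene_length", "n_exons",
                  "flank")
  for (key in names(config)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(template))
      .config_error("unknown configuration key: ", full)
    if (is.list(config[[key]]) && !key %in% leaf_lists)
      .check_config_keys(config[[key]], template[[key]], full)
  }
  invisible(TRUE)
}

#' Run the screen-analysis pipeline from a single configuration
#'
#' Executes the stages in dependency order — simulate (or load) insertions,
#' optionally emit and re-process junction reads, CIS scan and recurrence
#' filter per Cre group, group combination, driver classification, and the
#' optional exon-breakpoint and subtype-correlation stages — and returns a
#' machine-readable run report. All randomness derives from the single
#' top-level `seed`, so an identical configuration reproduces identical
#' outputs; the report embeds every parameter and seed needed to re-run.
#'
#' @param config a configuration list or the path to a YAML file. Recognised
#'   sections: `seed` (required), `output_dir`, `insertions` (path to a
#'   pre-mapped insertion TSV; real-data entry point), `simulate`
#'   (`catalog`, `screen`, `reads`), `cis`, `classify`, `breakpoint`,
#'   `correlate`. Unknown keys are rejected by name.
#' @return a `pipeline_report` list: parameters, per-stage record counts,
#'   candidate tables per group, the combined gene sets, driver calls, and
#'   any breakpoint/correlation results. When `output_dir` is set, tables are
#'   written as TSV and the report as `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) .data_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .config_error("config must be a list or YAML path")
  .check_config_keys(config)
  if (is.null(config$seed)) .config_error("config must set a top-level seed")
  seed <- as.integer(config$seed)
  report <- list(parameters = config, stages = list())

  cis_par <- utils::modifyList(list(alpha = 0.05, theta = 0.05, upstream = 3000,
                                    exclude_donor = FALSE),
                               config$cis %||% list())
  cls_par <- utils::modifyList(list(alpha = 0.05, cluster_min = 0.5,
                                    min_insertions = 5, window_frac = 0.2),
                               config$classify %||% list())

  # ---- stage 1: insertions (load or simulate) ----
  catalog <- NULL
  if (!is.null(config$insertions)) {
    if (!file.exists(config$insertions))
      .data_error("input file not found: ", config$insertions)
    ins <- read_insertions(config$insertions)
    report$stages$input <- list(file = config$insertions, sites = nrow(ins))
  } else {
    sim <- config$simulate %||% list()
    cat_par <- sim$catalog %||% list()
    cat_args <- list(seed = seed)
    if (!is.null(cat_par$n_genes)) cat_args$n_genes <- cat_par$n_genes
    if (!is.null(cat_par$chrom_lengths))
      cat_args$chrom_lengths <- unlist(cat_par$chrom_lengths)
    if (!is.null(cat_par$gene_length)) cat_args$gene_length <- unlist(cat_par$gene_length)
    if (!is.null(cat_par$n_exons)) cat_args$n_exons <- unlist(cat_par$n_exons)
    catalog <- do.call(make_gene_catalog, cat_args)

    scr <- sim$screen %||% list()
    drivers <- lapply(scr$drivers %||% list(), function(d) {
      do.call(driver_spec, d[!vapply(d, is.null, logical(1))])
    })
    sc_args <- list(seed = seed + 1L, drivers = drivers)
    if (!is.null(scr$n_tumours)) {
      nt <- scr$n_tumours
      sc_args$n_tumours <- if (is.data.frame(nt)) nt else
        do.call(rbind, lapply(nt, function(x) data.frame(
          strain = as.character(x$strain), cre = x$cre, n = x$n)))
    }
    if (!is.null(scr$background_rate)) sc_args$background_rate <- scr$background_rate
    if (!is.null(scr$hopping_factor)) sc_args$hopping_factor <- scr$hopping_factor
    if (!is.null(scr$donor_chrom)) sc_args$donor_chrom <- unlist(scr$donor_chrom)
    sconf <- do.call(screen_config, sc_args)

    reads_par <- sim$reads %||% list()
    if (isTRUE(reads_par$enabled)) {
      genome <- make_genome(catalog$chrom_lengths, seed = seed + 2L)
      truth_ins <- simulate_screen(catalog, sconf, genome = genome)
      rc_args <- list(seed = seed + 3L)
      for (f in c("error_rate", "contaminant_fraction", "read_length", "flank"))
        if (!is.null(reads_par[[f]])) rc_args[[f]] <- unlist(reads_par[[f]])
      reads <- emit_reads(truth_ins, genome, do.call(read_config, rc_args))
      trimmed <- trim_reads(reads)
      located <- locate_insertions(trimmed, genome)
      acc <- located[is.na(located$reject_reason), , drop = FALSE]
      ins <- dedupe_sites(acc)
      attr(ins, "tumours") <- attr(truth_ins, "tumours")
      attr(ins, "truth") <- attr(truth_ins, "truth")
      attr(ins, "donor_chrom") <- attr(truth_ins, "donor_chrom")
      report$stages$reads <- list(
        emitted = nrow(reads),
        trim = as.list(rejection_summary(trimmed)),
        locate = as.list(rejection_summary(located)),
        sites = nrow(ins))
    } else {
      ins <- simulate_screen(catalog, sconf)
    }
    report$stages$simulate <- list(
      genes = nrow(catalog$genes),
      tumours = nrow(attr(ins, "tumours")),
      sites = nrow(ins),
      planted = if (is.null(attr(ins, "truth"))) 0L else
        length(unique(attr(ins, "truth")$gene_id)))
  }
  if (is.null(catalog))
    .config_error("real-data runs need gene models; supply simulate.catalog")

  # ---- stage 2: CIS per Cre group + recurrence filter ----
  groups <- sort(unique(ins$cre))
  roster <- attr(ins, "tumours")
  candidates <- list()
  for (g in groups) {
    sub <- ins[ins$cre == g, , drop = FALSE]
    attr(sub, "tumours") <- roster[roster$cre == g, , drop = FALSE]
    attr(sub, "donor_chrom") <- attr(ins, "donor_chrom")
    class(sub) <- class(ins)
    cis <- gene_cis_scan(sub, catalog, alpha = cis_par$alpha,
                         upstream = cis_par$upstream,
                         exclude_donor = cis_par$exclude_donor)
    candidates[[g]] <- recurrence_filter(cis, theta = cis_par$theta, group = g)
    report$stages$cis[[g]] <- list(tumours = nrow(attr(sub, "tumours")),
                                   sites = nrow(sub),
                                   cis_genes = nrow(cis),
                                   candidates = nrow(candidates[[g]]))
  }

  combined <- if (length(candidates) >= 2) {
    combine_groups(candidates[[1]], candidates[[2]])
  } else {
    combine_groups(candidates[[1]], character(0))
  }
  report$combined <- as.list(combined$sizes)

  # ---- stage 3: driver classification over the union ----
  calls <- classify_candidates(combined$union, ins, catalog,
                               upstream = cis_par$upstream,
                               window_frac = cls_par$window_frac,
                               alpha = cls_par$alpha,
                               cluster_min = cls_par$cluster_min,
                               min_insertions = cls_par$min_insertions)
  report$stages$classify <- as.list(table(calls$class))

  # ---- optional: exon breakpoint demonstration stage ----
  breakpoint <- NULL
  bp_par <- config$breakpoint %||% list()
  if (isTRUE(bp_par$enabled)) {
    bp_args <- list(seed = seed + 4L)
    for (f in c("exon_lengths", "breakpoint_exon", "fold", "depth",
                "n_trapped", "n_control"))
      if (!is.null(bp_par[[f]])) bp_args[[f]] <- unlist(bp_par[[f]])
    ec <- do.call(simulate_exon_counts, bp_args)
    norm <- normalize_exon_counts(ec$counts, ec$lib_sizes, ec$exon_lengths)
    breakpoint <- detect_breakpoint(norm[, ec$group == "trapped", drop = FALSE],
                                    norm[, ec$group == "control", drop = FALSE],
                                    min_fold = bp_par$min_fold %||% 2)
    report$stages$breakpoint <- list(b = breakpoint$b, fold = breakpoint$fold)
  }

  # ---- optional: two-database subtype-correlation stage ----
  consensus <- NULL
  co_par <- config$correlate %||% list()
  if (isTRUE(co_par$enabled)) {
    n_pat <- co_par$n_patients %||% 1000L
    eff <- unlist(co_par$effect_genes %||% list())
    if (is.null(eff)) eff <- c(effect1 = 2)
    k <- co_par$k %||% 10L
    db1 <- simulate_patient_cohort(n_pat, eff, seed = seed + 5L,
                                   base_tnbc_rate = co_par$base_tnbc_rate %||% 0.15)
    db2 <- simulate_patient_cohort(n_pat, eff, seed = seed + 6L,
                                   base_tnbc_rate = co_par$base_tnbc_rate %||% 0.15)
    s1 <- tnbc_screen(db1, k = k, alpha = co_par$alpha %||% 0.05)
    s2 <- tnbc_screen(db2, k = k, alpha = co_par$alpha %||% 0.05)
    consensus <- cross_db_consensus(s1, s2, alpha = co_par$alpha %||% 0.05)
    report$stages$correlate <- list(genes = nrow(consensus),
                                    consensus = sum(consensus$consensus))
  }

  report$candidates <- lapply(candidates, as.data.frame)
  report$union <- combined$union
  report$intersection <- combined$intersection
  report$driver_calls <- as.data.frame(calls)
  if (!is.null(breakpoint))
    report$breakpoint <- breakpoint[c("gene_id", "b", "fold", "score")]
  if (!is.null(consensus)) report$consensus <- consensus
  class(report) <- "pipeline_report"

  outdir <- config$output_dir
  if (!is.null(outdir) && !is.na(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_insertions(ins, file.path(outdir, "insertions.tsv"))
    for (g in names(candidates))
      utils::write.table(as.data.frame(candidates[[g]]),
                         file.path(outdir, paste0("candidates_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(calls, file.path(outdir, "driver_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(consensus))
      utils::write.table(consensus, file.path(outdir, "consensus.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("SB screen pipeline report\n")
  if (!is.null(x$stages$simulate))
    cat(sprintf("  simulated: %d tumours, %d sites, %d genes\n",
                x$stages$simulate$tumours, x$stages$simulate$sites,
                x$stages$simulate$genes))
  for (g in names(x$candidates))
    cat(sprintf("  %s candidates: %d\n", g, nrow(x$candidates[[g]])))
  cat(sprintf("  union %d genes (%d overlapping)\n",
              x$combined[["union"]], x$combined[["intersection"]]))
  if (!is.null(x$driver_calls)) {
    tab <- table(x$driver_calls$class)
    cat("  classification:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
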