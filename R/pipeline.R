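pipeline_config_keys <- list(
  top = c("simulate", "inputs", "filter", "do_histogram_transform", "dmc",
          "dmr", "overlap", "select", "enrichment", "expression", "seed"),
  simulate = c("n_control", "n_obese", "n_crc", "n_chrom", "cpg_per_chrom",
               "coverage_mean", "dispersion", "age_slope", "planted",
               "island_fraction", "n_background_genes"),
  planted = c("n_obesity_only", "n_crc_only", "n_concordant_hyper",
              "n_concordant_hypo", "n_discordant", "n_cpgs", "effect"),
  inputs = c("coverage_files", "sample_sheet", "genes", "islands",
             "gene_sets", "counts", "expression_samples"),
  filter = c("min_coverage", "max_coverage_quantile", "excluded_chroms"),
  dmc = c("min_diff_pct", "max_q", "min_per_group"),
  dmr = c("min_cpgs", "min_dmcs", "min_mean_diff", "fallback_cutoff"),
  overlap = c("min_overlap_bp"),
  select = c("alpha", "require_pairs"),
  enrichment = c("alpha"),
  expression = c("n_genes", "n_de", "lfc", "base_mean")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("pipeline config: unknown key(s) %s in '%s'",
                         paste(bad, collapse = ", "), where))
  }
}

#' Validate a pipeline configuration
#'
#' A pipeline config is a nested list (typically read from YAML with
#' [read_pipeline_config()]) with sections `simulate` (or `inputs`),
#' `filter`, `dmc`, `dmr`, `overlap`, `select`, `enrichment`,
#' `expression`, plus `do_histogram_transform` and `seed`. Unknown keys
#' are rejected before any stage runs.
#'
#' @param config Nested configuration list.
#' @return The config, invisibly, if valid.
#' @export
validate_pipeline_config <- function(config) {
  check_keys(config, pipeline_config_keys$top, "top level")
  for (sec in c("simulate", "inputs", "filter", "dmc", "dmr", "overlap",
                "select", "enrichment", "expression")) {
    if (!is.null(config[[sec]])) check_keys(config[[sec]],
                                            pipeline_config_keys[[sec]], sec)
  }
  if (!is.null(config$simulate$planted)) {
    check_keys(config$simulate$planted, pipeline_config_keys$planted,
               "simulate$planted")
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    rlang::abort("pipeline config: need either 'simulate' or 'inputs'")
  }
  invisible(config)
}

#' @rdname validate_pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_pipeline_config(config)
  config
}

#' Default small synthetic end-to-end configuration
#'
#' The bundled smoke configuration: a synthetic cohort at the
#' motivating study's group sizes (15 controls, 10 obese, 15 CRC) over
#' two chromosomes of 1,200 background CpGs each, with 40 planted
#' regions (eight per concordance class) of five CpGs at an absolute
#' effect of 0.3, plus a 200-gene two-condition expression matrix with
#' twelve planted fold-changes.
#'
#' @param seed Master seed.
#' @return A validated pipeline config list.
#' @export
smoke_config <- function(seed = 1L) {
  validate_pipeline_config(list(
    simulate = list(
      n_control = 15, n_obese = 10, n_crc = 15,
      n_chrom = 2, cpg_per_chrom = 1200, coverage_mean = 30,
      dispersion = 0.05,
      planted = list(n_obesity_only = 8, n_crc_only = 8,
                     n_concordant_hyper = 8, n_concordant_hypo = 8,
                     n_discordant = 8, n_cpgs = 5, effect = 0.3),
      island_fraction = 0.4, n_background_genes = 12),
    do_histogram_transform = TRUE,
    expression = list(n_genes = 200, n_de = 12, lfc = 2, base_mean = 100),
    seed = as.integer(seed)))
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    s <- config$simulate
    planted <- if (!is.null(s$planted)) do.call(make_planted_regions, s$planted)
    cfg <- sim_config(
      n_control = s$n_control %||% 15, n_obese = s$n_obese %||% 10,
      n_crc = s$n_crc %||% 15, n_chrom = s$n_chrom %||% 2,
      cpg_per_chrom = s$cpg_per_chrom %||% 1200,
      coverage_mean = s$coverage_mean %||% 30,
      dispersion = s$dispersion %||% 0.05,
      age_slope = s$age_slope %||% 0.002,
      planted_regions = planted, seed = config$seed %||% 1L)
    sim <- simulate_methylation(cfg)
    ann <- simulate_annotation(sim,
                               n_background_genes = s$n_background_genes %||% 10,
                               island_fraction = s$island_fraction %||% 0.4)
    list(calls = sim$calls, sheet = sim$sheet, annotation = ann$annotation,
         truth = ann$truth, gene_sets = NULL)
  } else {
    inp <- config$inputs
    calls <- purrr::map_dfr(inp$coverage_files, read_coverage_file)
    list(calls = calls, sheet = read_sample_sheet(inp$sample_sheet),
         annotation = read_annotation(inp$genes, inp$islands),
         truth = NULL,
         gene_sets = if (!is.null(inp$gene_sets)) read_gmt(inp$gene_sets))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full cross-contrast methylation pipeline
#'
#' Stages, in order: preprocess (coverage/chromosome filters, coverage
#' normalization, histogram transform of each case group to the control
#' pool), DMC calling for the obesity and CRC contrasts, DMR
#' segmentation per contrast, cross-contrast overlap of DMCs and DMRs
#' with direction-concordance chi-square tests, genomic-context
#' annotation and distribution profiling, nonparametric candidate-DMR
#' selection, gene-set enrichment of the selected genes (when a
#' collection is supplied), and the expression concordance check. Every
#' stage's record counts are logged; all stage tables plus a summary
#' JSON are written under `outdir`. Rerunning with the same config and
#' seed reproduces the outputs byte-identically.
#'
#' @param config A validated pipeline config (see
#'   [validate_pipeline_config()], [smoke_config()]).
#' @param outdir Output directory for the report bundle.
#' @return An object of class `methcrossover_run`: a list with the
#'   stage results (`dmcs`, `dmrs`, `overlap`, `profile`, `selection`,
#'   `enrichment`, `expression`, `summary`, `paths`).
#' @export
run_pipeline <- function(config, outdir) {
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)))
    })
  }

  inputs <- run_stage("load", load_pipeline_inputs(config))
  calls <- inputs$calls
  sheet <- inputs$sheet
  stage_log("load", "%d call records, %d samples", nrow(calls), nrow(sheet))

  fp <- do.call(filter_policy, config$filter %||% list())
  calls <- run_stage("preprocess", {
    x <- filter_calls(calls, fp)
    x <- normalize_coverage(x)
    if (isTRUE(config$do_histogram_transform %||% TRUE)) {
      ctrl_ids <- sheet$sample_id[sheet$group == "control"]
      ctrl <- dplyr::filter(x, .data$sample_id %in% ctrl_ids)
      cases <- dplyr::filter(x, !(.data$sample_id %in% ctrl_ids))
      dplyr::bind_rows(ctrl, histogram_transform(cases, ctrl))
    } else x
  })
  stage_log("preprocess", "%d call records after filtering", nrow(calls))

  thr <- do.call(dmc_thresholds, config$dmc %||% list())
  dmcs <- run_stage("dmc", list(
    obesity = call_dmcs(calls, sheet, "obesity", thr),
    crc = call_dmcs(calls, sheet, "crc", thr)))
  stage_log("dmc", "obesity: %d tested / %d significant; crc: %d / %d",
            nrow(dmcs$obesity), sum(dmcs$obesity$significant),
            nrow(dmcs$crc), sum(dmcs$crc$significant))

  dmr_cfg <- config$dmr %||% list()
  filters <- dmr_filters(min_cpgs = dmr_cfg$min_cpgs %||% 3,
                         min_dmcs = dmr_cfg$min_dmcs %||% 1,
                         min_mean_diff = dmr_cfg$min_mean_diff %||% 5)
  dmrs <- run_stage("dmr", {
    lapply(dmcs, function(d) {
      cutoff <- distance_cutoff(d, fallback = dmr_cfg$fallback_cutoff %||% 100)
      call_dmrs(d, cutoff, filters)
    })
  })
  stage_log("dmr", "obesity: %d regions; crc: %d regions",
            nrow(dmrs$obesity), nrow(dmrs$crc))

  min_bp <- (config$overlap %||% list())$min_overlap_bp %||% 1
  ov <- run_stage("overlap", list(
    dmc = overlap_dmcs(dmcs$crc, dmcs$obesity, labels = c("crc", "obesity")),
    dmr = overlap_dmrs(dmrs$crc, dmrs$obesity, min_overlap_bp = min_bp,
                       labels = c("crc", "obesity"))))
  stage_log("overlap", "DMC overlap: %d; DMR overlap: %d",
            ov$dmc$n_overlap, ov$dmr$n_overlap)

  profile <- run_stage("annotate", {
    paired_a <- ov$dmr$pairs$id_a %||% character(0)
    feature_sets <- dplyr::bind_rows(
      dmrs$crc |> dplyr::filter(!(.data$dmr_id %in% paired_a)) |>
        dplyr::mutate(set = "crc_only"),
      dmrs$obesity |>
        dplyr::filter(!(.data$dmr_id %in% (ov$dmr$pairs$id_b %||% character(0)))) |>
        dplyr::mutate(set = "obesity_only"),
      dmrs$crc |> dplyr::filter(.data$dmr_id %in% paired_a) |>
        dplyr::mutate(set = "overlap"))
    annotated <- annotate_features(
      feature_sets[, c("dmr_id", "chrom", "start", "end", "direction", "set")],
      inputs$annotation)
    list(annotated = annotated,
         profile = if (nrow(annotated) > 0) distribution_profile(annotated))
  })

  sel_cfg <- config$select %||% list()
  selection <- run_stage("select", {
    overlap_ids <- ov$dmr$pairs$id_a %||% character(0)
    odmrs <- dmrs$crc[dmrs$crc$dmr_id %in% overlap_ids, , drop = FALSE]
    if (nrow(odmrs) == 0L) {
      list(means = NULL, table = NULL)
    } else {
      means <- dmr_subject_means(odmrs, calls)
      ann <- profile$annotated[profile$annotated$set == "overlap",
                               c("dmr_id", "subregion", "gene_id")]
      tab <- select_dmrs(means, sheet, alpha = sel_cfg$alpha %||% 0.1,
                         annotated = ann,
                         require_pairs = sel_cfg$require_pairs %||% "case_vs_control")
      tab <- dplyr::left_join(tab, ann[, c("dmr_id", "gene_id")], by = "dmr_id")
      list(means = means, table = tab)
    }
  })
  n_sel <- if (is.null(selection$table)) 0L else sum(selection$table$selected)
  n_sel_gene <- if (is.null(selection$table)) 0L
    else sum(selection$table$selected_gene, na.rm = TRUE)
  stage_log("select", "%d selected, %d in promoter/gene body", n_sel, n_sel_gene)

  enr <- run_stage("enrich", {
    if (is.null(inputs$gene_sets) || is.null(selection$table)) NULL else {
      query <- unique(stats::na.omit(
        selection$table$gene_id[selection$table$selected_gene]))
      if (length(query) == 0L) NULL else {
        enrich_all(query, inputs$gene_sets,
                   background = unique(inputs$annotation$genes$gene_id),
                   alpha = (config$enrichment %||% list())$alpha %||% 0.05)
      }
    }
  })

  expr <- run_stage("expression", {
    ecfg <- config$expression
    if (is.null(ecfg)) NULL else {
      n_genes <- ecfg$n_genes %||% 200
      n_de <- min(ecfg$n_de %||% 12, n_genes)
      lfc <- ecfg$lfc %||% 2
      et <- tibble::tibble(
        gene_id = sprintf("g%04d", seq_len(n_de)),
        lfc = lfc * rep_len(c(1, -1), n_de))
      sim <- simulate_expression(n_genes, effect_table = et,
                                 base_mean = ecfg$base_mean %||% 100,
                                 seed = (config$seed %||% 1L) + 101L)
      fac <- tmm_factors(sim$counts)
      lc <- log_cpm(sim$counts, fac)
      expectations <- tibble::tibble(
        gene_id = et$gene_id, expected = ifelse(et$lfc > 0, "up", "down"))
      list(counts = sim$counts, factors = fac, logcpm = lc,
           concordance = concordance_report(lc, sim$samples, expectations,
                                            conditions = c("WT", "DKO")))
    }
  })

  summary <- list(
    seed = config$seed %||% 1L,
    n_samples = nrow(sheet),
    n_sites_after_filter = length(unique(paste(calls$chrom, calls$pos))),
    dmc = list(
      tested = list(obesity = nrow(dmcs$obesity), crc = nrow(dmcs$crc)),
      significant = list(obesity = sum(dmcs$obesity$significant),
                         crc = sum(dmcs$crc$significant)),
      venn = list(crc_only = ov$dmc$n_a_only, obesity_only = ov$dmc$n_b_only,
                  overlap = ov$dmc$n_overlap),
      quadrant = if (!is.null(ov$dmc$quadrant)) as.vector(ov$dmc$quadrant),
      chi2 = ov$dmc$chi2, chi2_p = ov$dmc$chi2_p,
      concordant_fraction = ov$dmc$concordant_fraction,
      pct_of_obesity = if (ov$dmc$n_overlap + ov$dmc$n_b_only > 0)
        overlap_fraction(ov$dmc, "b") else NA),
    dmr = list(
      called = list(obesity = nrow(dmrs$obesity), crc = nrow(dmrs$crc)),
      venn = list(crc_only = ov$dmr$n_a_only, obesity_only = ov$dmr$n_b_only,
                  overlap = ov$dmr$n_overlap),
      quadrant = if (!is.null(ov$dmr$quadrant)) as.vector(ov$dmr$quadrant),
      chi2 = ov$dmr$chi2, chi2_p = ov$dmr$chi2_p,
      concordant_fraction = ov$dmr$concordant_fraction,
      pct_of_obesity = if (ov$dmr$n_overlap + ov$dmr$n_b_only > 0)
        overlap_fraction(ov$dmr, "b") else NA),
    selection = list(selected = n_sel, selected_gene = n_sel_gene),
    enrichment = list(n_terms = if (is.null(enr)) 0L else nrow(enr)),
    expression = list(
      n_agree = if (is.null(expr)) NA else sum(expr$concordance$status == "agree"),
      n_expected = if (is.null(expr)) NA else nrow(expr$concordance)))

  paths <- run_stage("report", {
    drop_members <- function(d) d[, setdiff(names(d), "member_pos")]
    tables <- list(
      sample_sheet = sheet,
      dmc_obesity = dmcs$obesity, dmc_crc = dmcs$crc,
      dmr_obesity = drop_members(dmrs$obesity),
      dmr_crc = drop_members(dmrs$crc),
      overlap_dmc_quadrants = tidy(ov$dmc),
      overlap_dmr_quadrants = tidy(ov$dmr),
      overlap_summary = dplyr::bind_rows(
        dplyr::mutate(glance(ov$dmc), level = "dmc", .before = 1),
        dplyr::mutate(glance(ov$dmr), level = "dmr", .before = 1)))
    if (!is.null(ov$dmr$pairs) && nrow(ov$dmr$pairs) > 0) {
      tables$overlap_dmr_pairs <- ov$dmr$pairs
    }
    if (!is.null(profile$profile)) {
      tables$annotation_counts <- profile$profile$counts
      tables$annotation_tv <- profile$profile$tv
    }
    if (!is.null(selection$table)) {
      tables$dmr_selection <- selection$table
      tables$dmr_subject_means <- selection$means
    }
    if (!is.null(enr)) tables$enrichment <- enr
    if (!is.null(expr)) {
      tables$expression_logcpm <- expr$logcpm
      tables$expression_concordance <- expr$concordance
    }
    p <- write_report(tables, outdir)
    sj <- file.path(outdir, "summary.json")
    jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, na = "null")
    c(p, sj)
  })

  structure(list(config = config, sheet = sheet, calls = calls,
                 dmcs = dmcs, dmrs = dmrs, overlap = ov,
                 annotated = profile$annotated, profile = profile$profile,
                 selection = selection, enrichment = enr, expression = expr,
                 truth = inputs$truth, summary = summary, paths = paths),
            class = "methcrossover_run")
}

#' @export
print.methcrossover_run <- function(x, ...) {
  s <- x$summary
  cat("methcrossover pipeline run\n")
  cat(sprintf("  DMCs: obesity %d, crc %d, overlap %d (%.1f%% of obesity)\n",
              s$dmc$significant$obesity, s$dmc$significant$crc,
              s$dmc$venn$overlap, s$dmc$pct_of_obesity))
  cat(sprintf("  DMRs: obesity %d, crc %d, overlap %d (%.1f%% of obesity)\n",
              s$dmr$called$obesity, s$dmr$called$crc,
              s$dmr$venn$overlap, s$dmr$pct_of_obesity))
  cat(sprintf("  selected DMRs: %d (%d in promoter/gene body)\n",
              s$selection$selected, s$selection$selected_gene))
  invisible(x)
}

#' Glance at a pipeline run
#'
#' @param x A `methcrossover_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with the run's headline counts.
#' @method glance methcrossover_run
#' @export
glance.methcrossover_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_dmc_obesity = s$dmc$significant$obesity,
    n_dmc_crc = s$dmc$significant$crc,
    n_dmc_overlap = s$dmc$venn$overlap,
    dmc_concordant_fraction = s$dmc$concordant_fraction,
    dmc_chi2_p = s$dmc$chi2_p,
    n_dmr_obesity = s$dmr$called$obesity,
    n_dmr_crc = s$dmr$called$crc,
    n_dmr_overlap = s$dmr$venn$overlap,
    n_selected = s$selection$selected,
    n_selected_gene = s$selection$selected_gene)
}
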