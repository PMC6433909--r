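#' Build a simulation configuration
#'
#' Defines the study conditions the synthetic generator emulates: a
#' three-group whole-blood RRBS cohort (lean controls, obese subjects,
#' colorectal-cancer patients) with group sizes and age structure
#' matching the motivating cohort (15/10/15; ages 40+/-15, 36+/-10,
#' 53+/-9 years), clustered CpG coordinates as produced by
#' MspI-fragment enrichment, a bimodal background methylation landscape,
#' and beta-binomially overdispersed read counts.
#'
#' @param n_control,n_obese,n_crc Samples per group (each >= 3, the
#'   minimum the differential caller requires).
#' @param age_mean_sd Named list of `c(mean, sd)` ages (years) per group.
#' @param n_chrom Number of autosomes to simulate.
#' @param cpg_per_chrom Background CpGs per chromosome (excluding
#'   planted regions).
#' @param coverage_mean Mean read coverage; coverage is drawn
#'   negative-binomially with size `coverage_size`.
#' @param coverage_size Negative-binomial size (inverse dispersion) of
#'   coverage.
#' @param baseline_beta_dist Mixture specification for background
#'   methylation levels: a list of `list(weight, shape1, shape2)` Beta
#'   components. The default is the bimodal landscape typical of CpG
#'   methylomes (mostly near-0 and near-1 sites plus an intermediate
#'   component).
#' @param planted_regions Tibble of planted differentially methylated
#'   regions (see [make_planted_regions()]), or `NULL` for none.
#' @param dispersion Beta-binomial overdispersion phi in `[0, 1)`;
#'   `0` gives exact binomial sampling.
#' @param age_slope Linear age effect on logit methylation
#'   (per year); exercises the age covariate of the caller.
#' @param intra_gap Distance (bp) between consecutive CpGs inside a
#'   planted region.
#' @param planted_flank_gap Guaranteed empty flank (bp) on both sides of
#'   every planted region.
#' @param seed Master seed; each output draws from its own stream at a
#'   stable offset from this seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_control = 15, n_obese = 10, n_crc = 15,
                       age_mean_sd = list(control = c(40, 15),
                                          obesity = c(36, 10),
                                          crc = c(53, 9)),
                       n_chrom = 2, cpg_per_chrom = 2000,
                       coverage_mean = 30, coverage_size = 8,
                       baseline_beta_dist = list(
                         list(weight = 0.45, shape1 = 1, shape2 = 8),
                         list(weight = 0.45, shape1 = 8, shape2 = 1),
                         list(weight = 0.10, shape1 = 2, shape2 = 2)
                       ),
                       planted_regions = NULL,
                       dispersion = 0.05, age_slope = 0.002,
                       intra_gap = 50, planted_flank_gap = 8000,
                       seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control), n_obese = as.integer(n_obese),
    n_crc = as.integer(n_crc), age_mean_sd = age_mean_sd,
    n_chrom = as.integer(n_chrom), cpg_per_chrom = as.integer(cpg_per_chrom),
    coverage_mean = coverage_mean, coverage_size = coverage_size,
    baseline_beta_dist = baseline_beta_dist,
    planted_regions = planted_regions,
    dispersion = dispersion, age_slope = age_slope,
    intra_gap = as.integer(intra_gap),
    planted_flank_gap = as.integer(planted_flank_gap),
    seed = as.integer(seed)
  )
  if (min(cfg$n_control, cfg$n_obese, cfg$n_crc) < 3L) {
    rlang::abort(paste(
      "group sizes must each be >= 3: the differential caller requires a",
      "minimum of three individuals per group, so smaller groups would",
      "produce no testable sites"))
  }
  stopifnot(cfg$n_chrom >= 1L, cfg$cpg_per_chrom >= 1L,
            cfg$coverage_mean >= 1, cfg$dispersion >= 0, cfg$dispersion < 1)
  w <- vapply(cfg$baseline_beta_dist, `[[`, numeric(1), "weight")
  stopifnot(all(w > 0), abs(sum(w) - 1) < 1e-8)
  if (!is.null(planted_regions)) validate_planted_regions(planted_regions)
  structure(cfg, class = "sim_config")
}

#' Build a planted-region table
#'
#' Planted regions carry a signed methylation effect (delta beta) for
#' each case contrast and fall into five classes: effect only in the
#' obesity contrast, only in the CRC contrast, concordant (same sign in
#' both, hyper or hypo), or discordant (opposite signs).
#'
#' @param n_obesity_only,n_crc_only,n_concordant_hyper,n_concordant_hypo,n_discordant
#'   Number of regions of each class.
#' @param n_cpgs CpGs per region (>= 3).
#' @param effect Absolute delta beta applied (<= 0.6).
#' @return A tibble with columns `region_id`, `class`, `n_cpgs`,
#'   `effect_obese`, `effect_crc`.
#' @export
make_planted_regions <- function(n_obesity_only = 0, n_crc_only = 0,
                                 n_concordant_hyper = 0, n_concordant_hypo = 0,
                                 n_discordant = 0,
                                 n_cpgs = 5, effect = 0.3) {
  one <- function(class, n, eff_o, eff_c) {
    if (n == 0L) return(NULL)
    tibble::tibble(class = class, n_cpgs = as.integer(n_cpgs),
                   effect_obese = rep_len(eff_o, n),
                   effect_crc = rep_len(eff_c, n))
  }
  alt <- effect * rep_len(c(1, -1), max(n_obesity_only, n_crc_only, n_discordant, 1))
  regions <- dplyr::bind_rows(
    one("obesity_only", n_obesity_only, alt[seq_len(max(n_obesity_only, 0))], 0),
    one("crc_only", n_crc_only, 0, alt[seq_len(max(n_crc_only, 0))]),
    one("concordant_hyper", n_concordant_hyper, effect, effect),
    one("concordant_hypo", n_concordant_hypo, -effect, -effect),
    one("discordant", n_discordant,
        alt[seq_len(max(n_discordant, 0))], -alt[seq_len(max(n_discordant, 0))])
  )
  if (is.null(regions) || nrow(regions) == 0L) {
    return(tibble::tibble(region_id = character(), class = character(),
                          n_cpgs = integer(), effect_obese = numeric(),
                          effect_crc = numeric()))
  }
  regions <- dplyr::mutate(regions,
                           region_id = sprintf("planted_%03d", dplyr::row_number()),
                           .before = 1)
  validate_planted_regions(regions)
}

validate_planted_regions <- function(regions) {
  stopifnot(all(c("region_id", "class", "n_cpgs",
                  "effect_obese", "effect_crc") %in% names(regions)))
  stopifnot(all(regions$n_cpgs >= 3L),
            all(abs(regions$effect_obese) <= 0.6),
            all(abs(regions$effect_crc) <= 0.6))
  ok <- with(regions, dplyr::case_when(
    class == "obesity_only" ~ effect_obese != 0 & effect_crc == 0,
    class == "crc_only" ~ effect_obese == 0 & effect_crc != 0,
    class == "concordant_hyper" ~ effect_obese > 0 & effect_crc > 0,
    class == "concordant_hypo" ~ effect_obese < 0 & effect_crc < 0,
    class == "discordant" ~ effect_obese * effect_crc < 0,
    TRUE ~ FALSE
  ))
  if (!all(ok)) {
    rlang::abort(sprintf("planted region %s: class inconsistent with effect signs",
                         regions$region_id[which(!ok)[1L]]))
  }
  regions
}

# stream seeding: one RNG stream per output, at a stable offset from the
# master seed (kept well below 2^31)
with_stream <- function(seed, offset, code) {
  withr::with_seed(((as.integer(seed) %% 1000003L) * 1009L + offset) %% 2147483647L,
                   code)
}

draw_baseline_beta <- function(n, mixture) {
  w <- vapply(mixture, `[[`, numeric(1), "weight")
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  s1 <- vapply(mixture, `[[`, numeric(1), "shape1")[comp]
  s2 <- vapply(mixture, `[[`, numeric(1), "shape2")[comp]
  stats::rbeta(n, s1, s2)
}

# lay out one chromosome: clustered background CpGs (RRBS-like fragments)
# with planted regions inserted between clusters behind guaranteed flanks
layout_chrom <- function(chrom, n_bg, regions, intra_gap, flank_gap) {
  pos <- integer(0)
  site_region <- character(0)
  cursor <- 1000L
  n_regions <- if (is.null(regions)) 0L else nrow(regions)
  # background arrives in clusters of ~8 CpGs, ~30 bp apart, clusters
  # ~2-4 kb apart; planted regions are interleaved evenly
  placed <- 0L
  region_rows <- list()
  insert_after <- if (n_regions > 0L) {
    unique(pmax(1L, floor(seq_len(n_regions) * (n_bg / 8) / (n_regions + 1))))
  } else integer(0)
  cluster_i <- 0L
  while (placed < n_bg || length(region_rows) < n_regions) {
    cluster_i <- cluster_i + 1L
    if (placed < n_bg) {
      size <- min(n_bg - placed, 1L + stats::rpois(1, 7))
      gaps <- 15L + stats::rgeom(size - 1L, 1 / 20)
      p <- cursor + c(0L, cumsum(gaps))
      pos <- c(pos, p)
      site_region <- c(site_region, rep(NA_character_, size))
      placed <- placed + size
      cursor <- max(p) + 500L + as.integer(stats::rlnorm(1, log(2500), 0.4))
    }
    k <- length(region_rows) + 1L
    if (k <= n_regions && (cluster_i %in% insert_after || placed >= n_bg)) {
      cursor <- cursor + flank_gap
      r <- regions[k, ]
      p <- cursor + (seq_len(r$n_cpgs) - 1L) * intra_gap
      pos <- c(pos, p)
      site_region <- c(site_region, rep(r$region_id, r$n_cpgs))
      region_rows[[k]] <- tibble::tibble(
        region_id = r$region_id, chrom = chrom,
        start = min(p), end = max(p) + 1L
      )
      cursor <- max(p) + flank_gap
    }
  }
  ord <- order(pos)
  list(sites = tibble::tibble(chrom = chrom, pos = as.integer(pos[ord]),
                              region_id = site_region[ord]),
       regions = dplyr::bind_rows(region_rows))
}

#' Simulate a three-group RRBS methylation data set
#'
#' Generates per-sample CpG methylation calls over a shared set of
#' clustered coordinates, a sample sheet, and a truth table locating
#' every planted region. Coverage is negative-binomial; methylated
#' counts are beta-binomial around a site-level mean equal to the
#' background level plus the sample group's planted effect (clipped to
#' `[0.01, 0.99]`), with an optional linear age effect on the logit
#' scale.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `meth_simulation` with elements
#'   `calls` (long tibble: `sample_id`, `chrom`, `pos`, `strand`,
#'   `coverage`, `n_meth`), `sheet` (sample sheet), `truth` (planted
#'   regions with their realized coordinates), and `sites` (per-site
#'   baseline and region membership).
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- c(rep("control", config$n_control),
              rep("obesity", config$n_obese),
              rep("crc", config$n_crc))
  sheet <- with_stream(config$seed, 1L, {
    ids <- sprintf("%s_%02d", c("ctrl", "obese", "crc")[
      match(groups, c("control", "obesity", "crc"))],
      stats::ave(seq_along(groups), groups, FUN = seq_along))
    ages <- vapply(groups, function(g) {
      ms <- config$age_mean_sd[[g]]
      max(18, round(stats::rnorm(1, ms[1], ms[2])))
    }, numeric(1))
    tibble::tibble(sample_id = ids, group = groups, age = unname(ages),
                   sex = sample(c("F", "M"), length(groups), replace = TRUE))
  })

  regions <- config$planted_regions
  n_regions <- if (is.null(regions)) 0L else nrow(regions)
  layout <- with_stream(config$seed, 2L, {
    split_idx <- if (n_regions > 0L) {
      sort(rep_len(seq_len(config$n_chrom), n_regions))
    } else integer(0)
    lapply(seq_len(config$n_chrom), function(ci) {
      layout_chrom(sprintf("chr%d", ci), config$cpg_per_chrom,
                   if (n_regions > 0L) regions[split_idx == ci, , drop = FALSE] else NULL,
                   config$intra_gap, config$planted_flank_gap)
    })
  })
  sites <- dplyr::bind_rows(lapply(layout, `[[`, "sites"))
  truth_coords <- dplyr::bind_rows(lapply(layout, `[[`, "regions"))
  truth <- if (n_regions > 0L) {
    dplyr::inner_join(regions, truth_coords, by = "region_id")
  } else {
    tibble::tibble(region_id = character(), class = character(),
                   n_cpgs = integer(), effect_obese = numeric(),
                   effect_crc = numeric(), chrom = character(),
                   start = integer(), end = integer())
  }

  n_sites <- nrow(sites)
  eff <- tibble::tibble(region_id = sites$region_id) |>
    dplyr::left_join(
      if (n_regions > 0L) regions[, c("region_id", "effect_obese", "effect_crc")]
      else tibble::tibble(region_id = character(), effect_obese = numeric(),
                          effect_crc = numeric()),
      by = "region_id")
  sites$effect_obese <- dplyr::coalesce(eff$effect_obese, 0)
  sites$effect_crc <- dplyr::coalesce(eff$effect_crc, 0)
  sites$baseline <- with_stream(config$seed, 3L, {
    b <- draw_baseline_beta(n_sites, config$baseline_beta_dist)
    # planted sites draw their baseline inside the band that lets the
    # full effect be realized without hitting the [0.01, 0.99] clip
    planted <- !is.na(sites$region_id)
    if (any(planted)) {
      lo <- 0.05 + pmax(0, -pmin(sites$effect_obese, sites$effect_crc, 0))
      hi <- 0.95 - pmax(0, pmax(sites$effect_obese, sites$effect_crc, 0))
      b[planted] <- stats::runif(sum(planted), lo[planted], hi[planted])
    }
    b
  })

  n_samples <- nrow(sheet)
  age_center <- mean(sheet$age)
  calls <- with_stream(config$seed, 4L, {
    purrr::map_dfr(seq_len(n_samples), function(si) {
      g <- sheet$group[si]
      delta <- switch(g, control = 0,
                      obesity = sites$effect_obese, crc = sites$effect_crc)
      mu <- pmin(pmax(sites$baseline + delta, 0.01), 0.99)
      mu <- stats::plogis(stats::qlogis(mu) +
                            config$age_slope * (sheet$age[si] - age_center))
      cov <- pmax(1L, stats::rnbinom(n_sites, mu = config$coverage_mean,
                                     size = config$coverage_size))
      p <- if (config$dispersion > 0) {
        phi <- config$dispersion
        stats::rbeta(n_sites, mu * (1 - phi) / phi, (1 - mu) * (1 - phi) / phi)
      } else mu
      tibble::tibble(sample_id = sheet$sample_id[si], chrom = sites$chrom,
                     pos = sites$pos, strand = ".",
                     coverage = cov,
                     n_meth = stats::rbinom(n_sites, cov, p))
    })
  })
  calls <- dplyr::arrange(calls, .data$sample_id, .data$chrom, .data$pos)
  structure(list(calls = calls, sheet = sheet, truth = truth, sites = sites,
                 config = config),
            class = "meth_simulation")
}

#' Simulate a genome annotation matched to a methylation simulation
#'
#' Constructs non-overlapping gene models (TSS, exons, introns, both
#' strands) and CpG-island intervals over the simulated coordinate
#' space. Each planted region is deliberately framed by a dedicated gene
#' so that its gene-subregion context (promoter, exon, intron or
#' intergenic) is known in advance; the assigned context is returned in
#' the truth table for annotation tests. Islands are grown over CpG
#' clusters until they cover approximately `island_fraction` of sites.
#'
#' @param sim A `meth_simulation` from [simulate_methylation()].
#' @param n_background_genes Filler genes per chromosome, placed in
#'   space left free by the region-framing genes.
#' @param island_fraction Target fraction of CpGs inside islands, in
#'   `[0, 1]`.
#' @param seed RNG seed (defaults to the simulation's master seed).
#' @return A list with `annotation` (class `genome_annotation`) and
#'   `truth` (the simulation truth table with an `expected_subregion`
#'   column).
#' @export
simulate_annotation <- function(sim, n_background_genes = 10,
                                island_fraction = 0.4, seed = NULL) {
  stopifnot(inherits(sim, "meth_simulation"))
  if (is.null(seed)) seed <- sim$config$seed
  truth <- sim$truth
  targets <- if (nrow(truth) > 0L) {
    rep_len(c("promoter", "exon", "intron", "intergenic"), nrow(truth))
  } else character(0)

  gene_rows <- list()
  gi <- 0L
  add_gene <- function(chrom, strand, tss, ex_s, ex_e) {
    gi <<- gi + 1L
    gene_rows[[gi]] <<- tibble::tibble(
      gene_id = sprintf("gene_%03d", gi), chrom = chrom, strand = strand,
      tss = as.integer(tss), exon_starts = list(as.integer(ex_s)),
      exon_ends = list(as.integer(ex_e)))
  }
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      r <- truth[i, ]
      tgt <- targets[i]
      if (tgt == "promoter") {
        # region sits in [tss-2000, tss) of a + strand gene just downstream
        tss <- r$end + 500L
        add_gene(r$chrom, "+", tss, c(tss, tss + 1500L), c(tss + 800L, tss + 2500L))
      } else if (tgt == "exon") {
        s <- r$start - 300L
        add_gene(r$chrom, "+", s, c(s, r$end + 600L), c(r$end + 200L, r$end + 1200L))
      } else if (tgt == "intron") {
        s <- r$start - 1200L
        e <- r$end + 1200L
        add_gene(r$chrom, "+", s, c(s, e - 400L), c(r$start - 400L, e))
      } # intergenic: no gene within the planted flank
    }
  }
  # filler genes on a regular pitch, kept clear of the framing genes and
  # of intergenic-target regions
  reserved <- dplyr::bind_rows(
    tibble::tibble(chrom = character(), start = integer(), end = integer()),
    if (gi > 0L) purrr::map_dfr(gene_rows, function(g) tibble::tibble(
      chrom = g$chrom, start = min(g$exon_starts[[1]], g$tss) - 2500L,
      end = max(g$exon_ends[[1]], g$tss) + 500L)),
    if (nrow(truth) > 0L) tibble::tibble(
      chrom = truth$chrom[targets == "intergenic"],
      start = truth$start[targets == "intergenic"] - 3000L,
      end = truth$end[targets == "intergenic"] + 3000L)
  )
  chrom_ends <- sim$sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos) + 1000L, .groups = "drop")
  withr::with_seed(seed + 7L, {
    for (ci in seq_len(nrow(chrom_ends))) {
      chrom <- chrom_ends$chrom[ci]
      pitch <- max(4000L, chrom_ends$len[ci] %/% max(1L, n_background_genes))
      starts <- seq(500L, max(501L, chrom_ends$len[ci] - 3000L), by = pitch)
      for (s in starts) {
        e <- s + 2500L
        res <- reserved[reserved$chrom == chrom, , drop = FALSE]
        if (nrow(res) > 0L && any(res$start < e & s < res$end)) next
        strand <- sample(c("+", "-"), 1L)
        tss <- if (strand == "+") s else e
        add_gene(chrom, strand, tss, c(s, s + 1500L), c(s + 1000L, e))
        reserved <- dplyr::bind_rows(reserved, tibble::tibble(
          chrom = chrom, start = s - 2500L, end = e + 500L))
      }
    }
  })
  genes <- validate_gene_models(dplyr::bind_rows(gene_rows))

  # islands: grow over CpG clusters (runs of sites < 500 bp apart) until
  # the requested fraction of CpGs is covered
  islands <- withr::with_seed(seed + 11L, {
    runs <- sim$sites |>
      dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$pos, .by_group = TRUE) |>
      dplyr::mutate(run = cumsum(c(1L, diff(.data$pos) >= 500L))) |>
      dplyr::group_by(.data$chrom, .data$run) |>
      dplyr::summarise(start = min(.data$pos) - 50L, end = max(.data$pos) + 51L,
                       n = dplyr::n(), .groups = "drop")
    if (island_fraction <= 0 || nrow(runs) == 0L) {
      runs[0, c("chrom", "start", "end")]
    } else {
      runs <- runs[sample.int(nrow(runs)), ]
      keep <- cumsum(runs$n) <= island_fraction * nrow(sim$sites)
      merge_intervals(runs[keep, c("chrom", "start", "end")])
    }
  })
  truth$expected_subregion <- targets
  list(annotation = structure(list(genes = genes, islands = islands),
                              class = "genome_annotation"),
       truth = truth)
}

#' Simulate a two-condition RNA-seq count matrix
#'
#' Negative-binomial gene-level counts for a two-condition,
#' two-replicate design (emulating wild-type vs DNMT1/DNMT3B
#' double-knockout colorectal carcinoma cell lines), with per-gene
#' log2 fold-changes applied to the second condition and library sizes
#' spread +/-20 percent.
#'
#' @param n_genes Number of genes (>= 1).
#' @param conditions Number of conditions (the design supports 2).
#' @param replicates Replicates per condition.
#' @param effect_table Tibble `gene_id`, `lfc` of planted log2
#'   fold-changes (condition 2 vs condition 1); missing genes get 0.
#' @param base_mean Median baseline expression (counts).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param lib_spread Half-width of the uniform library-size factor
#'   spread (0.2 = +/-20 percent).
#' @param condition_names Length-2 character vector of condition labels.
#' @param seed RNG seed.
#' @return A list with `counts` (tibble `gene_id` + one column per
#'   sample), `samples` (tibble `sample_id`, `condition`) and `truth`
#'   (per-gene lfc).
#' @export
simulate_expression <- function(n_genes, conditions = 2, replicates = 2,
                                effect_table = NULL, base_mean = 100,
                                nb_dispersion = 0.05, lib_spread = 0.2,
                                condition_names = c("WT", "DKO"),
                                seed = 1L) {
  stopifnot(n_genes >= 1, conditions == 2, replicates >= 1)
  withr::with_seed(as.integer(seed), {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    lfc <- rep(0, n_genes)
    if (!is.null(effect_table)) {
      idx <- match(effect_table$gene_id, gene_id)
      stopifnot(!anyNA(idx))
      lfc[idx] <- effect_table$lfc
    }
    mu0 <- stats::rlnorm(n_genes, log(base_mean), 1)
    samples <- tibble::tibble(
      sample_id = paste0(rep(condition_names, each = replicates), "_rep",
                         rep(seq_len(replicates), conditions)),
      condition = rep(condition_names, each = replicates))
    libf <- stats::runif(nrow(samples), 1 - lib_spread, 1 + lib_spread)
    counts <- tibble::tibble(gene_id = gene_id)
    for (si in seq_len(nrow(samples))) {
      mu <- mu0 * 2^(lfc * (samples$condition[si] == condition_names[2])) * libf[si]
      counts[[samples$sample_id[si]]] <-
        stats::rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion)
    }
    list(counts = counts, samples = samples,
         truth = tibble::tibble(gene_id = gene_id, lfc = lfc))
  })
}

#' Write a methylation simulation to disk in standard formats
#'
#' Emits one Bismark-style coverage file per sample, a sample-sheet CSV,
#' and a truth-table TSV.
#'
#' @param sim A `meth_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov_paths <- vapply(unique(sim$calls$sample_id), function(s) {
    p <- file.path(dir, paste0(s, ".cov"))
    write_coverage_file(dplyr::filter(sim$calls, .data$sample_id == s), p)
    p
  }, character(1))
  sheet_path <- file.path(dir, "samples.csv")
  write_sample_sheet(sim$sheet, sheet_path)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_path, progress = FALSE)
  invisible(list(coverage = cov_paths, sheet = sheet_path, truth = truth_path))
}
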