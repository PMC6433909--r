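small_cfg <- function(...) {
  sim_config(n_control = 4, n_obese = 3, n_crc = 3, n_chrom = 1,
             cpg_per_chrom = 200, seed = 7, ...)
}

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_methylation(small_cfg())
  s2 <- simulate_methylation(small_cfg())
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$sheet, s2$sheet)
  expect_identical(s1$truth, s2$truth)
})

test_that("methylated counts never exceed coverage and coverage is positive", {
  cfg <- sim_config(n_control = 3, n_obese = 3, n_crc = 3, n_chrom = 2,
                    cpg_per_chrom = 300, dispersion = 0.1,
                    planted_regions = make_planted_regions(
                      n_concordant_hyper = 3, n_concordant_hypo = 3,
                      n_discordant = 2, effect = 0.4),
                    seed = 9)
  sim <- simulate_methylation(cfg)
  expect_true(all(sim$calls$n_meth <= sim$calls$coverage))
  expect_true(all(sim$calls$coverage >= 1))
  expect_true(all(sim$calls$n_meth >= 0))
})

test_that("planted-region classes partition the truth table at the requested counts", {
  pr <- make_planted_regions(n_obesity_only = 4, n_crc_only = 3,
                             n_concordant_hyper = 5, n_concordant_hypo = 2,
                             n_discordant = 3)
  sim <- simulate_methylation(small_cfg(planted_regions = pr))
  expect_equal(sort(table(sim$truth$class)),
               sort(table(c(rep("obesity_only", 4), rep("crc_only", 3),
                            rep("concordant_hyper", 5),
                            rep("concordant_hypo", 2),
                            rep("discordant", 3)))))
  expect_equal(anyDuplicated(sim$truth$region_id), 0L)
  # realized coordinates cover exactly n_cpgs sites each
  site_counts <- table(stats::na.omit(sim$sites$region_id))
  expect_true(all(site_counts == 5L))
})

test_that("with no effects and no overdispersion the pooled methylated fraction is unbiased", {
  cfg <- sim_config(n_control = 5, n_obese = 5, n_crc = 5, n_chrom = 1,
                    cpg_per_chrom = 400, coverage_mean = 200,
                    dispersion = 0, age_slope = 0,
                    baseline_beta_dist = list(
                      list(weight = 1, shape1 = 5e5, shape2 = 5e5)),
                    seed = 21)
  sim <- simulate_methylation(cfg)
  expect_lt(abs(sum(sim$calls$n_meth) / sum(sim$calls$coverage) - 0.5), 0.005)
})

test_that("class/sign inconsistencies and tiny groups are rejected", {
  bad <- tibble::tibble(region_id = "r1", class = "concordant_hyper",
                        n_cpgs = 3L, effect_obese = 0.3, effect_crc = -0.3)
  expect_error(validate_planted_regions(bad), "inconsistent")
  expect_error(sim_config(n_control = 2, n_obese = 5, n_crc = 5),
               "three individuals")
})

test_that("simulated annotation frames each planted region in its stated subregion", {
  pr <- make_planted_regions(n_concordant_hyper = 4, n_concordant_hypo = 4,
                             n_obesity_only = 4, effect = 0.3)
  sim <- simulate_methylation(sim_config(n_control = 3, n_obese = 3, n_crc = 3,
                                         n_chrom = 2, cpg_per_chrom = 400,
                                         planted_regions = pr, seed = 13))
  ann <- simulate_annotation(sim, n_background_genes = 8, island_fraction = 0.4)
  got <- annotate_features(
    ann$truth[, c("region_id", "chrom", "start", "end")], ann$annotation)
  expect_equal(got$subregion, ann$truth$expected_subregion)

  # gene models are pairwise disjoint per chromosome, each with >= 1 exon
  g <- ann$annotation$genes
  expect_true(all(lengths(g$exon_starts) >= 1L))
  by_chrom <- split(g, g$chrom)
  for (gc in by_chrom) {
    gc <- gc[order(gc$gene_start), ]
    if (nrow(gc) > 1L) {
      expect_true(all(gc$gene_start[-1] >= gc$gene_end[-nrow(gc)]))
    }
  }
})

test_that("island fraction zero yields no islands and reproducible BED output", {
  sim <- simulate_methylation(small_cfg())
  ann0 <- simulate_annotation(sim, island_fraction = 0)
  expect_equal(nrow(ann0$annotation$islands), 0L)
  cpgs <- dplyr::distinct(sim$calls, chrom, pos)
  got <- annotate_features(cpgs, ann0$annotation)
  expect_true(all(got$island_context == "open_sea"))

  ann1 <- simulate_annotation(sim, island_fraction = 0.3)
  ann2 <- simulate_annotation(sim, island_fraction = 0.3)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(ann1$annotation$islands, f1)
  write_bed(ann2$annotation$islands, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("null simulation p-values from the DMC caller are approximately uniform", {
  cfg <- sim_config(n_control = 10, n_obese = 10, n_crc = 3, n_chrom = 1,
                    cpg_per_chrom = 3000, coverage_mean = 30,
                    dispersion = 0, seed = 31)
  sim <- simulate_methylation(cfg)
  dmcs <- call_dmcs(sim$calls, sim$sheet, "obesity")
  ks <- suppressWarnings(
    stats::ks.test(dmcs$p, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("expression simulation honours fold-changes, libraries and the seed", {
  # null: no effects, no library spread -> condition log-CPM difference ~ 0
  e0 <- simulate_expression(300, effect_table = NULL, lib_spread = 0,
                            seed = 5)
  lc <- log_cpm(e0$counts)
  m <- as.matrix(lc[-1])
  d <- rowMeans(m[, e0$samples$condition == "DKO"]) -
    rowMeans(m[, e0$samples$condition == "WT"])
  expect_lt(abs(mean(d)), 0.05)

  # lfc +2 -> DKO/WT mean count ratio ~ 4 over many genes
  et <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000), lfc = 2)
  e1 <- simulate_expression(1000, effect_table = et, base_mean = 1000,
                            lib_spread = 0, seed = 6)
  cm <- as.matrix(e1$counts[-1])
  ratio <- sum(cm[, e1$samples$condition == "DKO"]) /
    sum(cm[, e1$samples$condition == "WT"])
  expect_lt(abs(ratio - 4), 0.15)

  expect_identical(simulate_expression(50, seed = 3),
                   simulate_expression(50, seed = 3))
})

test_that("simulation outputs round-trip through the standard writers", {
  sim <- simulate_methylation(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  s1 <- sim$sheet$sample_id[1]
  back <- read_coverage_file(file.path(dir, paste0(s1, ".cov")), s1)
  orig <- dplyr::arrange(
    dplyr::filter(sim$calls, sample_id == s1), chrom, pos)
  expect_equal(back, orig)
  expect_equal(read_sample_sheet(paths$sheet), sim$sheet)
})
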