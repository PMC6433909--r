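test_that("identical groups give zero difference and p of one", {
  site <- tibble::tibble(coverage = rep(20L, 6), n_meth = rep(c(4L, 9L, 14L), 2),
                         case = rep(c(FALSE, TRUE), each = 3), age = 40)
  r <- test_site(site)
  expect_equal(r$meth_diff, 0)
  expect_gt(r$p, 0.999)
})

test_that("a fully separated site matches the closed-form binomial LRT oracle", {
  # case all 20/20, control all 0/20 (5 vs 5). MLEs are at the boundary:
  # full-model log-likelihood 0, null model p-hat = 0.5 over 200 trials,
  # so the deviance is -2 * 200 * log(0.5)
  site <- tibble::tibble(coverage = rep(20L, 10),
                         n_meth = rep(c(0L, 20L), each = 5),
                         case = rep(c(FALSE, TRUE), each = 5), age = 40)
  r <- test_site(site)
  expect_equal(r$meth_diff, 100)
  expect_lt(r$p, 1e-6)
  stat_oracle <- -2 * 200 * log(0.5)
  p_oracle <- stats::pchisq(stat_oracle, df = 1, lower.tail = FALSE)
  expect_equal(log(r$p), log(p_oracle), tolerance = 1e-3)
})

test_that("the per-site fit agrees with the formula-interface GLM oracle", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- 12
      site <- tibble::tibble(
        coverage = sample(10:50, n, replace = TRUE),
        case = rep(c(FALSE, TRUE), each = n / 2),
        age = sample(25:70, n, replace = TRUE))
      site$n_meth <- rbinom(n, site$coverage, ifelse(site$case, 0.55, 0.45))
      r <- test_site(site)
      full <- stats::glm(cbind(n_meth, coverage - n_meth) ~ case + age,
                         binomial, data = site)
      null <- stats::glm(cbind(n_meth, coverage - n_meth) ~ age,
                         binomial, data = site)
      p_oracle <- stats::anova(null, full, test = "Chisq")$`Pr(>Chi)`[2]
      expect_equal(r$p, p_oracle, tolerance = 1e-10)
    }
  })
})

test_that("swapping case and control labels negates the difference and keeps p", {
  withr::with_seed(23, {
    for (i in 1:8) {
      n <- 10
      site <- tibble::tibble(
        coverage = sample(5:40, n, replace = TRUE),
        case = rep(c(FALSE, TRUE), each = 5),
        age = sample(20:70, n, replace = TRUE))
      site$n_meth <- rbinom(n, site$coverage, runif(1, 0.2, 0.8))
      r1 <- test_site(site)
      r2 <- test_site(dplyr::mutate(site, case = !case))
      expect_equal(r2$meth_diff, -r1$meth_diff)
      expect_equal(r2$p, r1$p, tolerance = 1e-12)
    }
  })
})

test_that("shifting all ages by a constant leaves every p-value unchanged", {
  sim <- sim_two_group_calls(runif(30, 0.2, 0.8), runif(30, 0.2, 0.8),
                             ages = c(sample(25:45, 5), sample(50:70, 5)),
                             seed = 5)
  d1 <- call_dmcs(sim$calls, sim$sheet, "obesity")
  d2 <- call_dmcs(sim$calls, dplyr::mutate(sim$sheet, age = age + 100),
                  "obesity")
  expect_equal(d2$p, d1$p, tolerance = 1e-8)
  expect_equal(d2$meth_diff, d1$meth_diff)
})

test_that("the age covariate protects against age-confounded false positives", {
  # methylation rises with age; case group is much older, so without the
  # covariate the group term soaks up the age effect
  withr::with_seed(41, {
    n_sites <- 300
    ages <- c(sample(25:40, 8, replace = TRUE), sample(60:75, 8, replace = TRUE))
    ids <- sprintf("s%02d", 1:16)
    groups <- rep(c("control", "obesity"), each = 8)
    sheet <- tibble::tibble(sample_id = ids, group = groups, age = ages,
                            sex = "F")
    base <- runif(n_sites, 0.3, 0.7)
    calls <- purrr::map_dfr(1:16, function(si) {
      mu <- stats::plogis(stats::qlogis(base) + 0.02 * (ages[si] - 50))
      tibble::tibble(sample_id = ids[si], chrom = "chr1",
                     pos = seq_len(n_sites) * 100L, strand = ".",
                     coverage = 30L, n_meth = rbinom(n_sites, 30L, mu))
    })
  })
  with_cov <- call_dmcs(calls, sheet, "obesity", covariate = "age")
  without <- call_dmcs(calls, sheet, "obesity", covariate = NULL)
  expect_lt(mean(with_cov$p < 0.05), mean(without$p < 0.05))
})

test_that("significance requires both the effect and the q-value threshold", {
  withr::with_seed(57, {
    # site 1: huge true effect; site 2: real but sub-threshold 5 pp
    # effect at very deep coverage (tiny q, diff < 10); site 3: null
    sim <- sim_two_group_calls(
      beta_control = c(0.20, 0.50, 0.50),
      beta_case = c(0.80, 0.55, 0.50),
      n_control = 8, n_case = 8, coverage = 4000, seed = 3)
  })
  d <- call_dmcs(sim$calls, sim$sheet, "obesity")
  d <- d[order(d$pos), ]
  expect_true(d$significant[1])
  expect_equal(d$direction[1], "hyper")
  expect_lt(d$q[2], 0.05)           # clearly detected...
  expect_lt(abs(d$meth_diff[2]), 10)
  expect_false(d$significant[2])    # ...but fails the 10 pp effect rule
  expect_false(d$significant[3])
})

test_that("sites below the per-group sample minimum are not tested", {
  sim <- sim_two_group_calls(rep(0.5, 5), rep(0.5, 5), n_control = 5,
                             n_case = 5, seed = 9)
  # remove site 3 from all but two case samples
  calls <- dplyr::filter(
    sim$calls,
    !(pos == 3000L & sample_id %in% sprintf("obese_%02d", 1:3)))
  d <- call_dmcs(calls, sim$sheet, "obesity")
  expect_false(3000L %in% d$pos)
  expect_equal(nrow(d), 4L)
})

test_that("planted differential sites are recovered with controlled FDR", {
  withr::with_seed(71, {
    n_null <- 5000
    n_true <- 100
    base <- runif(n_null + n_true, 0.25, 0.55)
    beta_case <- base
    beta_case[seq_len(n_true)] <- base[seq_len(n_true)] + 0.4
    sim <- sim_two_group_calls(base, beta_case, n_control = 10, n_case = 10,
                               coverage = 30, seed = 72)
  })
  d <- call_dmcs(sim$calls, sim$sheet, "obesity")
  truth_pos <- seq_len(100) * 1000L
  called <- d$pos[d$significant]
  recall <- mean(truth_pos %in% called)
  fdr <- if (length(called) > 0) mean(!(called %in% truth_pos)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.10)
})
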