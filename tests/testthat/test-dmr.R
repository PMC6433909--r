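test_that("the distance cutoff lands between two well-separated gap modes", {
  withr::with_seed(19, {
    gaps <- round(10^c(rnorm(600, 1, 0.1), rnorm(600, 3, 0.1)))
    gaps <- pmax(2, sample(gaps))
    sites <- tibble::tibble(chrom = "chr1", pos = cumsum(gaps))
  })
  cutoff <- distance_cutoff(sites)
  expect_gte(cutoff, 10^1.8)
  expect_lte(cutoff, 10^2.2)

  # invariant to chromosome/row order permutation
  withr::with_seed(20, {
    shuffled <- sites[sample.int(nrow(sites)), ]
  })
  expect_equal(distance_cutoff(shuffled), cutoff)
})

test_that("degenerate gap distributions fall back to 100 bp", {
  withr::with_seed(4, {
    sites <- tibble::tibble(chrom = "chr1",
                            pos = cumsum(pmax(2, round(10^rnorm(500, 2, 0.05)))))
  })
  expect_equal(distance_cutoff(sites), 100)
  few <- tibble::tibble(chrom = "chr1", pos = (1:50) * 100L)
  expect_warning(co <- distance_cutoff(few), "fewer than")
  expect_equal(co, 100)
})

fake_dmcs <- function(pos, meth_diff, p, significant, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = ".",
                 meth_diff = meth_diff, p = p,
                 q = p, direction = ifelse(meth_diff > 0, "hyper", "hypo"),
                 n_case = 5L, n_control = 5L, flagged = FALSE,
                 significant = significant)
}

test_that("a run of close concordant CpGs with a DMC forms one hyper region", {
  d <- fake_dmcs(pos = c(100, 150, 200), meth_diff = c(20, 20, 20),
                 p = c(1e-6, 0.02, 0.03), significant = c(TRUE, FALSE, FALSE))
  r <- call_dmrs(d, cutoff = 100)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 100L)
  expect_equal(r$end, 201L)
  expect_equal(r$n_cpgs, 3L)
  expect_equal(r$n_dmcs, 1L)
  expect_equal(r$mean_meth_diff, 20)
  expect_equal(r$direction, "hyper")
})

test_that("regions failing any printed filter are rejected", {
  # two CpGs only
  d2 <- fake_dmcs(c(100, 150), c(30, 30), c(1e-8, 1e-8), c(TRUE, TRUE))
  expect_equal(nrow(call_dmrs(d2, 100)), 0L)
  # three CpGs but mean difference 4.9 pp
  d3 <- fake_dmcs(c(100, 150, 200), c(4.9, 4.9, 4.9), c(1e-8, 1e-8, 1e-8),
                  c(TRUE, TRUE, TRUE))
  expect_equal(nrow(call_dmrs(d3, 100)), 0L)
  # three CpGs, big difference, but no significant DMC
  d4 <- fake_dmcs(c(100, 150, 200), c(30, 30, 30), c(0.2, 0.2, 0.2),
                  c(FALSE, FALSE, FALSE))
  expect_equal(nrow(call_dmrs(d4, 100)), 0L)
})

test_that("gap merging agrees with a brute-force transitive-closure oracle", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      n <- sample(5:50, 1)
      pos <- sort(sample.int(5000, n))
      cutoff <- sample(c(50, 100, 300), 1)
      d <- fake_dmcs(pos, rep(20, n), rep(1e-4, n), rep(TRUE, n))
      got <- call_dmrs(d, cutoff, dmr_filters(min_cpgs = 1, min_dmcs = 0,
                                              min_mean_diff = -1))
      # oracle: O(n^2) same-region relation, sites i and j share a region
      # iff every consecutive gap on the path between them is <= cutoff
      member <- integer(n)
      member[1] <- 1L
      for (i in 2:n) {
        member[i] <- if (pos[i] - pos[i - 1] <= cutoff) member[i - 1]
          else member[i - 1] + 1L
      }
      oracle_regions <- split(pos, member)
      got_regions <- got$member_pos[order(got$start)]
      expect_equal(length(got_regions), length(oracle_regions))
      expect_true(all(purrr::map2_lgl(got_regions, unname(oracle_regions),
                                      ~identical(as.integer(.x),
                                                 as.integer(.y)))))
    }
  })
})

test_that("output regions are disjoint and every member CpG belongs to one region", {
  withr::with_seed(44, {
    pos <- sort(sample.int(50000, 400))
    d <- fake_dmcs(pos, rnorm(400, 0, 20), runif(400),
                   runif(400) < 0.2)
  })
  r <- call_dmrs(d, 200)
  if (nrow(r) > 1L) {
    r <- r[order(r$chrom, r$start), ]
    expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }
  members <- unlist(r$member_pos)
  expect_equal(anyDuplicated(members), 0L)
  expect_true(all(purrr::map2_lgl(
    r$member_pos, seq_len(nrow(r)),
    ~all(.x >= r$start[.y] & .x < r$end[.y]))))
})

test_that("signed Stouffer combination penalizes direction-inconsistent regions", {
  p <- c(1e-4, 1e-4, 1e-4)
  consistent <- fake_dmcs(c(100, 150, 200), c(20, 20, 20), p, rep(TRUE, 3))
  mixed <- fake_dmcs(c(100, 150, 200), c(20, -20, 20), p, rep(TRUE, 3))
  r1 <- call_dmrs(consistent, 100)
  r2 <- call_dmrs(mixed, 100, dmr_filters(min_mean_diff = 1))
  expect_lt(r1$region_p, r2$region_p)
})

test_that("planted regions are recovered with tight boundaries", {
  pr <- make_planted_regions(n_concordant_hyper = 15, n_concordant_hypo = 15,
                             n_cpgs = 5, effect = 0.3)
  cfg <- sim_config(n_control = 10, n_obese = 10, n_crc = 3, n_chrom = 1,
                    cpg_per_chrom = 300, coverage_mean = 30, dispersion = 0,
                    planted_regions = pr, intra_gap = 50,
                    planted_flank_gap = 10000, seed = 55)
  sim <- simulate_methylation(cfg)
  d <- call_dmcs(sim$calls, sim$sheet, "obesity")
  cutoff <- distance_cutoff(d)
  dmrs <- call_dmrs(d, cutoff)
  truth <- sim$truth
  hits <- purrr::map_lgl(seq_len(nrow(truth)), function(i) {
    ov <- dmrs[dmrs$chrom == truth$chrom[i] &
                 dmrs$start < truth$end[i] & truth$start[i] < dmrs$end, ]
    if (nrow(ov) == 0L) return(FALSE)
    # boundary error at most one CpG (50 bp spacing) at each end
    any(abs(ov$start - truth$start[i]) <= 50 &
          abs(ov$end - truth$end[i]) <= 50)
  })
  expect_gte(mean(hits), 0.9)
})
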