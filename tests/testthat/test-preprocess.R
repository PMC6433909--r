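test_that("coverage and chromosome filters drop the sites the policy names", {
  calls <- make_calls("s1", c("chr1", "chr1", "chrX", "chrM"),
                      c(10, 20, 30, 40), c(4, 5, 50, 50), c(1, 2, 10, 10))
  out <- filter_calls(calls)
  expect_equal(out$pos, 20L)  # coverage 4 and sex/mito sites removed
})

test_that("the 99.9th-percentile coverage filter removes a single extreme outlier", {
  n <- 10000
  cov <- c(rep(10L, n - 1L), 500L)  # outlier above the 99.9th percentile
  calls <- make_calls("s1", "chr1", seq_len(n), cov, 0L)
  # oracle: direct quantile computation on the fixture
  thr <- stats::quantile(cov, 0.999, type = 7)
  expect_true(500 > thr)
  out <- filter_calls(calls)
  expect_equal(nrow(out), n - 1L)
  expect_true(all(out$coverage == 10L))
})

test_that("filtering is idempotent", {
  withr::with_seed(11, {
    cov <- pmax(1L, stats::rnbinom(2000, mu = 30, size = 3))
    calls <- make_calls(rep(c("s1", "s2"), each = 1000),
                        "chr1", rep(seq_len(1000), 2), cov,
                        vapply(cov, function(k) sample(0:k, 1), integer(1)))
  })
  once <- filter_calls(calls)
  twice <- filter_calls(once)
  expect_equal(twice, once)
})

test_that("coverage normalization scales toward the grand median and preserves beta", {
  # sample A median 10, B median 20 -> grand median 15, B scaled by 0.75
  a <- make_calls("A", "chr1", c(1, 2, 3), c(10, 10, 12), c(5, 2, 6))
  b <- make_calls("B", "chr1", c(1, 2, 3), c(20, 20, 24), c(10, 4, 12))
  out <- normalize_coverage(dplyr::bind_rows(a, b))
  expect_equal(out$coverage[out$sample_id == "A"], c(15L, 15L, 18L))
  expect_equal(out$coverage[out$sample_id == "B"], c(15L, 15L, 18L))

  # identical samples are unchanged
  out2 <- normalize_coverage(dplyr::bind_rows(
    a, dplyr::mutate(a, sample_id = "A2")))
  expect_equal(out2$coverage, rep(c(10L, 10L, 12L), 2))
  expect_equal(out2$n_meth, rep(c(5L, 2L, 6L), 2))

  # beta preserved within rounding
  before <- dplyr::bind_rows(a, b)
  expect_true(all(abs(out$n_meth / out$coverage -
                        before$n_meth / before$coverage) <=
                    1 / out$coverage + 1e-12))
})

test_that("histogram transform is near-identity when case already matches control", {
  withr::with_seed(3, {
    beta <- stats::rbeta(2000, 2, 2)
    cov <- rep(100L, 2000)
    ctrl <- make_calls("c1", "chr1", seq_len(2000), cov, round(beta * 100))
    case <- dplyr::mutate(ctrl, sample_id = "k1")
  })
  out <- histogram_transform(case, ctrl)
  step <- 1 / 2000
  expect_true(max(abs(out$n_meth / out$coverage -
                        case$n_meth / case$coverage)) <= step + 1 / 100)
})

test_that("histogram transform moves a shifted case distribution toward control", {
  ks_of <- function(cov) {
    withr::with_seed(5, {
      n <- 5000
      beta_ctrl <- stats::rbeta(n, 2, 2)
      beta_case <- pmin(0.999, stats::rbeta(n, 2, 2) + 0.1)
      ctrl <- make_calls("c1", "chr1", seq_len(n), cov, round(beta_ctrl * cov))
      case <- make_calls("k1", "chr1", seq_len(n), cov, round(beta_case * cov))
    })
    out <- histogram_transform(case, ctrl)
    list(case = case, ctrl = ctrl, out = out)
  }
  d <- ks_of(50L)
  suppressWarnings({
    ks_pre <- stats::ks.test(d$case$n_meth / d$case$coverage,
                             d$ctrl$n_meth / d$ctrl$coverage)$statistic
    ks_post <- stats::ks.test(d$out$n_meth / d$out$coverage,
                              d$ctrl$n_meth / d$ctrl$coverage)$statistic
  })
  expect_lt(ks_post, ks_pre)

  # pooled 20-bin histograms agree to total variation <= 0.05; coverage
  # 100 keeps the count lattice fine relative to the bin width (coarser
  # grids alias beta atoms against bin edges)
  d <- ks_of(100L)
  bins <- seq(0, 1, length.out = 21)
  h_case <- table(cut(d$out$n_meth / d$out$coverage, bins, include.lowest = TRUE))
  h_ctrl <- table(cut(d$ctrl$n_meth / d$ctrl$coverage, bins, include.lowest = TRUE))
  expect_lte(tv_distance(as.numeric(h_case), as.numeric(h_ctrl)), 0.05)
})

test_that("histogram transform is monotone and preserves within-sample rank order", {
  withr::with_seed(8, {
    n <- 400
    cov <- sample(10:60, n, replace = TRUE)
    case <- make_calls("k1", "chr1", seq_len(n), cov,
                       vapply(cov, function(k) sample(0:k, 1), integer(1)))
    ctrl_cov <- sample(10:60, n, replace = TRUE)
    ctrl <- make_calls("c1", "chr1", seq_len(n), ctrl_cov,
                       vapply(ctrl_cov, function(k) sample(0:k, 1), integer(1)))
  })
  out <- histogram_transform(case, ctrl)
  b_old <- case$n_meth / case$coverage
  # recover the mapped beta before count rounding by re-deriving it
  q <- (rank(b_old, ties.method = "average") - 0.5) / length(b_old)
  b_new <- stats::quantile(sort(ctrl$n_meth / ctrl$coverage), probs = q,
                           type = 7, names = FALSE)
  # monotone non-decreasing: no rank inversions, ties map to ties
  ord <- order(b_old)
  expect_true(all(diff(b_new[ord]) >= -1e-12))
  ties <- outer(b_old, b_old, "==")
  expect_true(all(abs(outer(b_new, b_new, "-")[ties]) < 1e-12))
})

test_that("a degenerate control distribution is rejected", {
  ctrl <- make_calls("c1", "chr1", 1:5, 10L, 5L)
  case <- make_calls("k1", "chr1", 1:5, 10L, 7L)
  expect_error(histogram_transform(case, ctrl), "degenerate")
})
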