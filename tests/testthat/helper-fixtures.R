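# small programmatic fixtures shared across test files

# single-sample call table from parallel vectors
make_calls <- function(sample_id, chrom, pos, coverage, n_meth, strand = ".") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 strand = strand, coverage = as.integer(coverage),
                 n_meth = as.integer(n_meth))
}

# direct two-group binomial call generator for caller tests: site i has
# true level beta_control[i] in controls and beta_case[i] in the case
# group ("obesity"); ages optional per sample. Positions are spaced
# 1 kb apart on one chromosome.
sim_two_group_calls <- function(beta_control, beta_case,
                                n_control = 5, n_case = 5,
                                coverage = 30, ages = NULL, seed = 1) {
  withr::with_seed(seed, {
    n_sites <- length(beta_control)
    ids <- c(sprintf("ctrl_%02d", seq_len(n_control)),
             sprintf("obese_%02d", seq_len(n_case)))
    groups <- c(rep("control", n_control), rep("obesity", n_case))
    if (is.null(ages)) ages <- rep(40, length(ids))
    sheet <- tibble::tibble(sample_id = ids, group = groups, age = ages,
                            sex = "F")
    calls <- purrr::map_dfr(seq_along(ids), function(si) {
      beta <- if (groups[si] == "control") beta_control else beta_case
      cov <- rep(as.integer(coverage), n_sites)
      tibble::tibble(sample_id = ids[si], chrom = "chr1",
                     pos = seq_len(n_sites) * 1000L, strand = ".",
                     coverage = cov,
                     n_meth = stats::rbinom(n_sites, cov, beta))
    })
    list(calls = calls, sheet = sheet)
  })
}

# closed-form chi-square independence statistic: sum (O - E)^2 / E
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# brute-force two-sided Mann-Whitney p by direct enumeration on the
# U statistic computed from values (pairwise comparison counting)
mwu_brute <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  m <- length(x)
  u_obs <- u_of(x, y)
  cmb <- utils::combn(length(pooled), m)
  u_all <- apply(cmb, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  lo <- min(u_obs, m * length(y) - u_obs)
  hi <- max(u_obs, m * length(y) - u_obs)
  min(1, (sum(u_all <= lo + 1e-9) + sum(u_all >= hi - 1e-9)) / ncol(cmb))
}

# hypergeometric upper-tail P(X >= k) by direct choose() summation
hyper_tail <- function(k, N, K, n) {
  kk <- max(0, k):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
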