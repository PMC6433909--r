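#' Significance thresholds for differentially methylated CpGs
#'
#' A CpG is called differentially methylated when its case-control
#' methylation difference is at least `min_diff_pct` percentage points
#' and its Benjamini-Hochberg adjusted p-value is below `max_q`; a site
#' is only tested when at least `min_per_group` individuals per group
#' cover it.
#'
#' @param min_diff_pct Minimum absolute methylation difference
#'   (percentage points).
#' @param max_q Maximum adjusted p-value.
#' @param min_per_group Minimum covered individuals per group.
#' @return A list of class `dmc_thresholds`.
#' @export
dmc_thresholds <- function(min_diff_pct = 10, max_q = 0.05, min_per_group = 3) {
  stopifnot(min_diff_pct >= 0, max_q > 0, max_q <= 1, min_per_group >= 1)
  structure(list(min_diff_pct = min_diff_pct, max_q = max_q,
                 min_per_group = min_per_group),
            class = "dmc_thresholds")
}

binomial_family <- stats::binomial()

# likelihood-ratio test of the group term in
# logit(pi) = b0 + b1 * case + b2 * age, fitted to (n_meth, coverage - n_meth)
fit_site_lrt <- function(coverage, n_meth, case, age = NULL) {
  y <- cbind(n_meth, coverage - n_meth)
  n <- length(coverage)
  x0 <- if (is.null(age)) matrix(1, n, 1L) else cbind(1, age)
  x1 <- cbind(x0, as.numeric(case))
  f0 <- try(suppressWarnings(
    stats::glm.fit(x0, y, family = binomial_family)), silent = TRUE)
  f1 <- try(suppressWarnings(
    stats::glm.fit(x1, y, family = binomial_family)), silent = TRUE)
  flagged <- inherits(f0, "try-error") || inherits(f1, "try-error") ||
    !isTRUE(f0$converged) || !isTRUE(f1$converged)
  p <- if (flagged) 1 else {
    stats::pchisq(max(0, f0$deviance - f1$deviance), df = 1, lower.tail = FALSE)
  }
  beta <- n_meth / coverage
  meth_diff <- 100 * (mean(beta[case]) - mean(beta[!case]))
  c(p = p, meth_diff = meth_diff, flagged = as.numeric(flagged))
}

#' Test a single CpG site for differential methylation
#'
#' Fits a binomial logistic regression of methylated versus
#' unmethylated read counts on case status with age as covariate, and
#' returns the likelihood-ratio p-value of the case term together with
#' the methylation difference (unweighted mean of per-sample beta
#' values, case minus control, in percentage points). Non-convergent
#' fits are reported with `p = 1` and `flagged = TRUE` rather than
#' dropped.
#'
#' @param site A data frame with one row per sample and columns
#'   `coverage`, `n_meth`, `case` (logical) and optionally `age`.
#' @return A one-row tibble with `p`, `meth_diff`, `flagged`.
#' @examples
#' site <- tibble::tibble(coverage = 20, n_meth = c(2, 3, 2, 17, 18, 16),
#'                        case = rep(c(FALSE, TRUE), each = 3), age = 40)
#' test_site(site)
#' @export
test_site <- function(site) {
  stopifnot(all(c("coverage", "n_meth", "case") %in% names(site)))
  r <- fit_site_lrt(site$coverage, site$n_meth, site$case,
                    if ("age" %in% names(site)) site$age else NULL)
  tibble::tibble(p = r[["p"]], meth_diff = r[["meth_diff"]],
                 flagged = r[["flagged"]] > 0)
}

#' Call differentially methylated CpGs for one case-control contrast
#'
#' Runs the per-site logistic-regression test of [test_site()] over
#' every site covered by at least `min_per_group` individuals in both
#' the case and the control group, adjusts p-values by
#' Benjamini-Hochberg across all tested sites, and flags as significant
#' the sites with `|meth_diff| >= min_diff_pct` and `q < max_q`.
#'
#' @param calls Methylation call tibble over all samples (filtered and,
#'   optionally, histogram-transformed).
#' @param sheet Sample sheet with `sample_id`, `group`, `age`.
#' @param contrast Case group name (`"obesity"` or `"crc"`); controls
#'   are always the `"control"` group.
#' @param thresholds A [dmc_thresholds()].
#' @param covariate `"age"` to include the age covariate (default), or
#'   `NULL` for an unadjusted fit.
#' @return A tibble sorted by `(chrom, pos)` with columns `chrom`,
#'   `pos`, `strand`, `meth_diff`, `p`, `q`, `direction`, `n_case`,
#'   `n_control`, `flagged`, `significant`.
#' @export
call_dmcs <- function(calls, sheet, contrast,
                      thresholds = dmc_thresholds(), covariate = "age") {
  stopifnot(inherits(thresholds, "dmc_thresholds"))
  groups <- unique(sheet$group)
  if (!contrast %in% groups || !"control" %in% groups) {
    rlang::abort(sprintf("contrast '%s' and 'control' must both be in the sheet",
                         contrast))
  }
  use_age <- identical(covariate, "age")
  sub <- sheet[sheet$group %in% c(contrast, "control"), ]
  d <- calls |>
    dplyr::inner_join(sub[, c("sample_id", "group", "age")], by = "sample_id") |>
    dplyr::mutate(case = .data$group == contrast)

  key <- paste(d$chrom, d$pos, d$strand, sep = "\r")
  usite <- unique(key)
  idx <- split(seq_len(nrow(d)), factor(key, levels = usite))

  min_n <- thresholds$min_per_group
  res <- vector("list", length(usite))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    case <- d$case[rows]
    if (sum(case) < min_n || sum(!case) < min_n) next
    r <- fit_site_lrt(d$coverage[rows], d$n_meth[rows], case,
                      if (use_age) d$age[rows] else NULL)
    res[[i]] <- c(rows[1L], r, sum(case), sum(!case))
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    rlang::warn("call_dmcs: no testable sites")
    return(tibble::tibble(
      chrom = character(), pos = integer(), strand = character(),
      meth_diff = numeric(), p = numeric(), q = numeric(),
      direction = character(), n_case = integer(), n_control = integer(),
      flagged = logical(), significant = logical()))
  }
  m <- do.call(rbind, res)
  out <- tibble::tibble(
    chrom = d$chrom[m[, 1L]], pos = d$pos[m[, 1L]], strand = d$strand[m[, 1L]],
    meth_diff = m[, 3L], p = m[, 2L],
    q = stats::p.adjust(m[, 2L], method = "BH"),
    n_case = as.integer(m[, 5L]), n_control = as.integer(m[, 6L]),
    flagged = m[, 4L] > 0
  )
  out |>
    dplyr::mutate(
      direction = ifelse(.data$meth_diff > 0, "hyper", "hypo"),
      significant = abs(.data$meth_diff) >= thresholds$min_diff_pct &
        .data$q < thresholds$max_q
    ) |>
    dplyr::select("chrom", "pos", "strand", "meth_diff", "p", "q",
                  "direction", "n_case", "n_control", "flagged",
                  "significant") |>
    dplyr::arrange(.data$chrom, .data$pos)
}
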