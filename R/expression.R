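counts_matrix <- function(counts, check_nonneg = TRUE) {
  stopifnot("gene_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  if (check_nonneg && any(m < 0)) rlang::abort("counts must be non-negative")
  m
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-library scaling factors by the published TMM procedure: the
#' reference library is the one whose 75th count-proportion percentile
#' is closest to the mean across libraries; for every other library,
#' genes expressed in both are compared by log2 proportion ratio (M)
#' and average log2 proportion (A); genes in the upper and lower
#' `trim_M` tail of M and `trim_A` tail of A are discarded; the factor
#' is two to the power of the precision-weighted mean of the remaining
#' M values (weights from the asymptotic binomial variance); factors
#' are rescaled to geometric mean one.
#'
#' @param counts Counts tibble (`gene_id` + one column per sample).
#' @param trim_M Two-sided trim fraction on M (log-ratio).
#' @param trim_A Two-sided trim fraction on A (abundance).
#' @return A tibble `sample_id`, `lib_size`, `tmm_factor`.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2L) rlang::abort("tmm_factors: need >= 2 samples")
  lib <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)),
                function(i) stats::quantile(m[, i] / lib[i], 0.75, names = FALSE),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(m)), function(i) {
    if (i == ref) return(1)
    obs <- m[, i] / lib[i]
    rp <- m[, ref] / lib[ref]
    keep0 <- obs > 0 & rp > 0
    if (!any(keep0)) {
      rlang::warn(sprintf("tmm_factors: sample %s shares no expressed genes with the reference; factor 1",
                          colnames(m)[i]))
      return(1)
    }
    M <- log2(obs[keep0] / rp[keep0])
    A <- 0.5 * log2(obs[keep0] * rp[keep0])
    w <- (lib[i] - m[keep0, i]) / (lib[i] * m[keep0, i]) +
      (lib[ref] - m[keep0, ref]) / (lib[ref] * m[keep0, ref])
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    f <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    if (!is.finite(f) || f <= 0) 1 else f
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  tibble::tibble(sample_id = colnames(m), lib_size = unname(lib),
                 tmm_factor = unname(fac))
}

#' Normalized log2-counts-per-million
#'
#' Moderated log-CPM on TMM-scaled effective library sizes. The prior
#' is interpreted as reads per million and scaled to each effective
#' library (`prior_j = prior * L_j / 1e6`); the transform is
#' `log2((count + prior_j) / (L_j + 2 * prior_j) * 1e6)`, a pure
#' function of the count proportions, so globally rescaling every
#' library leaves the values exactly unchanged. For a library of one
#' million reads this reduces to
#' `log2((count + prior) / (lib_size * factor + 1) * 1e6)`.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param factors Factor tibble from [tmm_factors()], or `NULL` for
#'   all-one factors.
#' @param prior Average prior count added to every cell.
#' @return A tibble of the same shape with log-CPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  m <- counts_matrix(counts)
  lib <- colSums(m)
  fac <- rep(1, ncol(m))
  if (!is.null(factors)) {
    idx <- match(colnames(m), factors$sample_id)
    stopifnot(!anyNA(idx))
    fac <- factors$tmm_factor[idx]
    lib <- factors$lib_size[idx]
  }
  eff <- lib * fac
  prior_j <- prior * eff / 1e6
  out <- log2(sweep(sweep(m, 2, prior_j, "+"), 2, eff + 2 * prior_j, "/") * 1e6)
  dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id),
                   tibble::as_tibble(out))
}

#' Methylation-expression concordance on row-centered log-CPM
#'
#' Row-centers each gene's log-CPM across samples, averages per
#' condition, and compares the sign of the condition-2 minus
#' condition-1 difference with the expected direction of expression
#' change on demethylation (e.g. a gene hypermethylated in disease is
#' expected to rise when methylation is removed).
#'
#' @param logcpm Log-CPM tibble from [log_cpm()].
#' @param samples Tibble `sample_id`, `condition`.
#' @param expectations Tibble `gene_id`, `expected` with values
#'   `"up"` or `"down"` (expression change in condition 2 vs 1).
#' @param conditions Length-2 character vector ordering the
#'   conditions; defaults to their order of appearance.
#' @param tol Absolute difference below which a gene is `neutral`.
#' @return One row per expected gene: centered condition means,
#'   `delta` (cond2 - cond1), `expected`, `status`
#'   (`agree`/`disagree`/`neutral`).
#' @export
concordance_report <- function(logcpm, samples, expectations,
                               conditions = NULL, tol = 1e-8) {
  if (is.null(conditions)) conditions <- unique(samples$condition)
  stopifnot(length(conditions) == 2L)
  m <- counts_matrix(logcpm, check_nonneg = FALSE)
  centered <- m - rowMeans(m)
  cond <- samples$condition[match(colnames(m), samples$sample_id)]
  stopifnot(!anyNA(cond))
  mean1 <- rowMeans(centered[, cond == conditions[1], drop = FALSE])
  mean2 <- rowMeans(centered[, cond == conditions[2], drop = FALSE])
  out <- tibble::tibble(gene_id = rownames(m),
                        mean_cond1 = unname(mean1), mean_cond2 = unname(mean2),
                        delta = unname(mean2 - mean1))
  out <- dplyr::inner_join(expectations, out, by = "gene_id")
  out$status <- dplyr::case_when(
    abs(out$delta) <= tol ~ "neutral",
    out$delta > 0 & out$expected == "up" ~ "agree",
    out$delta < 0 & out$expected == "down" ~ "agree",
    TRUE ~ "disagree")
  names(out)[names(out) == "mean_cond1"] <- paste0("mean_", conditions[1])
  names(out)[names(out) == "mean_cond2"] <- paste0("mean_", conditions[2])
  out
}
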