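#' Per-subject mean methylation over DMR member CpGs
#'
#' For every region and subject, the coverage-weighted mean beta over
#' the region's member CpGs covered in that subject:
#' `sum(n_meth) / sum(coverage)`. Subjects covering none of the member
#' CpGs get no row (a missing cell).
#'
#' @param dmrs DMR table from [call_dmrs()] (needs the `member_pos`
#'   list-column).
#' @param calls Methylation call tibble over all samples.
#' @return A long tibble `dmr_id`, `sample_id`, `mean_beta`.
#' @export
dmr_subject_means <- function(dmrs, calls) {
  stopifnot("member_pos" %in% names(dmrs))
  members <- tibble::tibble(
    dmr_id = rep(dmrs$dmr_id, lengths(dmrs$member_pos)),
    chrom = rep(dmrs$chrom, lengths(dmrs$member_pos)),
    pos = unlist(dmrs$member_pos))
  members |>
    dplyr::inner_join(calls, by = c("chrom", "pos"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$dmr_id, .data$sample_id) |>
    dplyr::summarise(mean_beta = sum(.data$n_meth) / sum(.data$coverage),
                     .groups = "drop")
}

#' Two-sided Mann-Whitney U test
#'
#' Uses the exact permutation distribution (full enumeration over all
#' assignments of the pooled values to the two groups, so ties are
#' handled exactly) when both groups have at most `exact_max_n`
#' observations, and the tie-corrected normal approximation otherwise.
#' The two-sided exact p-value is
#' `P(U <= min(u, mn - u)) + P(U >= max(u, mn - u))`.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max_n Largest per-group size for the exact path.
#' @return A list with `u` (the U statistic of `x` over `y`, midranks
#'   for ties), `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mwu_test <- function(x, y, exact_max_n = 8) {
  m <- length(x); n <- length(y)
  stopifnot(m >= 1, n >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (max(m, n) <= exact_max_n) {
    cmb <- utils::combn(m + n, m)
    r1 <- colSums(matrix(r[cmb], nrow = m))
    u_all <- r1 - m * (m + 1) / 2
    lo <- min(u, m * n - u)
    hi <- max(u, m * n - u)
    eps <- 1e-9
    p <- (sum(u_all <= lo + eps) + sum(u_all >= hi - eps)) / length(u_all)
    return(list(u = u, p = min(1, p), method = "exact"))
  }
  wt <- try(suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)), silent = TRUE)
  p <- if (inherits(wt, "try-error") || is.nan(wt$p.value)) 1 else wt$p.value
  list(u = u, p = p, method = "normal")
}

kw_p <- function(values, groups) {
  if (length(unique(values)) < 2L) return(1)
  out <- try(suppressWarnings(stats::kruskal.test(values, factor(groups))),
             silent = TRUE)
  if (inherits(out, "try-error") || is.nan(out$p.value)) 1 else out$p.value
}

#' Select candidate DMRs by Kruskal-Wallis and Mann-Whitney U tests
#'
#' For each region's per-subject mean methylation levels, runs a
#' Kruskal-Wallis test across the three groups and pairwise
#' Mann-Whitney U tests, and selects the region when the KW p-value
#' and both case-versus-control MWU p-values are at most `alpha`
#' (marginal significance, default 0.1). When a subregion annotation
#' is supplied, a second-stage flag `selected_gene` additionally
#' requires the region to lie in a promoter or gene-body subregion. No
#' multiplicity correction is applied at this stage (raw nonparametric
#' p-values are reported).
#'
#' @param means Long tibble from [dmr_subject_means()].
#' @param sheet Sample sheet (`sample_id`, `group`).
#' @param alpha Selection threshold on the raw p-values.
#' @param annotated Optional tibble `dmr_id`, `subregion` (e.g. from
#'   [annotate_features()]).
#' @param gene_subregions Subregions counting as promoter/gene body.
#' @param min_per_group Minimum non-missing subjects per group for a
#'   region to be testable.
#' @param require_pairs Which pairwise MWU comparisons must pass:
#'   `"case_vs_control"` (both obesity-control and crc-control,
#'   default) or `"all"`.
#' @return One row per region: `dmr_id`, `testable`, `kw_p`,
#'   `mwu_obesity_control`, `mwu_crc_control`, `mwu_crc_obesity`,
#'   `selected`, and (when annotated) `subregion`, `selected_gene`.
#' @export
select_dmrs <- function(means, sheet, alpha = 0.1, annotated = NULL,
                        gene_subregions = c("promoter", "exon", "intron"),
                        min_per_group = 3,
                        require_pairs = c("case_vs_control", "all")) {
  require_pairs <- match.arg(require_pairs)
  d <- dplyr::inner_join(means, sheet[, c("sample_id", "group")],
                         by = "sample_id")
  res <- d |>
    dplyr::group_by(.data$dmr_id) |>
    dplyr::group_modify(function(g, key) {
      v <- split(g$mean_beta, g$group)
      ok <- all(c("control", "obesity", "crc") %in% names(v)) &&
        all(vapply(v, length, integer(1)) >= min_per_group)
      if (!ok) {
        return(tibble::tibble(testable = FALSE, kw_p = NA_real_,
                              mwu_obesity_control = NA_real_,
                              mwu_crc_control = NA_real_,
                              mwu_crc_obesity = NA_real_))
      }
      tibble::tibble(
        testable = TRUE,
        kw_p = kw_p(g$mean_beta, g$group),
        mwu_obesity_control = mwu_test(v$obesity, v$control)$p,
        mwu_crc_control = mwu_test(v$crc, v$control)$p,
        mwu_crc_obesity = mwu_test(v$crc, v$obesity)$p)
    }) |>
    dplyr::ungroup()
  pair_ok <- if (require_pairs == "all") {
    res$mwu_obesity_control <= alpha & res$mwu_crc_control <= alpha &
      res$mwu_crc_obesity <= alpha
  } else {
    res$mwu_obesity_control <= alpha & res$mwu_crc_control <= alpha
  }
  res$selected <- res$testable & res$kw_p <= alpha & pair_ok
  res$selected[is.na(res$selected)] <- FALSE
  if (!is.null(annotated)) {
    res <- dplyr::left_join(res, annotated[, c("dmr_id", "subregion")],
                            by = "dmr_id")
    res$selected_gene <- res$selected & res$subregion %in% gene_subregions
  }
  res
}
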