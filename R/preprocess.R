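#' Site-filtering policy
#'
#' Captures the standard RRBS call filters: minimum coverage 5X,
#' removal of sites above the per-sample 99.9th coverage percentile
#' (PCR-duplicate guard), and exclusion of the sex chromosomes and the
#' mitochondrion.
#'
#' @param min_coverage Minimum read coverage (reads).
#' @param max_coverage_quantile Per-sample coverage quantile above which
#'   sites are dropped (strictly above; quantile by linear
#'   interpolation).
#' @param excluded_chroms Chromosomes removed entirely.
#' @param min_per_group Minimum samples per group for a site to be
#'   testable (enforced by the differential caller, recorded here).
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(min_coverage = 5,
                          max_coverage_quantile = 0.999,
                          excluded_chroms = c("chrX", "chrY", "chrM"),
                          min_per_group = 3) {
  stopifnot(min_coverage >= 1,
            max_coverage_quantile > 0, max_coverage_quantile <= 1,
            min_per_group >= 1)
  structure(list(min_coverage = min_coverage,
                 max_coverage_quantile = max_coverage_quantile,
                 excluded_chroms = excluded_chroms,
                 min_per_group = min_per_group),
            class = "filter_policy")
}

#' Filter methylation calls by coverage and chromosome
#'
#' Applies, independently per sample: drop sites with coverage below
#' `min_coverage`, drop sites with coverage strictly above that sample's
#' `max_coverage_quantile` coverage percentile (linear-interpolation
#' quantile), and drop all sites on excluded chromosomes. The
#' percentile rule is re-evaluated on its own output until stable, so
#' filtering is idempotent: re-applying the policy changes nothing.
#'
#' @param calls Methylation call tibble (any number of samples).
#' @param policy A [filter_policy()].
#' @return The filtered call tibble.
#' @export
filter_calls <- function(calls, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  out <- calls |>
    dplyr::filter(!(.data$chrom %in% policy$excluded_chroms),
                  .data$coverage >= policy$min_coverage)
  repeat {
    n_before <- nrow(out)
    out <- out |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::filter(.data$coverage <= stats::quantile(
        .data$coverage, policy$max_coverage_quantile, type = 7)) |>
      dplyr::ungroup()
    if (nrow(out) == n_before) break
  }
  if (nrow(out) == 0L) rlang::warn("filter_calls: no sites retained")
  out
}

#' Normalize read coverage between samples
#'
#' Scales each sample's coverages by the ratio of the grand median (the
#' median of per-sample median coverages) to that sample's median
#' coverage, rounding to integers with a floor of one read. Methylated
#' counts are scaled by the same factor so that per-site beta values are
#' preserved up to rounding (|beta' - beta| <= 1/coverage').
#'
#' @param calls Methylation call tibble with at least two samples.
#' @return The tibble with rescaled `coverage` and `n_meth`.
#' @export
normalize_coverage <- function(calls) {
  meds <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(med = stats::median(.data$coverage), .groups = "drop")
  if (nrow(meds) < 2L) rlang::abort("normalize_coverage: need >= 2 samples")
  grand <- stats::median(meds$med)
  calls |>
    dplyr::left_join(meds, by = "sample_id") |>
    dplyr::mutate(
      beta = .data$n_meth / .data$coverage,
      coverage = pmax(1L, as.integer(round(.data$coverage * grand / .data$med))),
      n_meth = as.integer(round(.data$beta * .data$coverage))
    ) |>
    dplyr::select(-"med", -"beta")
}

#' Equalize case methylation distributions to the control group
#'
#' Maps each case sample's beta values onto the pooled control empirical
#' beta distribution by monotone quantile matching: a site at empirical
#' quantile q within its own sample is assigned the pooled-control
#' q-quantile. Methylated counts are recomputed as
#' `round(beta' * coverage)`; coverage is untouched. The mapping is
#' monotone non-decreasing in beta, so within-sample rank order is
#' preserved exactly.
#'
#' @param case_calls Call tibble for the case samples (one or more).
#' @param control_calls Call tibble for the pooled control samples.
#' @return `case_calls` with transformed `n_meth`.
#' @export
histogram_transform <- function(case_calls, control_calls) {
  if (nrow(control_calls) == 0L) {
    rlang::abort("histogram_transform: control pool is empty")
  }
  ctrl_beta <- sort(control_calls$n_meth / control_calls$coverage)
  if (diff(range(ctrl_beta)) == 0) {
    rlang::abort("histogram_transform: degenerate control distribution (all beta equal)")
  }
  case_calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      beta = .data$n_meth / .data$coverage,
      q = (rank(.data$beta, ties.method = "average") - 0.5) / dplyr::n(),
      beta_new = stats::quantile(ctrl_beta, probs = .data$q, type = 7,
                                 names = FALSE),
      n_meth = as.integer(round(.data$beta_new * .data$coverage))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"beta", -"q", -"beta_new")
}
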