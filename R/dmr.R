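#' Data-driven CpG gap cutoff for region segmentation
#'
#' RRBS coordinates are bimodal in the distance between consecutive
#' assayed CpGs: short within-fragment gaps and long between-fragment
#' gaps. A two-component Gaussian mixture is fitted to the pooled log10
#' nearest-neighbour distances (consecutive tested CpGs per chromosome)
#' and the cutoff is placed where the two weighted component densities
#' cross between the component means. When the mixture is degenerate
#' (component means closer than 0.2 in log10 units, too few sites, or a
#' failed fit) the cutoff falls back to 100 bp.
#'
#' @param sites Tibble of tested sites with columns `chrom`, `pos`.
#' @param fallback Fallback cutoff in bp.
#' @param min_sites Minimum number of tested sites for a mixture fit.
#' @return Cutoff distance in bp (numeric scalar).
#' @export
distance_cutoff <- function(sites, fallback = 100, min_sites = 100) {
  d <- sites |>
    dplyr::distinct(.data$chrom, .data$pos) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(gap = .data$pos - dplyr::lag(.data$pos)) |>
    dplyr::ungroup()
  gaps <- d$gap[!is.na(d$gap) & d$gap > 0]
  if (nrow(dplyr::distinct(sites, .data$chrom, .data$pos)) < min_sites) {
    rlang::warn(sprintf("distance_cutoff: fewer than %d sites, using %g bp",
                        min_sites, fallback))
    return(fallback)
  }
  x <- log10(gaps)
  fit <- try(suppressWarnings(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)), silent = TRUE)
  if (inherits(fit, "try-error") || is.null(fit)) return(fallback)
  mu <- as.numeric(fit$parameters$mean)
  sigma <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sigma) == 1L) sigma <- rep(sigma, 2L)
  pro <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sigma <- sigma[o]; pro <- pro[o]
  if (diff(mu) < 0.2) return(fallback)
  f <- function(z) pro[1] * stats::dnorm(z, mu[1], sigma[1]) -
    pro[2] * stats::dnorm(z, mu[2], sigma[2])
  if (f(mu[1]) <= 0 || f(mu[2]) >= 0) return(fallback)
  cross <- stats::uniroot(f, lower = mu[1], upper = mu[2])$root
  round(10^cross)
}

#' Region-level significance filters
#'
#' A candidate region is reported as a differentially methylated region
#' when it contains at least `min_cpgs` tested CpGs, at least `min_dmcs`
#' significant DMCs, and its mean methylation difference exceeds
#' `min_mean_diff` percentage points in absolute value.
#'
#' @param min_cpgs Minimum tested CpGs per region.
#' @param min_dmcs Minimum significant DMCs per region.
#' @param min_mean_diff Minimum absolute mean methylation difference
#'   (percentage points, strict inequality).
#' @return A list of class `dmr_filters`.
#' @export
dmr_filters <- function(min_cpgs = 3, min_dmcs = 1, min_mean_diff = 5) {
  structure(list(min_cpgs = min_cpgs, min_dmcs = min_dmcs,
                 min_mean_diff = min_mean_diff),
            class = "dmr_filters")
}

signed_stouffer <- function(p, meth_diff) {
  z <- stats::qnorm(pmin(p, 1) / 2, lower.tail = FALSE) * sign(meth_diff)
  z[!is.finite(z)] <- 0
  zc <- sum(z) / sqrt(length(z))
  2 * stats::pnorm(abs(zc), lower.tail = FALSE)
}

#' Segment tested CpGs into differentially methylated regions
#'
#' Consecutive tested CpGs closer than the gap cutoff are merged into
#' candidate regions. Each candidate gets a region p-value by signed
#' Stouffer combination of its member-site p-values (z-scores signed by
#' the member methylation difference, so direction-inconsistent regions
#' cancel), a Benjamini-Hochberg q-value across candidates, and is then
#' filtered by the region criteria of [dmr_filters()].
#'
#' @param dmcs Full tested-site table from [call_dmcs()] (all tested
#'   sites, not only the significant ones).
#' @param cutoff Gap cutoff in bp (see [distance_cutoff()]).
#' @param filters A [dmr_filters()].
#' @return A tibble of regions with columns `dmr_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `n_cpgs`, `n_dmcs`, `mean_meth_diff`,
#'   `region_p`, `region_q`, `direction`, and a `member_pos`
#'   list-column of member CpG positions.
#' @export
call_dmrs <- function(dmcs, cutoff, filters = dmr_filters()) {
  stopifnot(inherits(filters, "dmr_filters"))
  if (nrow(dmcs) == 0L) {
    return(tibble::tibble(dmr_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_cpgs = integer(), n_dmcs = integer(),
                          mean_meth_diff = numeric(), region_p = numeric(),
                          region_q = numeric(), direction = character(),
                          member_pos = list()))
  }
  candidates <- dmcs |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(gap = .data$pos - dplyr::lag(.data$pos),
                  block = cumsum(is.na(.data$gap) | .data$gap > cutoff)) |>
    dplyr::group_by(.data$chrom, .data$block) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos) + 1L,
      n_cpgs = dplyr::n(), n_dmcs = sum(.data$significant),
      mean_meth_diff = mean(.data$meth_diff),
      region_p = signed_stouffer(.data$p, .data$meth_diff),
      member_pos = list(.data$pos),
      .groups = "drop")
  candidates$region_q <- stats::p.adjust(candidates$region_p, method = "BH")
  candidates |>
    dplyr::filter(.data$n_cpgs >= filters$min_cpgs,
                  .data$n_dmcs >= filters$min_dmcs,
                  abs(.data$mean_meth_diff) > filters$min_mean_diff) |>
    dplyr::mutate(direction = ifelse(.data$mean_meth_diff > 0, "hyper", "hypo"),
                  dmr_id = sprintf("dmr_%05d", dplyr::row_number())) |>
    dplyr::select("dmr_id", "chrom", "start", "end", "n_cpgs", "n_dmcs",
                  "mean_meth_diff", "region_p", "region_q", "direction",
                  "member_pos")
}
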