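#' Construct a cross-contrast overlap result
#'
#' Container for the intersection of two contrasts' differential
#' features: Venn counts, the 2x2 hyper/hypo direction quadrant table
#' over overlapping features, the chi-square independence test on that
#' table, and the concordant fraction. Normally produced by
#' [overlap_dmcs()] or [overlap_dmrs()], but can be assembled directly
#' from counts (e.g. published totals).
#'
#' @param n_overlap,n_a_only,n_b_only Venn counts.
#' @param quadrant 2x2 matrix of overlapping-feature counts, rows =
#'   direction in contrast A (`hyper`, `hypo`), columns = direction in
#'   contrast B; `NULL` if unknown.
#' @param pairs Optional tibble of the overlapping feature pairs.
#' @param labels Length-2 character vector naming contrasts A and B.
#' @param correct Apply Yates continuity correction to the chi-square
#'   test (default off: the motivating tables are large).
#' @return An object of class `contrast_overlap`.
#' @export
contrast_overlap <- function(n_overlap, n_a_only, n_b_only, quadrant = NULL,
                             pairs = NULL, labels = c("A", "B"),
                             correct = FALSE) {
  chi2 <- chi2_p <- NA_real_
  concordant <- NA_real_
  if (!is.null(quadrant)) {
    stopifnot(is.matrix(quadrant), all(dim(quadrant) == 2L))
    dimnames(quadrant) <- list(a = c("hyper", "hypo"), b = c("hyper", "hypo"))
    if (sum(quadrant) != n_overlap) {
      rlang::abort("quadrant table must sum to n_overlap")
    }
    if (n_overlap > 0) {
      concordant <- (quadrant[1, 1] + quadrant[2, 2]) / n_overlap
    }
    if (any(rowSums(quadrant) == 0) || any(colSums(quadrant) == 0)) {
      rlang::warn("quadrant table has a zero margin; chi-square undefined (NA)")
    } else {
      ct <- suppressWarnings(stats::chisq.test(quadrant, correct = correct))
      chi2 <- unname(ct$statistic)
      chi2_p <- unname(ct$p.value)
    }
  }
  structure(list(n_overlap = n_overlap, n_a_only = n_a_only,
                 n_b_only = n_b_only, quadrant = quadrant,
                 chi2 = chi2, chi2_p = chi2_p,
                 concordant_fraction = concordant,
                 pairs = pairs, labels = labels),
            class = "contrast_overlap")
}

quadrant_matrix <- function(dir_a, dir_b) {
  m <- matrix(0, 2, 2, dimnames = list(a = c("hyper", "hypo"),
                                       b = c("hyper", "hypo")))
  t <- table(factor(dir_a, c("hyper", "hypo")),
             factor(dir_b, c("hyper", "hypo")))
  m[] <- as.numeric(t)
  m
}

#' Overlap significant DMCs from two contrasts
#'
#' A CpG is an overlapping DMC when it is significant in both
#' contrasts (exact `(chrom, pos)` site-key intersection). The
#' direction of each overlapping site is taken independently per
#' contrast from that contrast's methylation-difference sign, and the
#' association between contrasts is tested by chi-square independence
#' on the 2x2 direction quadrant table.
#'
#' @param dmcs_a,dmcs_b DMC tables from [call_dmcs()]; rows with
#'   `significant == TRUE` are used (tables without a `significant`
#'   column are taken as already-significant sets).
#' @param labels Contrast names for reporting.
#' @inheritParams contrast_overlap
#' @return A [contrast_overlap] object whose `pairs` element holds one
#'   row per overlapping site with both contrasts' `meth_diff` and
#'   direction.
#' @export
overlap_dmcs <- function(dmcs_a, dmcs_b, labels = c("A", "B"),
                         correct = FALSE) {
  sig <- function(x) if ("significant" %in% names(x)) x[x$significant, ] else x
  a <- sig(dmcs_a)
  b <- sig(dmcs_b)
  pairs <- dplyr::inner_join(
    dplyr::select(a, "chrom", "pos", diff_a = "meth_diff", dir_a = "direction"),
    dplyr::select(b, "chrom", "pos", diff_b = "meth_diff", dir_b = "direction"),
    by = c("chrom", "pos")) |>
    dplyr::mutate(quadrant = paste(.data$dir_a, .data$dir_b, sep = "-"))
  contrast_overlap(
    n_overlap = nrow(pairs),
    n_a_only = nrow(a) - nrow(pairs),
    n_b_only = nrow(b) - nrow(pairs),
    quadrant = if (nrow(pairs) > 0) quadrant_matrix(pairs$dir_a, pairs$dir_b),
    pairs = pairs, labels = labels, correct = correct)
}

#' Overlap DMRs from two contrasts by interval intersection
#'
#' Regions overlap when they share at least `min_overlap_bp` bp on the
#' same chromosome. Pairing is one-to-one and greedy: candidate pairs
#' are ranked by intersection width (ties broken toward the leftmost B
#' region, then the leftmost A region) and accepted while both members
#' are unused, so each region is counted at most once.
#'
#' @param dmrs_a,dmrs_b DMR tables from [call_dmrs()].
#' @param min_overlap_bp Minimum intersection width in bp.
#' @inheritParams overlap_dmcs
#' @return A [contrast_overlap] object; `pairs` holds the matched
#'   region pairs with both mean methylation differences and the
#'   intersection width.
#' @export
overlap_dmrs <- function(dmrs_a, dmrs_b, min_overlap_bp = 1,
                         labels = c("A", "B"), correct = FALSE) {
  cand <- dplyr::inner_join(
    dplyr::select(dmrs_a, id_a = "dmr_id", "chrom", start_a = "start",
                  end_a = "end", diff_a = "mean_meth_diff", dir_a = "direction"),
    dplyr::select(dmrs_b, id_b = "dmr_id", "chrom", start_b = "start",
                  end_b = "end", diff_b = "mean_meth_diff", dir_b = "direction"),
    by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(intersection = pmin(.data$end_a, .data$end_b) -
                    pmax(.data$start_a, .data$start_b)) |>
    dplyr::filter(.data$intersection >= min_overlap_bp) |>
    dplyr::arrange(dplyr::desc(.data$intersection), .data$start_b, .data$start_a)
  used_a <- used_b <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$id_a[i] %in% used_a) && !(cand$id_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$id_a[i])
      used_b <- c(used_b, cand$id_b[i])
    }
  }
  pairs <- cand[keep, ] |>
    dplyr::mutate(quadrant = paste(.data$dir_a, .data$dir_b, sep = "-"))
  contrast_overlap(
    n_overlap = nrow(pairs),
    n_a_only = nrow(dmrs_a) - nrow(pairs),
    n_b_only = nrow(dmrs_b) - nrow(pairs),
    quadrant = if (nrow(pairs) > 0) quadrant_matrix(pairs$dir_a, pairs$dir_b),
    pairs = pairs, labels = labels, correct = correct)
}

#' Percentage of one contrast's features that overlap the other
#'
#' @param overlap A [contrast_overlap] object.
#' @param denominator Which contrast supplies the denominator: `"a"` or
#'   `"b"`.
#' @return `100 * n_overlap / (n_overlap + n_<denominator>_only)`.
#' @examples
#' ov <- contrast_overlap(n_overlap = 40605, n_a_only = 145906,
#'                        n_b_only = 51204, labels = c("crc", "obesity"))
#' overlap_fraction(ov, "b")  # share of obesity DMCs that overlap
#' @export
overlap_fraction <- function(overlap, denominator = c("a", "b")) {
  denominator <- match.arg(denominator)
  only <- if (denominator == "a") overlap$n_a_only else overlap$n_b_only
  total <- overlap$n_overlap + only
  if (total == 0) rlang::abort("overlap_fraction: denominator contrast is empty")
  100 * overlap$n_overlap / total
}

#' @export
print.contrast_overlap <- function(x, ...) {
  cat(sprintf("Cross-contrast overlap (%s vs %s)\n", x$labels[1], x$labels[2]))
  cat(sprintf("  %s only: %d   %s only: %d   overlap: %d\n",
              x$labels[1], x$n_a_only, x$labels[2], x$n_b_only, x$n_overlap))
  if (!is.null(x$quadrant)) {
    cat("  direction quadrants (rows:", x$labels[1], "cols:", x$labels[2], ")\n")
    print(x$quadrant)
    cat(sprintf("  concordant fraction: %.3f  chi2 = %s, p = %s\n",
                x$concordant_fraction, format(x$chi2), format(x$chi2_p)))
  }
  invisible(x)
}

#' Tidy a cross-contrast overlap
#'
#' @param x A [contrast_overlap] object.
#' @param ... Unused.
#' @return One row per direction quadrant with counts and fractions.
#' @method tidy contrast_overlap
#' @export
tidy.contrast_overlap <- function(x, ...) {
  if (is.null(x$quadrant)) {
    return(tibble::tibble(dir_a = character(), dir_b = character(),
                          n = numeric(), fraction = numeric()))
  }
  tibble::tibble(
    dir_a = rep(rownames(x$quadrant), 2L),
    dir_b = rep(colnames(x$quadrant), each = 2L),
    n = as.numeric(x$quadrant),
    fraction = as.numeric(x$quadrant) / max(1, x$n_overlap))
}

#' Glance at a cross-contrast overlap
#'
#' @param x A [contrast_overlap] object.
#' @param ... Unused.
#' @return A one-row tibble with the Venn counts, overlap fractions,
#'   concordant fraction and chi-square result.
#' @method glance contrast_overlap
#' @export
glance.contrast_overlap <- function(x, ...) {
  tibble::tibble(
    n_a_only = x$n_a_only, n_b_only = x$n_b_only, n_overlap = x$n_overlap,
    pct_of_a = if (x$n_overlap + x$n_a_only > 0) overlap_fraction(x, "a") else NA_real_,
    pct_of_b = if (x$n_overlap + x$n_b_only > 0) overlap_fraction(x, "b") else NA_real_,
    concordant_fraction = x$concordant_fraction,
    chi2 = x$chi2, chi2_p = x$chi2_p)
}
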