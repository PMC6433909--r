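#' Assign features to gene subregions and CpG-island context
#'
#' Each feature (a DMR interval, or a single CpG treated as a width-1
#' interval) receives exactly one gene subregion and one island
#' context. Subregions follow the precedence promoter > exon > intron >
#' intergenic, where the promoter is the 2 kb window immediately
#' upstream of a gene's transcription start site on the gene strand,
#' and intron means inside the gene span but in no exon or promoter.
#' Island context is `island` when the feature intersects a CpG island,
#' `shore` when it lies within `shore_width` bp of one, else
#' `open_sea`. The assigning gene is the one with the largest
#' intersection; features on chromosomes absent from the annotation are
#' intergenic with a warning.
#'
#' @param features Tibble with `chrom` and either `start`/`end`
#'   (0-based half-open) or `pos`.
#' @param annotation A `genome_annotation` (see [read_annotation()] or
#'   [simulate_annotation()]).
#' @param promoter_width Promoter window upstream of the TSS, in bp.
#' @param shore_width Shore width flanking islands, in bp.
#' @return `features` with added columns `subregion`, `island_context`,
#'   `gene_id`.
#' @export
annotate_features <- function(features, annotation,
                              promoter_width = 2000, shore_width = 2000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  feats <- features
  if (!"start" %in% names(feats)) {
    stopifnot("pos" %in% names(feats))
    feats$start <- feats$pos
    feats$end <- feats$pos + 1L
  }
  genes <- annotation$genes
  promoters <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$tss - promoter_width, genes$tss),
    end = ifelse(genes$strand == "+", genes$tss, genes$tss + promoter_width))
  exons <- tibble::tibble(
    gene_id = rep(genes$gene_id, lengths(genes$exon_starts)),
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts), end = unlist(genes$exon_ends))
  bodies <- tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                           start = genes$gene_start, end = genes$gene_end)
  islands <- annotation$islands

  known <- unique(c(genes$chrom, islands$chrom))
  if (!all(feats$chrom %in% known)) {
    rlang::warn("annotate_features: feature(s) on chromosome absent from annotation; set intergenic")
  }

  best_hit <- function(f_start, f_end, f_chrom, ivals) {
    hit <- ivals[ivals$chrom == f_chrom &
                   ivals$start < f_end & f_start < ivals$end, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    ov <- pmin(hit$end, f_end) - pmax(hit$start, f_start)
    hit$gene_id[which.max(ov)]
  }
  n <- nrow(feats)
  subregion <- character(n)
  gene_id <- rep(NA_character_, n)
  island_context <- character(n)
  for (i in seq_len(n)) {
    s <- feats$start[i]; e <- feats$end[i]; ch <- feats$chrom[i]
    g <- best_hit(s, e, ch, promoters)
    if (!is.null(g)) {
      subregion[i] <- "promoter"; gene_id[i] <- g
    } else if (!is.null(g <- best_hit(s, e, ch, exons))) {
      subregion[i] <- "exon"; gene_id[i] <- g
    } else if (!is.null(g <- best_hit(s, e, ch, bodies))) {
      subregion[i] <- "intron"; gene_id[i] <- g
    } else {
      subregion[i] <- "intergenic"
    }
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    island_context[i] <- if (nrow(isl) > 0L &&
                             any(isl$start < e & s < isl$end)) {
      "island"
    } else if (nrow(isl) > 0L &&
               any(isl$start - shore_width < e & s < isl$end + shore_width)) {
      "shore"
    } else {
      "open_sea"
    }
  }
  feats$subregion <- subregion
  feats$island_context <- island_context
  feats$gene_id <- gene_id
  feats
}

#' Total-variation distance between two count profiles
#'
#' Profiles are normalized to probability vectors; the distance is
#' half the L1 distance, in `[0, 1]`.
#'
#' @param p,q Non-negative count (or probability) vectors of equal
#'   length, aligned by category.
#' @return The total-variation distance.
#' @examples
#' tv_distance(c(1, 1, 1, 1), c(1, 0, 0, 0))  # 0.75
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0),
            sum(p) > 0, sum(q) > 0)
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}

#' Profile annotated feature sets by genomic context
#'
#' Tabulates hyper/hypo feature counts per gene subregion and per
#' island context for each feature set (typically cancer-specific,
#' obesity-specific, and overlapping), and computes pairwise
#' total-variation distances between the sets' normalized
#' direction-by-category profiles. The TV distances make the visual
#' question "which specific set does the overlap resemble?" a number.
#'
#' @param annotated Tibble with columns `set`, `direction`,
#'   `subregion`, `island_context` (one row per feature).
#' @return A list with `counts` (set x direction x category counts,
#'   long) and `tv` (pairwise TV distances per category type).
#' @export
distribution_profile <- function(annotated) {
  stopifnot(all(c("set", "direction", "subregion", "island_context")
                %in% names(annotated)))
  if (nrow(annotated) == 0L) rlang::abort("distribution_profile: empty input")
  long <- dplyr::bind_rows(
    annotated |>
      dplyr::count(.data$set, .data$direction,
                   category = .data$subregion, name = "n") |>
      dplyr::mutate(category_type = "subregion"),
    annotated |>
      dplyr::count(.data$set, .data$direction,
                   category = .data$island_context, name = "n") |>
      dplyr::mutate(category_type = "island_context"))
  sets <- unique(annotated$set)
  tv <- purrr::map_dfr(c("subregion", "island_context"), function(ct) {
    wide <- long |>
      dplyr::filter(.data$category_type == ct) |>
      tidyr::complete(set = sets, .data$direction, .data$category,
                      fill = list(n = 0)) |>
      dplyr::arrange(.data$direction, .data$category)
    combn_sets <- utils::combn(sets, 2L, simplify = FALSE)
    purrr::map_dfr(combn_sets, function(pr) {
      p <- wide$n[wide$set == pr[1]]
      q <- wide$n[wide$set == pr[2]]
      tibble::tibble(category_type = ct, set1 = pr[1], set2 = pr[2],
                     tv = tv_distance(p, q))
    })
  })
  list(counts = long[, c("set", "direction", "category_type", "category", "n")],
       tv = tv)
}
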