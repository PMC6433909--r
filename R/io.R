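#' Read a Bismark-style coverage file of CpG methylation calls
#'
#' Parses the six-column coverage dialect emitted by Bismark's
#' `coverage2cytosine`/`bismark2bedGraph` tools: chromosome, start, end
#' (both 1-based, inclusive, start == end for a CpG), methylation
#' percentage, methylated read count, unmethylated read count. Files may
#' be gzip-compressed. Positions are converted to the package-internal
#' 0-based convention on load.
#'
#' @param path Path to a coverage TSV (optionally `.gz`).
#' @param sample_id Sample identifier attached to every record. Defaults
#'   to the file name stripped of extensions.
#' @param strand Strand to record for all sites (the coverage dialect
#'   carries no strand column); one of `"+"`, `"-"`, `"."`.
#' @return A tibble of methylation calls with columns `sample_id`,
#'   `chrom`, `pos` (0-based), `strand`, `coverage`, `n_meth`, sorted by
#'   `(chrom, pos)`.
#' @examples
#' tmp <- tempfile(fileext = ".cov")
#' writeLines("chr1\t100\t100\t50\t5\t5", tmp)
#' read_coverage_file(tmp, sample_id = "s1")
#' @export
read_coverage_file <- function(path, sample_id = NULL, strand = ".") {
  stopifnot(file.exists(path))
  strand <- match.arg(strand, c(".", "+", "-"))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(cov|txt|tsv)(\\.gz)?$", "", basename(path))
  }
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "meth_pct", "count_meth", "count_unmeth"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      meth_pct = readr::col_double(),
      count_meth = readr::col_double(),
      count_unmeth = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    rlang::warn(sprintf("coverage file '%s' is empty", path))
    return(empty_calls(sample_id))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    rlang::abort(sprintf(
      "malformed coverage rows in '%s' at line(s) %s",
      path, paste(utils::head(unique(probs$row), 10L), collapse = ", ")
    ))
  }
  bad <- which(
    is.na(raw$start) | is.na(raw$count_meth) | is.na(raw$count_unmeth) |
      raw$count_meth < 0 | raw$count_unmeth < 0 | raw$start < 1 |
      raw$start != raw$end
  )
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "invalid coverage record(s) in '%s' at line(s) %s",
      path, paste(utils::head(bad, 10L), collapse = ", ")
    ))
  }
  calls <- tibble::tibble(
    sample_id = sample_id,
    chrom = raw$chrom,
    pos = as.integer(raw$start - 1L),
    strand = strand,
    coverage = as.integer(raw$count_meth + raw$count_unmeth),
    n_meth = as.integer(raw$count_meth)
  )
  validate_calls(calls, context = path)
  dplyr::arrange(calls, .data$chrom, .data$pos)
}

empty_calls <- function(sample_id = character()) {
  tibble::tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    strand = character(), coverage = integer(), n_meth = integer()
  )
}

#' Validate a methylation call table
#'
#' Enforces the call-set invariants: `n_meth <= coverage`, `coverage >= 1`,
#' and unique positions per `(sample_id, chrom, strand)`.
#'
#' @param calls A methylation call tibble (see [read_coverage_file()]).
#' @param context Label used in error messages (e.g. a file path).
#' @return `calls`, invisibly, if valid.
#' @export
validate_calls <- function(calls, context = "calls") {
  req <- c("sample_id", "chrom", "pos", "strand", "coverage", "n_meth")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("%s: missing column(s) %s", context,
                         paste(missing_cols, collapse = ", ")))
  }
  if (any(calls$coverage < 1L)) {
    rlang::abort(sprintf("%s: coverage < 1 at %d record(s)", context,
                         sum(calls$coverage < 1L)))
  }
  over <- calls$n_meth > calls$coverage
  if (any(over)) {
    i <- which(over)[1L]
    rlang::abort(sprintf("%s: n_meth > coverage at %s:%d", context,
                         calls$chrom[i], calls$pos[i]))
  }
  dup <- duplicated(calls[, c("sample_id", "chrom", "pos", "strand")])
  if (any(dup)) {
    i <- which(dup)[1L]
    rlang::abort(sprintf("%s: duplicate site %s:%d (strand %s) in sample %s",
                         context, calls$chrom[i], calls$pos[i],
                         calls$strand[i], calls$sample_id[i]))
  }
  invisible(calls)
}

#' Write methylation calls in Bismark coverage format
#'
#' Inverse of [read_coverage_file()]: internal 0-based positions are
#' written back as 1-based inclusive start/end columns.
#'
#' @param calls A single-sample methylation call tibble.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(calls, path) {
  stopifnot(length(unique(calls$sample_id)) <= 1L)
  out <- tibble::tibble(
    chrom = calls$chrom,
    start = calls$pos + 1L,
    end = calls$pos + 1L,
    meth_pct = round(100 * calls$n_meth / calls$coverage, 6),
    count_meth = calls$n_meth,
    count_unmeth = calls$coverage - calls$n_meth
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read or write a sample sheet
#'
#' The sample sheet is a CSV with columns `sample_id`, `group` (one of
#' `control`, `obesity`, `crc`), `age` (years) and `sex` (`F`, `M` or
#' `unknown`).
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character()
  ), progress = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_csv(sheet, path, progress = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(sheet) {
  stopifnot(all(c("sample_id", "group", "age", "sex") %in% names(sheet)))
  if (anyDuplicated(sheet$sample_id)) {
    rlang::abort("sample sheet: duplicated sample_id")
  }
  bad <- setdiff(unique(sheet$group), c("control", "obesity", "crc"))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("sample sheet: unknown group(s) %s",
                         paste(bad, collapse = ", ")))
  }
  invisible(sheet)
}

#' Read a BED file of intervals
#'
#' Accepts BED3 or BED6; coordinates are 0-based half-open, as in the
#' BED standard, and are kept as-is internally.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @return A tibble with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  if (length(first) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  nm <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6L))]
  bed <- readr::read_tsv(path, col_names = nm, progress = FALSE,
                         col_types = readr::cols(chrom = readr::col_character()))
  if (any(bed$end <= bed$start)) {
    i <- which(bed$end <= bed$start)[1L]
    rlang::abort(sprintf("BED interval with end <= start at line %d (%s:%s-%s)",
                         i, bed$chrom[i], bed$start[i], bed$end[i]))
  }
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  bed
}

#' @rdname read_bed
#' @param records A tibble with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` are written when present.
#' @export
write_bed <- function(records, path) {
  if (any(records$end <= records$start)) {
    rlang::abort("cannot write BED interval with end <= start")
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(records))
  readr::write_tsv(records[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read or write refFlat-like gene models
#'
#' The gene-model TSV has columns `gene_id`, `chrom`, `strand`, `tss`,
#' `exon_starts`, `exon_ends`, where the exon columns are comma-joined
#' 0-based half-open coordinates. Internally exons become integer
#' list-columns.
#'
#' @param path Path to the gene-model TSV.
#' @return A tibble with list-columns `exon_starts`, `exon_ends` plus
#'   derived `gene_start`/`gene_end` (span of the exons).
#' @export
read_gene_models <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), tss = readr::col_integer(),
    exon_starts = readr::col_character(), exon_ends = readr::col_character()
  ), progress = FALSE)
  g$exon_starts <- lapply(strsplit(g$exon_starts, ","), as.integer)
  g$exon_ends <- lapply(strsplit(g$exon_ends, ","), as.integer)
  validate_gene_models(g)
}

#' @rdname read_gene_models
#' @param genes A gene-model tibble as returned by [read_gene_models()].
#' @export
write_gene_models <- function(genes, path) {
  out <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss,
    exon_starts = vapply(genes$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

validate_gene_models <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss",
                  "exon_starts", "exon_ends") %in% names(genes)))
  for (i in seq_len(nrow(genes))) {
    s <- genes$exon_starts[[i]]
    e <- genes$exon_ends[[i]]
    if (length(s) != length(e) || length(s) == 0L || any(e <= s)) {
      rlang::abort(sprintf("gene %s: invalid exon intervals", genes$gene_id[i]))
    }
  }
  genes$gene_start <- vapply(genes$exon_starts, min, integer(1))
  genes$gene_end <- vapply(genes$exon_ends, max, integer(1))
  # the promoter anchor must sit at the strand-appropriate end of the span
  bad <- ifelse(genes$strand == "+",
                genes$tss != genes$gene_start,
                genes$tss != genes$gene_end)
  if (any(bad)) {
    rlang::abort(sprintf("gene %s: TSS outside gene span for its strand",
                         genes$gene_id[which(bad)[1L]]))
  }
  genes
}

#' Load a genome annotation (gene models + CpG islands)
#'
#' @param genes_path Gene-model TSV (see [read_gene_models()]).
#' @param islands_path BED file of CpG-island intervals.
#' @return A list with elements `genes` and `islands` (islands merged so
#'   that no two overlap), of class `genome_annotation`.
#' @export
read_annotation <- function(genes_path, islands_path) {
  genes <- read_gene_models(genes_path)
  islands <- merge_intervals(read_bed(islands_path))
  structure(list(genes = genes, islands = islands),
            class = "genome_annotation")
}

#' Merge overlapping intervals per chromosome
#'
#' @param bed A tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return A tibble of disjoint intervals sorted by `(chrom, start)`.
#' @export
merge_intervals <- function(bed) {
  if (nrow(bed) == 0L) return(bed[, c("chrom", "start", "end")])
  bed |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_block = .data$start > dplyr::lag(cummax(.data$end), default = -1L),
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$chrom, .data$block) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end")
}

#' Read or write a gene-by-sample count matrix
#'
#' Counts TSV: first column `gene_id`, one integer column per sample.
#'
#' @param path Path to the counts TSV.
#' @return A tibble with `gene_id` plus one column per sample.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (any(vapply(counts[-1], function(x) any(x < 0), logical(1)))) {
    rlang::abort("counts matrix contains negative values")
  }
  counts
}

#' @rdname read_counts
#' @param counts A counts tibble (`gene_id` + sample columns).
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each GMT line is `term_id <TAB> term_name <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `term_id`, `term_name` and a `genes`
#'   list-column of member gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3L
  if (any(short)) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 fields", which(short)[1L]))
  }
  sets <- tibble::tibble(
    term_id = vapply(parts, `[[`, "", 1L),
    term_name = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(sets$term_id)) rlang::abort("GMT: duplicated term ids")
  sets
}

#' Write a named list of tables as TSV reports
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
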