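# Default factor vocabularies. The genotype order runs from the fully smooth
# deletion (tec1) to the fully ruffled one (dig1); the spatiotemporal order is
# whole colony at day 2, day-5 interior, day-5 periphery. All figures and the
# G-cluster label semantics rely on these orders.

#' Default genotype levels, smooth to ruffled
#' @return character vector of the four genotype levels
#' @export
genotype_levels <- function() c("tec1", "wt", "sfl1", "dig1")

#' Default spatiotemporal levels
#' @return character vector of the three spatiotemporal levels
#' @export
spatio_levels <- function() c("day2", "day5_in", "day5_out")

#' Construct and validate a count matrix
#'
#' A `count_matrix` is an integer matrix of read counts with genes as rows
#' (unique systematic names) and sequencing libraries as columns.
#'
#' @param counts numeric matrix with rownames (gene ids) and colnames
#'   (library ids); all entries non-negative integers.
#' @return the validated matrix with class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("count matrix is empty")
  if (is.null(rownames(counts))) stop("count matrix lacks gene identifiers (rownames)")
  if (is.null(colnames(counts))) stop("count matrix lacks library identifiers (colnames)")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicated gene identifier(s): ", paste(unique(dup), collapse = ", "))
  dupl <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dupl))
    stop("duplicated library identifier(s): ", paste(unique(dupl), collapse = ", "))
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(as.numeric(counts))))[1]
    stop("non-numeric count at ", .cell_name(counts, bad))
  }
  if (anyNA(counts)) stop("missing (NA) count at ", .cell_name(counts, which(is.na(counts))[1]))
  neg <- which(counts < 0)
  if (length(neg)) stop("negative count at ", .cell_name(counts, neg[1]))
  nonint <- which(abs(counts - round(counts)) > 1e-8)
  if (length(nonint)) stop("non-integer count at ", .cell_name(counts, nonint[1]))
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

.cell_name <- function(m, idx) {
  rc <- arrayInd(idx, dim(m))
  sprintf("gene '%s', library '%s'", rownames(m)[rc[1]], colnames(m)[rc[2]])
}

#' Read a count matrix
#'
#' Supported dialects: `tsv_featurecounts` (tab-separated, `#` comment lines
#' skipped, first column the gene id, count columns selected by header name,
#' the standard annotation columns Chr/Start/End/Strand/Length dropped),
#' `csv_matrix` (plain CSV, first column gene ids, remaining columns one per
#' library), and `xlsx_sheet` (first or named sheet of a workbook, same
#' layout as `csv_matrix`; requires the readxl package).
#'
#' @param path file to read.
#' @param dialect one of `"tsv_featurecounts"`, `"csv_matrix"`, `"xlsx_sheet"`.
#' @param count_columns optional character vector naming the columns to keep
#'   as libraries (default: all non-annotation columns).
#' @param sheet sheet name or index for the xlsx dialect.
#' @return a [count_matrix].
#' @export
read_counts <- function(path,
                        dialect = c("tsv_featurecounts", "csv_matrix", "xlsx_sheet"),
                        count_columns = NULL, sheet = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (dialect == "tsv_featurecounts") {
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    annot <- intersect(c("Chr", "Start", "End", "Strand", "Length"), names(df))
    df <- df[, setdiff(names(df), annot), drop = FALSE]
  } else if (dialect == "csv_matrix") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("the xlsx_sheet dialect requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                        check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2L) stop("count table has no library columns")
  gene_ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (!is.null(count_columns)) {
    missing_cols <- setdiff(count_columns, names(df))
    if (length(missing_cols))
      stop("count column(s) not found: ", paste(missing_cols, collapse = ", "))
    df <- df[, count_columns, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "numeric")
  }
  rownames(m) <- gene_ids
  count_matrix(m)
}

#' Write a count matrix
#'
#' Inverse of [read_counts] for the text dialects (`tsv_featurecounts`,
#' `csv_matrix`); the xlsx dialect is read-only.
#'
#' @param cm a [count_matrix].
#' @param path output file.
#' @param dialect `"tsv_featurecounts"` or `"csv_matrix"`.
#' @export
write_counts <- function(cm, path, dialect = c("tsv_featurecounts", "csv_matrix")) {
  dialect <- match.arg(dialect)
  df <- data.frame(Geneid = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE)
  if (dialect == "tsv_featurecounts") {
    writeLines("# Program:colonyexpr; gene-level read counts", path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  } else {
    utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Restrict a count matrix to the gene universe
#'
#' Keeps exactly the genes whose identifier starts with `prefix`, preserving
#' order. The study's universe is the set of S288c ORFs, i.e. systematic
#' names beginning with "Y".
#'
#' @param cm a [count_matrix].
#' @param prefix non-empty identifier prefix (default `"Y"`).
#' @return the filtered [count_matrix]; error if no gene matches.
#' @export
filter_gene_universe <- function(cm, prefix = "Y") {
  stopifnot(is.character(prefix), length(prefix) == 1L)
  if (!nzchar(prefix)) stop("prefix must be non-empty")
  keep <- startsWith(rownames(cm), prefix)
  if (!any(keep))
    stop("gene-universe filter with prefix '", prefix,
         "' removed every gene; pipeline cannot proceed")
  out <- unclass(cm)[keep, , drop = FALSE]
  count_matrix(out)
}

#' Construct and validate a sample design
#'
#' @param df data.frame with columns `library_id`, `genotype`, `spatio`,
#'   `replicate`.
#' @param genotypes,spatios allowed level vocabularies, in display order.
#' @return a `sample_design` data.frame; attributes `cells` (cell-count
#'   table) and `balanced` report the design balance.
#' @export
sample_design <- function(df, genotypes = genotype_levels(),
                          spatios = spatio_levels()) {
  need <- c("library_id", "genotype", "spatio", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$library_id <- as.character(df$library_id)
  dup <- df$library_id[duplicated(df$library_id)]
  if (length(dup))
    stop("duplicated library_id in design: ", paste(unique(dup), collapse = ", "))
  bad_g <- setdiff(unique(as.character(df$genotype)), genotypes)
  if (length(bad_g))
    stop("unknown genotype level(s) ", paste(bad_g, collapse = ", "),
         "; allowed: ", paste(genotypes, collapse = ", "))
  bad_s <- setdiff(unique(as.character(df$spatio)), spatios)
  if (length(bad_s))
    stop("unknown spatio level(s) ", paste(bad_s, collapse = ", "),
         "; allowed: ", paste(spatios, collapse = ", "))
  df$genotype <- factor(df$genotype, levels = genotypes)
  df$spatio <- factor(df$spatio, levels = spatios)
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  cells <- table(df$genotype, df$spatio)
  empty <- which(cells == 0, arr.ind = TRUE)
  if (nrow(empty))
    stop("empty design cell(s): ",
         paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  balanced <- length(unique(as.vector(cells))) == 1L
  attr(df, "cells") <- cells
  attr(df, "balanced") <- balanced
  if (!balanced) {
    deficient <- which(cells < max(cells), arr.ind = TRUE)
    attr(df, "deficient_cells") <-
      sprintf("(%s, %s)", rownames(cells)[deficient[, 1]],
              colnames(cells)[deficient[, 2]])
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read a sample design CSV
#'
#' Expects header columns `library_id,genotype,spatio,replicate`.
#'
#' @inheritParams sample_design
#' @param path CSV file.
#' @return a validated [sample_design].
#' @export
read_design <- function(path, genotypes = genotype_levels(),
                        spatios = spatio_levels()) {
  if (!file.exists(path)) stop("design file not found: ", path)
  sample_design(utils::read.csv(path, stringsAsFactors = FALSE),
                genotypes = genotypes, spatios = spatios)
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design: %d libraries, %d x %d cells, %s\n",
              nrow(x), nlevels(x$genotype), nlevels(x$spatio),
              if (isTRUE(attr(x, "balanced"))) "balanced"
              else paste("UNBALANCED; deficient:",
                         paste(attr(x, "deficient_cells"), collapse = " "))))
  print(attr(x, "cells"))
  invisible(x)
}

#' Align a count matrix with a sample design
#'
#' Fails loudly when the library sets differ; otherwise reorders the count
#' columns to the design row order.
#'
#' @param cm a [count_matrix].
#' @param design a [sample_design].
#' @return the reordered [count_matrix].
#' @export
join_counts_design <- function(cm, design) {
  only_counts <- setdiff(colnames(cm), design$library_id)
  only_design <- setdiff(design$library_id, colnames(cm))
  if (length(only_counts) || length(only_design))
    stop("library sets differ between counts and design",
         if (length(only_counts))
           paste0("; only in counts: ", paste(only_counts, collapse = ", ")),
         if (length(only_design))
           paste0("; only in design: ", paste(only_design, collapse = ", ")))
  out <- unclass(cm)[, design$library_id, drop = FALSE]
  count_matrix(out)
}
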