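#' Construct an expression matrix
#'
#' The universal carrier between pipeline stages: a numeric gene-by-sample
#' matrix with unique row (gene) and column (sample) identifiers, an explicit
#' `NA` missing marker, and a declared value kind.
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @param value_kind One of `"counts"`, `"logcpm"`, `"logfc"`,
#'   `"expression"`. Under `"counts"` all non-missing values must be
#'   non-negative integers.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `value_kind`.
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, "counts")
#' @export
expression_matrix <- function(values,
                              value_kind = c("counts", "logcpm", "logfc",
                                             "expression")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'values' must have gene rownames and sample colnames",
         call. = FALSE)
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    stop("duplicate gene id: ", dup_g[1L], call. = FALSE)
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stop("duplicate sample id: ", dup_s[1L], call. = FALSE)
  if (value_kind == "counts") {
    v <- values[!is.na(values)]
    if (any(v < 0))
      stop("negative values are not allowed when value_kind is 'counts'",
           call. = FALSE)
    if (any(v != round(v)))
      stop("non-integral values are not allowed when value_kind is 'counts'",
           call. = FALSE)
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         value_kind = value_kind),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples, %d missing\n",
              x$value_kind, length(x$gene_ids), length(x$sample_ids),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' numeric cells with `"NA"` (case-sensitive) as the missing token. Row and
#' column order are preserved exactly.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path,
                                   value_kind = c("counts", "logcpm",
                                                  "logfc", "expression")) {
  value_kind <- match.arg(value_kind)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L)
    stop("expression TSV needs a gene-id column plus at least one sample: ",
         path, call. = FALSE)
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- df[[j + 1L]]
    is_na <- cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column '%s' in %s",
                   cell[bad[1L]], bad[1L], sample_ids[j], path),
           call. = FALSE)
    num[is_na] <- NA_real_
    vals[, j] <- num
  }
  expression_matrix(vals, value_kind)
}

#' Write an expression matrix as TSV
#'
#' Values are serialized at full (17 significant digit) precision so that a
#' write/read round-trip is value-exact; missing values are written as `"NA"`.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  chr <- matrix(sprintf("%.17g", x$values), nrow(x$values))
  chr[is.na(x$values)] <- "NA"
  df <- data.frame(gene_id = x$gene_ids, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", x$sample_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Checks the required columns (`sample_id`, `study_id`, `subject_id`,
#' `group`, `timepoint`, `time_category`), the controlled vocabularies of the
#' enum columns, and sample-id uniqueness. Extra columns are kept untouched
#' as covariates.
#'
#' @param df A data frame.
#' @return The validated data frame (classed `sample_metadata`).
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "study_id", "subject_id", "group", "timepoint",
                "time_category")
  missing_col <- setdiff(required, colnames(df))
  if (length(missing_col))
    stop("missing required metadata column: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", dup[1L], call. = FALSE)
  check_enum <- function(col, levels) {
    bad <- which(!(df[[col]] %in% levels))
    if (length(bad))
      stop(sprintf("invalid %s token '%s' at row %d", col,
                   df[[col]][bad[1L]], bad[1L]), call. = FALSE)
  }
  check_enum("group", GROUP_LEVELS)
  check_enum("timepoint", TIMEPOINT_LEVELS)
  check_enum("time_category", TIME_CATEGORY_LEVELS)
  class(df) <- unique(c("sample_metadata", class(df)))
  df
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with the required columns of
#'   [sample_metadata()]; any further columns are carried as covariates.
#' @return A validated `sample_metadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Write sample metadata as TSV
#'
#' @param meta A `sample_metadata` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of member gene ids.
#' @param descriptions Optional named character vector of descriptions
#'   (carried verbatim, never interpreted).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named", call. = FALSE)
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup))
    stop("duplicate gene set name: ", dup[1L], call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("gene sets must be non-empty", call. = FALSE)
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n",
              length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line; tab-separated fields; field 1 is
#' the set name, field 2 a description, fields 3+ the members. Duplicate
#' members within a line are silently de-duplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    nm <- fields[1L]
    if (nm %in% names(sets))
      stop("duplicate gene set name: ", nm, call. = FALSE)
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in set '%s' de-duplicated", nm),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[nm]] <- members
    descriptions[nm] <- fields[2L]
  }
  gene_set_collection(sets, descriptions)
}

#' Write gene sets as GMT
#'
#' @param x A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
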