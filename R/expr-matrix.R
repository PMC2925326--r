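#' Expression matrix container
#'
#' An `expr_matrix` holds a dense probe x sample intensity matrix for one
#' tissue depot together with a flag recording whether it has been quantile
#' normalized. Probe identifiers are the row names, sample identifiers the
#' column names; both must be unique and all values finite and non-negative
#' (raw fluorescence intensities are never negative).
#'
#' @param values numeric matrix, rows = probes, columns = samples, with
#'   unique row and column names.
#' @param tissue depot label, one of `"SAT"`, `"VAT"`, `"OTHER"`.
#' @param normalized logical; has `quantile_normalize()` been applied?
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `tissue` and `normalized`.
#' @examples
#' m <- matrix(rexp(12, 1 / 100), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' expression_matrix(m, tissue = "SAT")
#' @export
expression_matrix <- function(values, tissue = c("SAT", "VAT", "OTHER"),
                              normalized = FALSE) {
  tissue <- match.arg(tissue)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values) || !all(is.finite(values)))
    stop("expression values must be finite with no missing entries")
  if (any(values < 0))
    stop("expression intensities must be non-negative")
  structure(list(values = values, tissue = tissue,
                 normalized = isTRUE(normalized)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$tissue,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a probe x sample expression matrix
#'
#' Reads either a plain tab-separated file (first column `probe_id`,
#' remaining columns one per sample) or the table section of a GEO
#' series-matrix text file (the lines between `!series_matrix_table_begin`
#' and `!series_matrix_table_end`, with quoted identifiers tolerated).
#' Duplicate probe identifiers and non-numeric or missing cells are
#' rejected: arrays are complete, and readers refuse to impute.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()] with `normalized = FALSE`.
#' @export
read_expression_matrix <- function(path, format = c("tsv", "geo_series_matrix"),
                                   tissue = c("SAT", "VAT", "OTHER")) {
  format <- match.arg(format)
  tissue <- match.arg(tissue)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "geo_series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("no series-matrix table section found in ", path)
    lines <- lines[(beg + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("malformed header: expected probe id column plus sample columns")
  samples <- header[-1L]
  body <- fields[-1L]
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop("row ", bad[1L] + 1L, " has ", lengths(body)[bad[1L]],
         " fields, expected ", length(header))
  probes <- vapply(body, `[[`, character(1L), 1L)
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  cells <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body),
                  byrow = TRUE)
  vals <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  nn <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nn)) {
    stop(sprintf("non-numeric or missing value '%s' at probe '%s', sample '%s'",
                 cells[nn[1L, 1L], nn[1L, 2L]], probes[nn[1L, 1L]],
                 samples[nn[1L, 2L]]))
  }
  dimnames(vals) <- list(probes, samples)
  expression_matrix(vals, tissue = tissue, normalized = FALSE)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] for the `tsv` format: first column
#' `probe_id`, one column per sample. Values are written at full precision
#' so that a write/read round trip reproduces the matrix exactly.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(probe_id = probe_ids(x),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical trait table
#'
#' Expects a header row naming the traits, a first column `sample_id`, and
#' one row per sample; empty cells denote missing values and are preserved
#' as `NA`. All trait columns are numeric except `gender`, which is recoded
#' to 0/1 through `gender_map`.
#'
#' @param path path to the tab-separated trait file.
#' @param gender_map named numeric vector mapping the file's gender labels
#'   to 0/1, e.g. `c(M = 0, F = 1)`. Labels `"0"` and `"1"` are always
#'   accepted as themselves.
#' @return A data.frame with column `sample_id` followed by numeric trait
#'   columns; `gender` (if present) is coded 0/1.
#' @export
read_trait_table <- function(path, gender_map = c(M = 0, F = 1)) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = "")
  if (names(raw)[1L] != "sample_id")
    stop("first column must be 'sample_id', got '", names(raw)[1L], "'")
  out <- data.frame(sample_id = raw$sample_id, stringsAsFactors = FALSE)
  for (nm in names(raw)[-1L]) {
    col <- raw[[nm]]
    if (identical(nm, "gender")) {
      map <- c(gender_map, "0" = 0, "1" = 1)
      known <- col %in% names(map) | is.na(col)
      if (!all(known))
        stop("unknown gender label(s): ",
             paste(unique(col[!known]), collapse = ", "))
      out[[nm]] <- unname(map[col])
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in trait '%s', sample '%s'",
                     col[bad[1L]], nm, out$sample_id[bad[1L]]))
      out[[nm]] <- num
    }
  }
  out
}

#' @rdname read_trait_table
#' @param traits trait data.frame as returned by `read_trait_table()`.
#' @export
write_trait_table <- function(traits, path) {
  stopifnot(is.data.frame(traits), names(traits)[1L] == "sample_id")
  fmt <- traits
  for (nm in names(fmt)[-1L])
    fmt[[nm]] <- ifelse(is.na(fmt[[nm]]), "",
                        format(fmt[[nm]], digits = 17, trim = TRUE))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
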