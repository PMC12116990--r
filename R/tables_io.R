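#' Construct an abundance table
#'
#' An `abundance_table` is a numeric features x samples matrix with unique
#' row (feature) and column (sample) ids, all values non-negative, and a
#' `mode` recording whether the values are raw counts or relative abundances
#' (every sample column summing to 1).
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   `rownames` are feature ids, `colnames` sample ids.
#' @param mode `"counts"` or `"relative"`.
#' @return an object of class `abundance_table` (a matrix with a `mode`
#'   attribute).
#' @export
abundance_table <- function(values, mode = c("relative", "counts"),
                            validate = TRUE) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  x <- structure(values, mode_flag = mode,
                 class = c("abundance_table", "matrix", "array"))
  if (validate) validate_abundance_table(x)
  x
}

#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, mode_flag = table_mode(x),
                     class = c("abundance_table", "matrix", "array"))
  out
}

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
validate_abundance_table <- function(x) {
  v <- unclass(x)
  if (anyDuplicated(rownames(v)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (anyNA(v)) stop("missing cells are not allowed")
  if (any(v < 0)) stop("negative abundance values are not allowed")
  if (identical(table_mode(x), "relative")) {
    cs <- colSums(v)
    bad <- which(abs(cs - 1) > 1e-8)
    if (length(bad))
      stop("relative-mode columns must sum to 1; offending sample(s): ",
           paste0(colnames(v)[bad], " (sum ", signif(cs[bad], 6), ")",
                  collapse = ", "))
  }
  invisible(x)
}

#' @rdname abundance_table
#' @export
table_mode <- function(x) attr(x, "mode_flag")

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples (mode = %s)\n",
              nrow(x), ncol(x), table_mode(x)))
  invisible(x)
}

#' Read a features x samples abundance table from TSV
#'
#' Expects a header row of sample ids and feature ids in the first column.
#'
#' @param path file path.
#' @param mode `"relative"` or `"counts"`; validated accordingly.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return an [abundance_table].
#' @export
read_abundance_table <- function(path, mode = c("relative", "counts"),
                                 sep = "\t") {
  mode <- match.arg(mode)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("table must have a feature-id column and >= 1 sample")
  ids <- df[[1L]]
  m <- as.matrix(df[-1L])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at feature '%s', sample '%s' (value '%s')",
                 ids[bad[1L]], colnames(m)[bad[2L]], m[bad[1L], bad[2L]]))
  }
  dimnames(num) <- list(ids, colnames(m))
  abundance_table(num, mode = mode)
}

#' Write an abundance table as TSV
#'
#' @param x an [abundance_table] (or any named numeric matrix).
#' @param path output path.
#' @param id_column name for the first (feature id) column.
#' @param sep field separator.
#' @export
write_abundance_table <- function(x, path, id_column = "feature_id",
                                  sep = "\t") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Close a counts table to relative abundance
#'
#' Divides every sample column by its sum (total-sum scaling), so that
#' columns sum to 1. Idempotent in the sense that re-closing relative data
#' is refused rather than silently re-applied.
#'
#' @param x an [abundance_table] with `mode = "counts"`.
#' @return the closed table with `mode = "relative"`.
#' @export
close_to_relative <- function(x) {
  if (!inherits(x, "abundance_table")) stop("`x` must be an abundance_table")
  if (!identical(table_mode(x), "counts"))
    stop("close_to_relative() expects a counts-mode table; input is already relative")
  cs <- colSums(x)
  zero <- which(cs == 0)
  if (length(zero))
    stop("all-zero sample column(s): ", paste(colnames(x)[zero], collapse = ", "))
  abundance_table(sweep(unclass(x), 2L, cs, "/"), mode = "relative")
}

#' Read per-sample metadata
#'
#' The metadata TSV must carry the exact header
#' `sample_id, subject_id, timepoint, sex`. Timepoints become an ordered
#' factor (numeric order when the labels parse as numbers, file order
#' otherwise); `(subject_id, timepoint)` pairs must be unique.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a `data.frame` with columns `sample_id`, `subject_id`,
#'   `timepoint` (ordered factor) and `sex` (factor with levels F, M).
#' @export
read_sample_metadata <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "")
  req <- c("sample_id", "subject_id", "timepoint", "sex")
  if (!identical(colnames(df)[seq_along(req)], req))
    stop("metadata header must be: ", paste(req, collapse = ", "))
  as_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df a data.frame with the metadata columns.
#' @export
as_sample_metadata <- function(df) {
  req <- c("sample_id", "subject_id", "timepoint", "sex")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[req]
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (anyDuplicated(df[c("subject_id", "timepoint")]))
    stop("duplicate (subject_id, timepoint) pairs in metadata")
  tp <- as.character(df$timepoint)
  lev <- unique(tp)
  num <- suppressWarnings(as.numeric(lev))
  if (!anyNA(num)) lev <- lev[order(num)]
  df$timepoint <- factor(tp, levels = lev, ordered = TRUE)
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  df$sex <- factor(df$sex, levels = c("F", "M"))
  rownames(df) <- NULL
  df
}

#' Write sample metadata as TSV
#' @param metadata metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  out <- metadata
  out$timepoint <- as.character(out$timepoint)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metabolite concentration table (analytes x samples)
#'
#' Same layout as an abundance table; values are non-negative concentrations
#' in whatever unit each analyte was measured in (e.g. ug/mL serum).
#'
#' @param path file path.
#' @param sep field separator.
#' @return numeric matrix, analytes in rows.
#' @export
read_metabolite_table <- function(path, sep = "\t") {
  x <- read_abundance_table(path, mode = "counts", sep = sep)
  m <- unclass(x)
  attr(m, "mode_flag") <- NULL
  class(m) <- c("matrix", "array")
  m
}

#' Align an abundance table with its sample metadata
#'
#' Reorders both objects to the common set of samples (metadata order);
#' samples present on only one side are dropped with a warning giving the
#' count.
#'
#' @param table an [abundance_table] or analyte matrix with sample columns.
#' @param metadata metadata data.frame (see [read_sample_metadata]).
#' @return `list(table =, metadata =)` with identical sample order.
#' @export
align_samples <- function(table, metadata) {
  common <- intersect(metadata$sample_id, colnames(table))
  if (!length(common))
    stop("no samples shared between abundance table and metadata")
  dropped <- (ncol(table) - length(common)) +
    (nrow(metadata) - length(common))
  if (dropped > 0)
    warning(sprintf("align_samples: dropped %d unmatched sample(s)", dropped))
  md <- metadata[metadata$sample_id %in% common, , drop = FALSE]
  rownames(md) <- NULL
  tab <- table[, md$sample_id, drop = FALSE]
  list(table = tab, metadata = md)
}
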