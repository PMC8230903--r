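#' Expression time series
#'
#' A light container for a genes-by-time expression matrix `x_i(t)`, the time
#' spacing between consecutive columns, and (optionally) a developmental-stage
#' label per time point. This is the common currency passed between the
#' simulator, the noise generator, and the network-inference functions.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#'   Row names are taken as gene identifiers (generated if absent).
#' @param dt positive time spacing between consecutive columns, in index
#'   units. Lag `k` in the lasso refers to `k * dt`.
#' @param stages optional character vector of stage labels, one per column.
#' @return an object of class `expression_ts`.
#' @export
expression_ts <- function(values, dt = 1, stages = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("'values' must be a numeric matrix")
  if (ncol(values) < 2L) stopf("an expression time series needs at least 2 time points")
  if (anyNA(values)) stopf("'values' must not contain missing values")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stopf("'dt' must be a positive scalar")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  }
  if (anyDuplicated(rownames(values))) stopf("gene identifiers must be unique")
  if (!is.null(stages)) {
    stages <- as.character(stages)
    if (length(stages) != ncol(values)) {
      stopf("'stages' must have one label per time point (%d != %d)",
            length(stages), ncol(values))
    }
  }
  structure(list(values = values, dt = dt, stages = stages),
            class = "expression_ts")
}

#' @export
print.expression_ts <- function(x, ...) {
  cat(sprintf("Expression time series: %d gene(s) x %d time point(s), dt = %g\n",
              nrow(x$values), ncol(x$values), x$dt))
  if (!is.null(x$stages)) {
    cat("Stages:", paste(unique(x$stages), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_ts <- function(x) dim(x$values)

#' @export
as.matrix.expression_ts <- function(x, ...) x$values

gene_ids <- function(ts) rownames(ts$values)

#' Read / write expression time series as TSV
#'
#' Genes in rows, time points in columns, with a header row of time-point
#' labels and gene identifiers in the first column.
#'
#' @param ts an [expression_ts()].
#' @param path file path.
#' @param dt,stages see [expression_ts()] (used when reading).
#' @return `read_expression_tsv` returns an `expression_ts`;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "expression_ts"))
  df <- data.frame(gene_id = rownames(ts$values), ts$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, dt = 1, stages = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_ts(m, dt = dt, stages = stages)
}
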