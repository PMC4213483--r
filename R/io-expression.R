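#' Read a feature-by-sample expression matrix from TSV
#'
#' The expected layout is the one emitted by [write_expression()]: first
#' column feature identifiers, header row sample identifiers, numeric body.
#' An optional sibling detection-P file of identical shape can be attached.
#' Missing cells (`NA` in the file) are kept as `NA`, never coerced to zero.
#'
#' @param path Path to the expression TSV.
#' @param detection_path Optional path to a detection-P TSV with the same
#'   rows and columns.
#' @return A numeric matrix with feature rownames and sample colnames; if
#'   `detection_path` is given, the detection-P matrix is attached as
#'   attribute `"detectionP"`.
#' @export
read_expression <- function(path, detection_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs an ID column plus >=1 sample")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature IDs in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body) & body != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                 ids[bad[1L, 1L]], colnames(df)[-1L][bad[1L, 2L]]),
         call. = FALSE)
  dimnames(num) <- list(ids, colnames(df)[-1L])
  if (!is.null(detection_path)) {
    dp <- read_expression(detection_path)
    if (!identical(dim(dp), dim(num)) ||
        !identical(rownames(dp), rownames(num)) ||
        !identical(colnames(dp), colnames(num)))
      stop("detection-P matrix shape or identifiers do not match expression",
           call. = FALSE)
    attr(num, "detectionP") <- dp
  }
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: numeric content round-trips at the stated
#' precision (15 significant digits).
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_col = "feature_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a sample metadata (design) table
#'
#' Plain TSV with one row per sample. [read_design()] validates the columns
#' used by the pipeline when present.
#'
#' @param path File path.
#' @param design A data.frame as returned by [default_design()].
#' @return A data.frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("design table must contain a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in design table", call. = FALSE)
  if (all(c("cell_type", "depolarized") %in% colnames(df)) &&
      any(df$depolarized == 1 & df$cell_type != "neuron"))
    stop("depolarized = 1 is only valid for neurons", call. = FALSE)
  df
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' Optional step for platforms with multiple probes per gene: for each gene
#' the probe with the highest mean expression is retained (a common,
#' deterministic collapse rule).
#'
#' @param expr Probe-by-sample matrix.
#' @param probe2gene Named character vector mapping probe ID to gene ID.
#' @return Gene-by-sample matrix; unmapped probes are dropped.
#' @export
collapse_probes <- function(expr, probe2gene) {
  keep <- rownames(expr) %in% names(probe2gene)
  expr <- expr[keep, , drop = FALSE]
  gene <- probe2gene[rownames(expr)]
  means <- rowMeans(expr, na.rm = TRUE)
  ord <- order(gene, -means, rownames(expr))
  expr <- expr[ord, , drop = FALSE]
  gene <- gene[ord]
  sel <- !duplicated(gene)
  out <- expr[sel, , drop = FALSE]
  rownames(out) <- unname(gene[sel])
  out
}

#' One-line stage log
#'
#' Every pipeline stage reports its input shape, parameter echo, and output
#' shape through this helper so a run is auditable from its log alone.
#' Silenced with `options(coexnet.quiet = TRUE)`.
#' @param stage Stage name.
#' @param ... Named values to echo.
#' @keywords internal
stage_log <- function(stage, ...) {
  if (isTRUE(getOption("coexnet.quiet", FALSE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), vapply(kv, function(v)
                  paste(format(v), collapse = "x"), character(1)),
                  sep = "=", collapse = " "))
  message(msg)
  invisible(NULL)
}
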