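#' Quantile normalization
#'
#' Forces every sample (column) onto the common across-sample mean
#' distribution while preserving within-sample rank order; tied values
#' receive the mean of the mean-quantile values they span. Idempotent on
#' tie-free data: a second application changes nothing.
#'
#' @param mat Numeric feature x sample matrix (no missing values).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  check_finite(mat)
  if (anyNA(mat))
    stop("missing values are not supported by quantile normalization",
         call. = FALSE)
  target <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(x)
    ave(target[rank(x, ties.method = "first")], x, FUN = mean))
  dimnames(out) <- dimnames(mat)
  out
}

#' Log2 transform and quantile-normalize raw intensities
#'
#' @param raw Strictly positive feature x sample intensity matrix. Values
#'   <= 0 trigger a shift-log: the whole matrix is shifted so its minimum
#'   is 1 before taking log2 (with a warning).
#' @return Quantile-normalized log2 matrix; a `detectionP` attribute on the
#'   input is carried through untouched.
#' @export
log2_quantile_normalize <- function(raw) {
  check_finite(raw)
  dp <- attr(raw, "detectionP")
  if (any(raw <= 0)) {
    warning("non-positive intensities; applying shift-log")
    raw <- raw - min(raw) + 1
  }
  out <- quantile_normalize(log2(raw))
  if (!is.null(dp)) attr(out, "detectionP") <- dp
  out
}

check_finite <- function(mat) {
  bad <- which(!is.finite(mat) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- if (is.null(rownames(mat))) bad[1L, 1L] else rownames(mat)[bad[1L, 1L]]
    cn <- if (is.null(colnames(mat))) bad[1L, 2L] else colnames(mat)[bad[1L, 2L]]
    stop(sprintf("non-finite value at feature '%s', sample '%s'", rn, cn),
         call. = FALSE)
  }
  invisible(mat)
}

#' Filter features by detection P value
#'
#' A feature is called robustly expressed when its detection P value is
#' below `alpha` in at least `ceiling(min_fraction * n_samples)` samples
#' ("at least half" by default, honoured with `>=` for odd sample counts).
#'
#' @param expr Feature x sample expression matrix.
#' @param detectionP Matching detection-P matrix; if `NULL`, taken from the
#'   `detectionP` attribute of `expr`.
#' @param alpha Detection significance level.
#' @param min_fraction Minimum fraction of samples required.
#' @return The filtered matrix, with attributes `n_before`, `n_after`, and
#'   `removed` (dropped feature ids).
#' @export
filter_expressed <- function(expr, detectionP = NULL, alpha = 0.05,
                             min_fraction = 0.5) {
  if (is.null(detectionP)) detectionP <- attr(expr, "detectionP")
  if (is.null(detectionP))
    stop("no detection-P matrix supplied; to run without the detection ",
         "filter, skip this stage explicitly", call. = FALSE)
  if (!identical(dim(detectionP), dim(expr)))
    stop("detectionP shape does not match expression", call. = FALSE)
  need <- ceiling(min_fraction * ncol(expr))
  n_pass <- rowSums(detectionP < alpha)
  keep <- n_pass >= need
  out <- expr[keep, , drop = FALSE]
  attr(out, "detectionP") <- detectionP[keep, , drop = FALSE]
  attr(out, "n_before") <- nrow(expr)
  attr(out, "n_after") <- sum(keep)
  attr(out, "removed") <- rownames(expr)[!keep]
  stage_log("filter_expressed", before = nrow(expr), after = sum(keep),
            alpha = alpha, min_fraction = min_fraction)
  out
}

#' Flag outlier samples by low mean inter-sample correlation
#'
#' Computes each sample's mean Pearson correlation with all other samples
#' (mean inter-array correlation), standardizes these means across samples,
#' and flags samples whose z-score falls below `z_cut`. Flagging is
#' advisory: removal is the caller's choice. Constant (zero-variance)
#' samples are flagged with reason `"zero_variance"`.
#'
#' @param expr Feature x sample matrix (>= 3 samples).
#' @param z_cut Flagging threshold on the standardized mean correlation.
#' @return A data.frame with `sample_id`, `mean_cor`, `z`, `flagged`,
#'   `reason`.
#' @export
detect_outlier_samples <- function(expr, z_cut = -2) {
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(expr, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  cc <- suppressWarnings(stats::cor(expr, use = "pairwise.complete.obs"))
  diag(cc) <- NA
  mean_iac <- rowMeans(cc, na.rm = TRUE)
  sd_iac <- stats::sd(mean_iac[!const], na.rm = TRUE)
  z <- if (is.na(sd_iac) || sd_iac == 0) rep(0, ncol(expr))
       else (mean_iac - mean(mean_iac[!const], na.rm = TRUE)) / sd_iac
  flagged <- (!is.na(z) & z < z_cut) | const
  reason <- ifelse(const, "zero_variance",
                   ifelse(flagged, "low_mean_correlation", ""))
  data.frame(sample_id = colnames(expr), mean_cor = mean_iac, z = z,
             flagged = flagged, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}
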