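#' Module-trait association by per-module linear regression
#'
#' For each module x trait pair fits ordinary least squares
#' `ME ~ trait` and reports the slope, R-squared, the two-sided t-test P
#' value on the slope, and the Benjamini-Hochberg q value. The BH family is
#' corrected within each trait across modules by default (per-trait
#' reporting); set `pool = TRUE` to correct across the whole
#' module x trait grid.
#'
#' @param eigengenes Sample x module ME matrix (or [module_eigengenes()]
#'   output).
#' @param traits Sample x trait numeric matrix, rows aligned with the ME
#'   rows.
#' @param fdr_alpha Significance level on q.
#' @param pool Pool the BH family over all traits.
#' @return A data.frame: `module`, `trait`, `slope`, `r_squared`, `p`,
#'   `q`, `direction` ("up"/"down"), `significant`.
#' @export
associate_modules <- function(eigengenes, traits, fdr_alpha = 0.05,
                              pool = FALSE) {
  if (is.list(eigengenes)) eigengenes <- eigengenes$eigengenes
  if (nrow(eigengenes) != nrow(traits))
    stop("eigengene and trait tables have different sample counts",
         call. = FALSE)
  if (nrow(eigengenes) < 3L) stop("need at least 3 samples", call. = FALSE)
  const <- apply(traits, 2L, function(x) stats::sd(x) == 0)
  if (any(const))
    stop("constant trait(s): ",
         paste(colnames(traits)[const], collapse = ", "), call. = FALSE)
  grid <- expand.grid(module = colnames(eigengenes),
                      trait = colnames(traits),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fits <- Map(function(m, tr) {
    fit <- stats::lm(eigengenes[, m] ~ traits[, tr])
    sm <- summary(fit)
    slope <- stats::coef(fit)[2L]
    p <- sm$coefficients[2L, 4L]
    c(slope = unname(slope), r_squared = sm$r.squared, p = unname(p))
  }, grid$module, grid$trait)
  stats_mat <- do.call(rbind, fits)
  out <- cbind(grid, as.data.frame(stats_mat))
  rownames(out) <- NULL
  if (pool) {
    out$q <- stats::p.adjust(out$p, method = "BH")
  } else {
    out$q <- NA_real_
    for (tr in unique(out$trait)) {
      sel <- out$trait == tr
      out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
    }
  }
  out$direction <- ifelse(out$slope >= 0, "up", "down")
  out$significant <- out$q < fdr_alpha
  out
}

#' Gene-trait correlations
#'
#' Pearson correlation of each gene with each trait, with a flag marking
#' `|cor| > 0.5` (strict inequality). Constant genes get `NA` and are never
#' flagged.
#'
#' @param expr Feature x sample matrix.
#' @param traits Sample x trait matrix.
#' @return A data.frame in long form: `feature`, `trait`, `cor`, `flagged`.
#' @export
gene_trait_correlation <- function(expr, traits) {
  if (ncol(expr) != nrow(traits))
    stop("expression and trait tables have different sample counts",
         call. = FALSE)
  cc <- suppressWarnings(stats::cor(t(expr), traits,
                                    use = "pairwise.complete.obs"))
  out <- data.frame(
    feature = rep(rownames(cc), times = ncol(cc)),
    trait = rep(colnames(cc), each = nrow(cc)),
    cor = as.vector(cc),
    stringsAsFactors = FALSE)
  out$flagged <- !is.na(out$cor) & abs(out$cor) > 0.5
  out
}
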