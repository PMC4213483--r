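#' Permutation-based module preservation between two expression sets
#'
#' For every module of a reference partition, computes density and
#' connectivity preservation statistics in a test expression set and
#' standardizes each against a permutation null of random same-sized gene
#' sets drawn (without replacement) from the features present in both data
#' sets, excluding grey:
#'
#' * density — `meanAdj`: mean within-module signed adjacency in the test
#'   set; `meanCor`: mean within-module correlation in the test set;
#' * connectivity — `cor.kIM`: correlation of intramodular-connectivity
#'   ranks between reference and test; `cor.cor`: correlation of the
#'   module's gene-gene correlation vectors between the two sets.
#'
#' Each statistic yields `Z = (obs - mean_null) / sd_null`; `Zdensity` and
#' `Zconnectivity` are the medians of their class, and
#' `Zsummary = (Zdensity + Zconnectivity) / 2`. Modules with
#' `Zsummary > threshold` (default 2) are called preserved.
#'
#' @param ref_expr,test_expr Feature x sample matrices; features are
#'   intersected.
#' @param partition Named feature -> module vector from the reference set.
#' @param beta Soft power for the signed adjacency used in the statistics.
#' @param n_perm Number of permutations (>= 50).
#' @param seed Integer RNG seed.
#' @param threshold Zsummary preservation threshold.
#' @return A data.frame with one row per module: observed statistics, their
#'   permutation means/SDs and Z scores, `Zdensity`, `Zconnectivity`,
#'   `Zsummary`, `preserved`, `n_genes`, plus skipped modules flagged in
#'   `note`.
#' @export
module_preservation <- function(ref_expr, test_expr, partition, beta = 12,
                                n_perm = 200L, seed = 1L, threshold = 2) {
  if (n_perm < 50L) stop("n_perm must be >= 50", call. = FALSE)
  common <- intersect(rownames(ref_expr), rownames(test_expr))
  common <- intersect(common, names(partition))
  part <- partition[common]
  # null sets are drawn from every feature shared by the two data sets:
  # restricting draws to assigned (non-grey) genes makes the null itself
  # module-structured and degenerates when few modules exist
  universe <- common
  if (length(universe) < 3L)
    stop("fewer than 3 non-grey features shared between data sets",
         call. = FALSE)
  stage_log("module_preservation", common_features = length(common),
            universe = length(universe), n_perm = n_perm)
  cor_ref <- stats::cor(t(ref_expr[universe, , drop = FALSE]),
                        use = "pairwise.complete.obs")
  cor_test <- stats::cor(t(test_expr[universe, , drop = FALSE]),
                         use = "pairwise.complete.obs")
  set.seed(seed)
  mods <- setdiff(unique(part), "grey")
  rows <- lapply(mods, function(m) {
    genes <- names(part)[part == m]
    genes <- intersect(genes, universe)
    if (length(genes) < 3L) {
      return(data.frame(module = m, n_genes = length(genes),
                        Zdensity = NA_real_, Zconnectivity = NA_real_,
                        Zsummary = NA_real_, preserved = NA,
                        note = "skipped: fewer than 3 shared genes",
                        stringsAsFactors = FALSE))
    }
    idx <- match(genes, universe)
    obs <- preservation_stats(cor_ref, cor_test, idx, beta)
    null_mat <- t(vapply(seq_len(n_perm), function(i) {
      ridx <- sample.int(length(universe), length(idx))
      preservation_stats(cor_ref, cor_test, ridx, beta)
    }, numeric(4L)))
    mu <- colMeans(null_mat)
    sdev <- apply(null_mat, 2L, stats::sd)
    z <- (obs - mu) / sdev
    # a degenerate null (e.g. cor.kIM = 1 for every set when the two data
    # sets coincide) carries no evidence either way: Z = 0
    degen <- sdev == 0 & abs(obs - mu) < 1e-12
    z[degen] <- 0
    zden <- stats::median(z[c("meanAdj", "meanCor")])
    zcon <- stats::median(z[c("cor.kIM", "cor.cor")])
    zsum <- mean(c(zden, zcon))
    df <- data.frame(module = m, n_genes = length(genes),
                     Zdensity = zden, Zconnectivity = zcon,
                     Zsummary = zsum, preserved = zsum > threshold,
                     note = "", stringsAsFactors = FALSE)
    for (s in names(obs)) {
      df[[paste0(s, ".obs")]] <- obs[[s]]
      df[[paste0(s, ".null_mean")]] <- mu[[s]]
      df[[paste0(s, ".null_sd")]] <- sdev[[s]]
      df[[paste0(s, ".Z")]] <- z[[s]]
    }
    df$n_perm <- n_perm
    df
  })
  merged <- Reduce(function(a, b) merge(a, b, all = TRUE, sort = FALSE),
                   rows)
  merged[match(mods, merged$module), , drop = FALSE]
}

preservation_stats <- function(cor_ref, cor_test, idx, beta) {
  cr <- cor_ref[idx, idx]
  ct <- cor_test[idx, idx]
  at <- ((1 + ct) / 2)^beta
  ar <- ((1 + cr) / 2)^beta
  off <- upper.tri(ct)
  mean_adj <- mean(at[off])
  mean_cor <- mean(ct[off])
  kim_ref <- rowSums(ar) - 1
  kim_test <- rowSums(at) - 1
  cor_kim <- suppressWarnings(stats::cor(rank(kim_ref), rank(kim_test)))
  cor_cor <- suppressWarnings(stats::cor(cr[off], ct[off]))
  c(meanAdj = mean_adj, meanCor = mean_cor,
    cor.kIM = cor_kim, cor.cor = cor_cor)
}
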