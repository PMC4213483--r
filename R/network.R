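#' Conventional module color palette
#'
#' Color labels assigned to modules by decreasing size (largest =
#' turquoise, then blue, brown, ...), following the conventional
#' co-expression-module labeling so module names are comparable across
#' analyses. Sizes beyond the palette fall back to `module<N>`.
#'
#' @param n Number of labels required.
#' @return Character vector of `n` labels.
#' @export
module_color_order <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen",
           "darkturquoise", "darkgrey", "orange", "darkorange", "white",
           "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
           "darkolivegreen", "darkmagenta", "sienna", "yellowgreen",
           "skyblue3", "plum", "orangered", "mediumpurple")
  if (n <= length(pal)) pal[seq_len(n)]
  else c(pal, sprintf("module%d", seq_len(n - length(pal)) + length(pal)))
}

#' Signed weighted adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2) ^ beta` with Pearson correlation over
#' pairwise-complete observations, so anti-correlated genes get near-zero
#' adjacency. The diagonal is 1.
#'
#' @param expr Feature x sample matrix (>= 3 samples).
#' @param beta Soft-thresholding power.
#' @return Symmetric feature x feature matrix in `[0, 1]` with attribute
#'   `"beta"`.
#' @export
signed_adjacency <- function(expr, beta = 12) {
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(expr, 1L, stats::sd, na.rm = TRUE)
  zero <- which(!is.na(sds) & sds == 0)
  if (length(zero))
    stop("zero-variance feature(s): ",
         paste(utils::head(rownames(expr)[zero], 10L), collapse = ", "),
         call. = FALSE)
  cc <- stats::cor(t(expr), use = "pairwise.complete.obs")
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit over a grid of soft powers
#'
#' For each power, computes whole-network connectivity `k_i = sum_j a_ij`
#' (j != i), bins `k`, and regresses `log10(frequency)` on `log10(mean k)`
#' per bin. The signed R-squared is positive when the slope is negative
#' (the scale-free expectation). The recommended power is the smallest one
#' reaching `r2_cut`, or `NA` if none does.
#'
#' @param expr Feature x sample matrix.
#' @param betas Vector of candidate powers.
#' @param n_bins Number of equal-width connectivity bins.
#' @param r2_cut Signed-R2 threshold for the recommendation.
#' @return A data.frame (`beta`, `r2`, `mean_k`) with attribute
#'   `"recommended"`.
#' @export
scale_free_fit <- function(expr, betas = c(1:10, 12, 14, 16, 18, 20),
                           n_bins = 10L, r2_cut = 0.8) {
  if (!length(betas)) stop("empty beta grid", call. = FALSE)
  cc <- stats::cor(t(expr), use = "pairwise.complete.obs")
  s <- (1 + cc) / 2
  diag(s) <- 0
  res <- lapply(betas, function(b) {
    k <- colSums(s^b)
    data.frame(beta = b, r2 = scale_free_r2(k, n_bins), mean_k = mean(k))
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$r2) & out$r2 >= r2_cut
  attr(out, "recommended") <- if (any(ok)) min(out$beta[ok]) else NA_real_
  out
}

scale_free_r2 <- function(k, n_bins = 10L) {
  if (diff(range(k)) == 0) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 4L) return(NA_real_)
  x <- log10(kmean[keep]); y <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm(y ~ x)
  unname(-sign(stats::coef(fit)[2L]) * summary(fit)$r.squared)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu`; the diagonal is 1. High overlap means
#' two genes are both directly connected and share neighbors.
#'
#' @param adj Symmetric adjacency with unit diagonal.
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  a <- unname(adj)
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  L <- a %*% a
  # diag(a) = 1, so sum_{u != i,j} a_iu a_uj = L_ij - 2 a_ij; adding back
  # the a_ij numerator term gives L_ij - a_ij
  num <- L - a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Hierarchical module detection with a static height cut
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`,
#' followed by a static cut at `cut_height` (default: 99% of the maximum
#' merge height). Clusters smaller than `min_module_size` are assigned to
#' "grey"; surviving clusters are labeled through [module_color_order()] by
#' decreasing size. A deterministic approximation of dynamic tree cutting;
#' an optional kME-based reassignment refinement is available via
#' [reassign_by_kme()].
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size Smallest retained cluster.
#' @param cut_height Absolute dissimilarity cut height, or `NULL` for the
#'   default.
#' @return Named character vector feature -> module color ("grey" =
#'   unassigned), with attributes `"hclust"` and `"cut_height"`.
#' @export
cluster_and_cut <- function(tom, min_module_size = 40L, cut_height = NULL) {
  d <- stats::as.dist(1 - tom)
  h <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(h$height)
  cl <- stats::cutree(h, h = cut_height)
  partition <- relabel_by_size(cl, min_module_size)
  names(partition) <- rownames(tom)
  if (min_module_size > nrow(tom))
    warning("min_module_size exceeds feature count; all features grey")
  attr(partition, "hclust") <- h
  attr(partition, "cut_height") <- cut_height
  stage_log("cluster_and_cut", features = nrow(tom),
            modules = length(setdiff(unique(partition), "grey")),
            cut_height = round(cut_height, 4))
  partition
}

relabel_by_size <- function(cl, min_module_size) {
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order by decreasing size, breaking ties by first appearance
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  colors <- module_color_order(length(keep))
  out <- rep("grey", length(cl))
  for (i in seq_along(keep)) out[cl == keep[i]] <- colors[i]
  out
}

#' Module eigengenes
#'
#' The eigengene (ME) of a module is the first right-singular vector of the
#' standardized (per-gene mean 0, SD 1 across samples) expression of its
#' genes, i.e. the first principal component across samples. Its sign is
#' aligned so that it correlates positively with the module's mean
#' standardized expression. Constant genes are dropped with a warning.
#'
#' @param expr Feature x sample matrix.
#' @param partition Named feature -> module vector; "grey" is skipped.
#' @return List with `eigengenes` (sample x module matrix) and
#'   `var_explained` (named fraction per module).
#' @export
module_eigengenes <- function(expr, partition) {
  mods <- setdiff(unique(partition), "grey")
  mods <- mods[order(-tabulate(factor(partition, levels = mods)))]
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(partition)[partition == m]
    X <- expr[genes, , drop = FALSE]
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("module ", m, ": dropping ", sum(sds == 0),
              " constant gene(s) from the eigengene SVD")
      X <- X[sds > 0, , drop = FALSE]
    }
    if (nrow(X) < 2L)
      stop("module ", m, " has fewer than 2 usable genes", call. = FALSE)
    Z <- t(scale(t(X)))           # genes x samples, standardized per gene
    sv <- svd(Z, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    s <- suppressWarnings(stats::cor(v, colMeans(Z)))
    # exactly balanced modules (mean profile ~ 0) fall back to the first
    # usable gene for a deterministic orientation
    if (is.na(s)) s <- stats::cor(v, Z[1L, ])
    if (!is.na(s) && s < 0) v <- -v
    me[, m] <- v
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Merge modules with close eigengenes
#'
#' Iteratively clusters module eigengenes by dissimilarity `1 - cor`,
#' merges every clade of modules closer than `merge_height` (so retained
#' modules differ by at least that much), recomputes eigengenes, and
#' repeats until no merge occurs. Grey never merges. Merged modules adopt
#' the label of their largest member.
#'
#' @param expr Feature x sample matrix.
#' @param partition Named feature -> module vector.
#' @param merge_height Eigengene dissimilarity threshold.
#' @return List with `partition` and the result of [module_eigengenes()] on
#'   the merged partition.
#' @export
merge_close_modules <- function(expr, partition, merge_height = 0.25) {
  part <- partition
  repeat {
    mods <- setdiff(unique(part), "grey")
    if (length(mods) < 2L) break
    eg <- module_eigengenes(expr, part)
    dis <- 1 - stats::cor(eg$eigengenes)
    h <- stats::hclust(stats::as.dist(dis), method = "average")
    grp <- stats::cutree(h, h = merge_height)
    if (max(grp) == length(mods)) break
    sizes <- table(part)
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      if (length(members) < 2L) next
      target <- members[which.max(sizes[members])]
      part[part %in% members] <- target
    }
  }
  attributes(part) <- attributes(partition)["names"]
  names(part) <- names(partition)
  list(partition = part, eigengenes = module_eigengenes(expr, part))
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module
#' eigengene. Constant genes get `NA`.
#'
#' @param expr Feature x sample matrix.
#' @param eigengenes Sample x module ME matrix (or the list returned by
#'   [module_eigengenes()]).
#' @return Feature x module kME matrix.
#' @export
compute_kme <- function(expr, eigengenes) {
  if (is.list(eigengenes)) eigengenes <- eigengenes$eigengenes
  suppressWarnings(stats::cor(t(expr), eigengenes,
                              use = "pairwise.complete.obs"))
}

#' Hub genes of a module
#'
#' Genes with own-module kME above `threshold`, ranked by decreasing kME
#' (ties broken lexicographically by feature id) and truncated to `cap` —
#' i.e. the smaller of the two candidate sets.
#'
#' @param kme kME matrix from [compute_kme()].
#' @param partition Named feature -> module vector.
#' @param module Module label.
#' @param threshold kME threshold.
#' @param cap Maximum number of hubs returned.
#' @return Character vector of hub gene ids, ordered.
#' @export
hub_genes <- function(kme, partition, module, threshold = 0.6, cap = 200L) {
  if (!module %in% colnames(kme)) stop("unknown module: ", module,
                                       call. = FALSE)
  genes <- names(partition)[partition == module]
  v <- kme[genes, module]
  v <- v[!is.na(v) & v > threshold]
  ord <- order(-v, names(v))
  utils::head(names(v)[ord], cap)
}

#' kME-based refinement of a module partition
#'
#' Refinement after the static cut, playing the role of the partitioning
#' stage of hybrid tree cutting: (1) an assigned gene whose own-module kME
#' falls below `prune_kme` is demoted to grey (loosely attached genes swept
#' up by the static cut do not belong in the module core); (2) a gene whose
#' maximum kME module differs from its assigned module and exceeds the
#' own-module kME by more than `gap` is reassigned there. Grey genes are
#' never recruited, and modules falling below `min_module_size` after
#' pruning dissolve to grey.
#'
#' @param expr Feature x sample matrix.
#' @param partition Named feature -> module vector.
#' @param gap Required kME advantage for reassignment.
#' @param prune_kme Own-module kME below which a gene is demoted to grey;
#'   `NA` disables pruning.
#' @param min_module_size Modules smaller than this after pruning dissolve.
#' @return Updated partition vector.
#' @export
reassign_by_kme <- function(expr, partition, gap = 0.1, prune_kme = 0.5,
                            min_module_size = 1L) {
  eg <- module_eigengenes(expr, partition)
  kme <- compute_kme(expr, eg)
  part <- partition
  assigned <- names(part)[part != "grey"]
  for (g in assigned) {
    own <- kme[g, part[[g]]]
    best <- which.max(kme[g, ])
    if (colnames(kme)[best] != part[[g]] &&
        !is.na(own) && kme[g, best] > own + gap) {
      part[[g]] <- colnames(kme)[best]
      own <- kme[g, part[[g]]]
    }
    if (!is.na(prune_kme) && (is.na(own) || own < prune_kme))
      part[[g]] <- "grey"
  }
  sizes <- table(part[part != "grey"])
  small <- names(sizes)[sizes < min_module_size]
  part[part %in% small] <- "grey"
  part
}

#' Full module detection: adjacency, TOM, cut, refine, merge
#'
#' Convenience wrapper chaining [signed_adjacency()],
#' [topological_overlap()], [cluster_and_cut()], [reassign_by_kme()] and
#' [merge_close_modules()].
#'
#' @param expr Feature x sample matrix.
#' @param beta Soft power.
#' @param min_module_size Minimum module size.
#' @param merge_height Eigengene merge height.
#' @param prune_kme kME pruning threshold for [reassign_by_kme()].
#' @return List with `partition`, `eigengenes` (see
#'   [module_eigengenes()]), `kme`, and `tom`.
#' @export
detect_modules <- function(expr, beta = 12, min_module_size = 40L,
                           merge_height = 0.25, prune_kme = 0.5) {
  adj <- signed_adjacency(expr, beta)
  tom <- topological_overlap(adj)
  part <- cluster_and_cut(tom, min_module_size)
  if (length(setdiff(unique(part), "grey"))) {
    part <- reassign_by_kme(expr, part, prune_kme = prune_kme,
                            min_module_size = min_module_size)
    if (length(setdiff(unique(part), "grey")) > 1L) {
      merged <- merge_close_modules(expr, part, merge_height)
      part <- merged$partition
    }
  }
  eg <- if (length(setdiff(unique(part), "grey")))
    module_eigengenes(expr, part) else NULL
  list(partition = part,
       eigengenes = eg,
       kme = if (!is.null(eg)) compute_kme(expr, eg) else NULL,
       tom = tom)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
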