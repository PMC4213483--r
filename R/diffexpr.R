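#' Paired differentiation differential expression
#'
#' Forms progenitor-neuron pairs via `pair_id` (same clone, same
#' differentiation experiment; depolarized neurons never enter pairs), and
#' tests the per-feature mean of paired differences (neuron - progenitor)
#' with an empirical-Bayes moderated one-sample t-test: gene-wise variances
#' are shrunk toward a common prior estimated by moment-matching a scaled
#' chi-squared model, and the moderated t is referenced to the augmented
#' degrees of freedom. Set `moderated = FALSE` for the plain one-sample t.
#'
#' @param expr Feature x sample matrix (log2 scale).
#' @param design Design table with `sample_id`, `cell_type`, `depolarized`,
#'   `genotype`, `pair_id`.
#' @param group `"control"` or `"TS"`.
#' @param de_alpha Per-test significance level.
#' @param moderated Use empirical-Bayes variance moderation.
#' @return A data.frame: `feature`, `group`, `logFC`, `t`, `p`,
#'   `significant`, with attribute `"n_pairs"`.
#' @export
fit_paired_differentiation <- function(expr, design, group,
                                       de_alpha = 0.05, moderated = TRUE) {
  D <- paired_differences(expr, design, group)
  n <- ncol(D)
  if (moderated) {
    fit <- limma::eBayes(limma::lmFit(D, matrix(1, n, 1L)))
    out <- data.frame(feature = rownames(D), group = group,
                      logFC = fit$coefficients[, 1L],
                      t = fit$t[, 1L], p = fit$p.value[, 1L],
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    m <- rowMeans(D)
    s <- apply(D, 1L, stats::sd)
    tt <- m / (s / sqrt(n))
    out <- data.frame(feature = rownames(D), group = group,
                      logFC = m, t = tt,
                      p = 2 * stats::pt(-abs(tt), n - 1L),
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  zero_var <- apply(D, 1L, function(x) stats::sd(x) == 0) & n > 1L
  # a constant difference vector is still informative (logFC), but its
  # plain-t is undefined; moderated-t remains defined via the prior
  if (!moderated) out$p[zero_var] <- NA_real_
  out$significant <- !is.na(out$p) & out$p < de_alpha
  attr(out, "n_pairs") <- n
  out
}

paired_differences <- function(expr, design, group = NULL) {
  d <- design
  if (!is.null(group)) d <- d[d$genotype == group, , drop = FALSE]
  d <- d[!is.na(d$pair_id) & d$depolarized == 0, , drop = FALSE]
  prog <- d[d$cell_type == "progenitor", ]
  neur <- d[d$cell_type == "neuron", ]
  pairs <- intersect(prog$pair_id, neur$pair_id)
  n_unpaired <- nrow(d) - 2L * length(pairs)
  if (n_unpaired > 0L)
    stage_log("paired_differences", group = if (is.null(group)) "all" else group,
              excluded_unpaired = n_unpaired)
  if (length(pairs) < 2L)
    stop("fewer than 2 complete progenitor-neuron pairs",
         if (!is.null(group)) paste0(" in group '", group, "'"),
         call. = FALSE)
  ip <- prog$sample_id[match(pairs, prog$pair_id)]
  im <- neur$sample_id[match(pairs, neur$pair_id)]
  D <- expr[, im, drop = FALSE] - expr[, ip, drop = FALSE]
  colnames(D) <- pairs
  D
}

#' Factorial interaction between differentiation and genotype
#'
#' Tests whether the mean differentiation change differs between control
#' and TS pairs: a two-sample moderated t on the per-pair paired
#' differences with genotype as the factor (the paired-difference
#' equivalent of the cell-type x genotype interaction in a factorial
#' model). Features with zero residual variance get `NA`.
#'
#' @inheritParams fit_paired_differentiation
#' @return A data.frame: `feature`, `delta` (TS minus control mean
#'   differentiation change), `t`, `p`.
#' @export
fit_interaction <- function(expr, design, moderated = TRUE) {
  groups <- intersect(c("control", "TS"), unique(design$genotype))
  if (length(groups) < 2L)
    stop("both control and TS pairs are required", call. = FALSE)
  Dc <- paired_differences(expr, design, "control")
  Dt <- paired_differences(expr, design, "TS")
  D <- cbind(Dc, Dt)
  grp <- rep(c(0, 1), c(ncol(Dc), ncol(Dt)))
  X <- cbind(intercept = 1, ts = grp)
  if (moderated) {
    fit <- limma::eBayes(limma::lmFit(D, X))
    out <- data.frame(feature = rownames(D),
                      delta = fit$coefficients[, "ts"],
                      t = fit$t[, "ts"], p = fit$p.value[, "ts"],
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    fit <- limma::lmFit(D, X)
    df <- ncol(D) - 2L
    se <- fit$stdev.unscaled[, "ts"] * fit$sigma
    tt <- fit$coefficients[, "ts"] / se
    out <- data.frame(feature = rownames(D),
                      delta = fit$coefficients[, "ts"], t = tt,
                      p = 2 * stats::pt(-abs(tt), df),
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  resid_var <- vapply(seq_len(nrow(D)), function(i) {
    stats::var(D[i, grp == 0]) + stats::var(D[i, grp == 1])
  }, numeric(1))
  out$p[resid_var == 0] <- NA_real_
  out
}

#' Four-category differentiation-trajectory classification
#'
#' A feature gets a non-`none` category only when two criteria hold:
#' (1) it is significantly differentially expressed upon differentiation in
#' exactly one of the two groups, and (2) the differentiation x genotype
#' interaction is significant. The direction comes from the significant
#' group's log fold change, giving the four categories `control_up`,
#' `control_down`, `ts_up`, `ts_down`.
#'
#' @param control_de,ts_de Per-group results of
#'   [fit_paired_differentiation()].
#' @param interaction Result of [fit_interaction()].
#' @param de_alpha Significance level for all three tests.
#' @return A data.frame: `feature`, `category`, `p_control`, `p_ts`,
#'   `p_interaction`.
#' @export
classify_trajectories <- function(control_de, ts_de, interaction,
                                  de_alpha = 0.05) {
  feats <- control_de$feature
  if (!identical(sort(feats), sort(ts_de$feature)) ||
      !identical(sort(feats), sort(interaction$feature)))
    stop("the three inputs must cover the same features", call. = FALSE)
  ts_de <- ts_de[match(feats, ts_de$feature), ]
  interaction <- interaction[match(feats, interaction$feature), ]
  sig_c <- !is.na(control_de$p) & control_de$p < de_alpha
  sig_t <- !is.na(ts_de$p) & ts_de$p < de_alpha
  sig_i <- !is.na(interaction$p) & interaction$p < de_alpha
  one_group <- xor(sig_c, sig_t)
  category <- rep("none", length(feats))
  sel <- one_group & sig_i
  category[sel & sig_c] <- ifelse(control_de$logFC[sel & sig_c] >= 0,
                                  "control_up", "control_down")
  category[sel & sig_t] <- ifelse(ts_de$logFC[sel & sig_t] >= 0,
                                  "ts_up", "ts_down")
  data.frame(feature = feats, category = category,
             p_control = control_de$p, p_ts = ts_de$p,
             p_interaction = interaction$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' End-to-end trajectory analysis
#'
#' Convenience wrapper running both per-group paired tests, the interaction
#' test, and the classification.
#'
#' @inheritParams fit_paired_differentiation
#' @return List with `control`, `ts`, `interaction`, `classification`.
#' @export
trajectory_analysis <- function(expr, design, de_alpha = 0.05,
                                moderated = TRUE) {
  ctrl <- fit_paired_differentiation(expr, design, "control", de_alpha,
                                     moderated)
  ts <- fit_paired_differentiation(expr, design, "TS", de_alpha, moderated)
  inter <- fit_interaction(expr, design, moderated)
  cls <- classify_trajectories(ctrl, ts, inter, de_alpha)
  list(control = ctrl, ts = ts, interaction = inter, classification = cls)
}
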