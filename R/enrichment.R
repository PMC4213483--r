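#' One-sided Fisher over-representation of a gene set
#'
#' Builds the 2x2 table of query x annotation membership over a background
#' universe (query and annotation are first intersected with the
#' background, logged when that drops genes) and computes the one-sided
#' (greater) hypergeometric tail P. The odds ratio is the sample odds ratio
#' `(a d) / (b c)`, with `Inf` as sentinel when `b c = 0` and the table is
#' enriched.
#'
#' @param query Character vector of query genes (e.g. a module).
#' @param annotation Character vector of annotation-set genes.
#' @param background Character vector: the gene universe (e.g. all
#'   expressed genes).
#' @return A one-row data.frame: `overlap`, `query_size`,
#'   `annotation_size`, `background_size`, `odds_ratio`, `p`.
#' @export
fisher_overrepresentation <- function(query, annotation, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  q0 <- unique(query); a0 <- unique(annotation)
  query <- intersect(q0, background)
  annotation <- intersect(a0, background)
  if (length(query) < length(q0) || length(annotation) < length(a0))
    stage_log("fisher_overrepresentation",
              dropped_query = length(q0) - length(query),
              dropped_annotation = length(a0) - length(annotation))
  a <- length(intersect(query, annotation))
  overrep_test(a, length(query), length(annotation), length(background))
}

#' One-sided over-representation test from 2x2 counts
#'
#' The count-level core of [fisher_overrepresentation()]: given the overlap
#' and the three set sizes, returns the sample odds ratio and the one-sided
#' (greater) hypergeometric tail P including the observed table.
#'
#' @param overlap Genes in both query and annotation.
#' @param query_size,annotation_size,background_size Set sizes (annotation
#'   already restricted to the background). All four arguments vectorize.
#' @return A data.frame (one row per input table): `overlap`,
#'   `query_size`, `annotation_size`, `background_size`, `odds_ratio`,
#'   `p`.
#' @export
overrep_test <- function(overlap, query_size, annotation_size,
                         background_size) {
  a <- overlap
  b <- query_size - a
  c_ <- annotation_size - a
  d <- background_size - query_size - c_
  if (any(pmin(a, b, c_, d) < 0))
    stop("inconsistent 2x2 counts", call. = FALSE)
  or <- ifelse(b * c_ == 0,
               ifelse(a * d == 0, NaN, Inf),
               (a * d) / (b * c_))
  p <- stats::phyper(a - 1, annotation_size,
                     background_size - annotation_size,
                     query_size, lower.tail = FALSE)
  data.frame(overlap = a, query_size = query_size,
             annotation_size = annotation_size,
             background_size = background_size,
             odds_ratio = or, p = p, stringsAsFactors = FALSE)
}

#' Fisher over-representation against a whole gene-set collection
#'
#' Applies [fisher_overrepresentation()] to each set of a GMT-style
#' collection and adds a Benjamini-Hochberg q value across the sets.
#'
#' @param query Character vector of query genes.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Gene universe.
#' @return A data.frame with one row per set, ordered as `sets`.
#' @export
fisher_collection <- function(query, sets, background) {
  rows <- lapply(names(sets), function(nm) {
    r <- fisher_overrepresentation(query, sets[[nm]], background)
    cbind(set = nm, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Permutation annotation enrichment with over-representation Z scores
#'
#' For each annotation set, the observed overlap with the query is compared
#' against `n_perm` random query-sized draws (without replacement) from the
#' background: `Z = (obs - mean_null) / sd_null` and the empirical
#' `P = (1 + #{null >= obs}) / (1 + n_perm)`. The background should be the
#' full list of expressed genes.
#'
#' @param query Character vector of query genes.
#' @param sets Named list of annotation sets.
#' @param background Gene universe.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer RNG seed.
#' @return A data.frame: `set`, `overlap`, `null_mean`, `null_sd`, `z`,
#'   `p`.
#' @export
permutation_annotation_enrichment <- function(query, sets, background,
                                              n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  background <- unique(background)
  query <- intersect(unique(query), background)
  set.seed(seed)
  sets_bg <- lapply(sets, function(s) intersect(unique(s), background))
  flags <- vapply(sets_bg, function(s) background %in% s,
                  logical(length(background)))
  obs <- vapply(sets_bg, function(s) length(intersect(query, s)),
                integer(1))
  nq <- length(query)
  null_counts <- matrix(0L, n_perm, length(sets_bg))
  for (i in seq_len(n_perm)) {
    draw <- sample.int(length(background), nq)
    null_counts[i, ] <- colSums(flags[draw, , drop = FALSE])
  }
  mu <- colMeans(null_counts)
  sdev <- apply(null_counts, 2L, stats::sd)
  z <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  p <- vapply(seq_along(obs), function(j)
    (1 + sum(null_counts[, j] >= obs[j])) / (1 + n_perm), numeric(1))
  data.frame(set = names(sets_bg), overlap = obs, null_mean = mu,
             null_sd = sdev, z = z, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric validation of predicted targets against ChIP data
#'
#' Upper cumulative hypergeometric probability of observing at least the
#' realized overlap when drawing `|predicted|` genes from a population
#' containing `|chip|` ChIP-supported targets. The population size should
#' be the total number of expressed genes.
#'
#' @param predicted Character vector of predicted target genes.
#' @param chip_targets Character vector of ChIP-supported targets.
#' @param population_size Size of the gene population.
#' @return A one-row data.frame: `overlap`, `n_predicted`, `n_chip`,
#'   `population_size`, `p`.
#' @export
chip_validation <- function(predicted, chip_targets, population_size) {
  predicted <- unique(predicted)
  chip_targets <- unique(chip_targets)
  k <- length(intersect(predicted, chip_targets))
  if (length(predicted) > population_size ||
      length(chip_targets) > population_size)
    stop("gene lists exceed the stated population size", call. = FALSE)
  p <- stats::phyper(k - 1L, length(chip_targets),
                     population_size - length(chip_targets),
                     length(predicted), lower.tail = FALSE)
  data.frame(overlap = k, n_predicted = length(predicted),
             n_chip = length(chip_targets),
             population_size = population_size, p = p,
             stringsAsFactors = FALSE)
}
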