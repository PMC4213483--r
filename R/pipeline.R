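write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + offset
}

#' Run the full synthetic-study pipeline
#'
#' Composes every stage end to end on synthetic data with known ground
#' truth: simulate -> preprocess (log2 + quantile normalization, detection
#' filter, outlier flagging) -> signed network and module detection ->
#' module-trait association -> module preservation against an independent
#' replicate -> paired/factorial differential expression and trajectory
#' classification -> gene-set over-representation -> promoter motif
#' enrichment with ChIP validation. All randomness derives from
#' `config$rng_seed`; with a fixed seed the run is bit-reproducible and all
#' written outputs are byte-identical.
#'
#' @param config A [coex_config()].
#' @param out_dir Output directory for TSV reports, or `NULL` to skip
#'   writing.
#' @param n_background Background gene count for the simulated study.
#' @param n_perm_enrichment Overrides `config$n_perm_enrichment` (the
#'   default 10,000 is used for final runs; smaller values speed up
#'   exploratory runs).
#' @return A list with each stage's main result (`truth`, `expr`,
#'   `partition`, `eigengenes`, `kme`, `hubs`, `associations`,
#'   `preservation`, `trajectory`, `enrichment`, `tfbs`, `chip`, `ari`).
#' @export
run_pipeline <- function(config = coex_config(), out_dir = NULL,
                         n_background = 2300L,
                         n_perm_enrichment = config$n_perm_enrichment) {
  seed <- config$rng_seed
  stage_log("run_pipeline", seed = seed)

  # --- simulate -----------------------------------------------------------
  design <- default_design()
  sim <- generate_expression(design,
                             modules = default_module_specs(),
                             n_background = n_background,
                             trajectory = trajectory_spec(),
                             n_low_detection = 100L,
                             seed = derive_seed(seed, 1L))

  # --- preprocess ---------------------------------------------------------
  raw <- sim$raw
  attr(raw, "detectionP") <- sim$detectionP
  norm <- log2_quantile_normalize(raw)
  expr <- filter_expressed(norm)
  outliers <- detect_outlier_samples(expr)

  # --- network ------------------------------------------------------------
  net_genes <- rownames(expr)
  net <- detect_modules(expr, beta = config$soft_power,
                        min_module_size = config$min_module_size,
                        merge_height = config$merge_height)
  partition <- net$partition
  eigengenes <- net$eigengenes
  kme <- net$kme
  hubs <- lapply(colnames(eigengenes$eigengenes), function(m)
    hub_genes(kme, partition, m, config$kme_hub_threshold, config$hub_cap))
  names(hubs) <- colnames(eigengenes$eigengenes)

  truth_mod <- sim$truth$module[names(partition)]
  truth_mod[is.na(truth_mod)] <- "other"
  ari <- adjusted_rand_index(truth_mod, partition)

  # --- traits -------------------------------------------------------------
  traits <- sim$truth$traits[colnames(expr), , drop = FALSE]
  assoc <- associate_modules(eigengenes, traits, config$fdr_alpha)

  # --- preservation (independent replicate of the same model) -------------
  sim2 <- generate_expression(design,
                              modules = default_module_specs(),
                              n_background = n_background,
                              seed = derive_seed(seed, 2L))
  pres <- module_preservation(expr, sim2$log2, partition,
                              beta = config$soft_power,
                              n_perm = config$n_perm_preservation,
                              seed = derive_seed(seed, 3L))

  # --- differential expression / trajectories -----------------------------
  de <- trajectory_analysis(expr, design, config$de_alpha)

  # --- gene-set over-representation ---------------------------------------
  ts_module <- best_matching_module(partition, sim$truth$module, "mod4")
  module_genes <- names(partition)[partition == ts_module]
  bg_genes <- setdiff(net_genes, module_genes)
  gs <- generate_genesets_and_chip(module_genes, bg_genes,
                                   set_size = 40L, overlap_fraction = 0.5,
                                   seed = derive_seed(seed, 4L))
  fish <- fisher_collection(module_genes,
                            list(disease = gs$disease_set), net_genes)
  perm_enr <- permutation_annotation_enrichment(
    module_genes, list(disease = gs$disease_set), net_genes,
    n_perm = n_perm_enrichment, seed = derive_seed(seed, 5L))

  # --- TFBS ----------------------------------------------------------------
  motif <- new_pwm("SYN_MOTIF", synthetic_motif_counts())
  planted <- names(partition)[truth_mod == "mod4"]
  proms <- generate_promoters(net_genes, motif, planted,
                              occurrences = 1L,
                              length = config$promoter_length,
                              seed = derive_seed(seed, 6L))
  bgpools <- generate_backgrounds(n_seq = 300L,
                                  length = config$promoter_length,
                                  seed = derive_seed(seed, 7L))
  tf <- empirical_motif_enrichment(proms[module_genes], motif, bgpools,
                                   n_draws = config$n_bg_draws,
                                   seed = derive_seed(seed, 8L))
  pred <- predicted_targets(proms[module_genes], motif)
  chip <- generate_genesets_and_chip(module_genes, bg_genes,
                                     planted_genes = planted,
                                     decoy_count = 50L,
                                     seed = derive_seed(seed, 9L))
  chipval <- chip_validation(pred, chip$chip_targets, length(net_genes))

  res <- list(config = config, truth = sim$truth, expr = expr,
              outliers = outliers, partition = partition,
              eigengenes = eigengenes, kme = kme, hubs = hubs, ari = ari,
              associations = assoc, preservation = pres, trajectory = de,
              enrichment = list(fisher = fish, permutation = perm_enr),
              tfbs = tf, predicted_targets = pred, chip = chipval)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

best_matching_module <- function(partition, truth_module, truth_id) {
  genes <- names(truth_module)[truth_module == truth_id]
  labs <- partition[intersect(genes, names(partition))]
  labs <- labs[labs != "grey"]
  if (!length(labs)) return("grey")
  names(sort(table(labs), decreasing = TRUE))[1L]
}

synthetic_motif_counts <- function() {
  # a well-determined 8-bp synthetic motif (consensus TGGAAACA)
  matrix(c(1, 1, 1, 17,   # T
           1, 1, 17, 1,   # G
           1, 1, 17, 1,   # G
           17, 1, 1, 1,   # A
           17, 1, 1, 1,   # A
           17, 1, 1, 1,   # A
           1, 17, 1, 1,   # C
           17, 1, 1, 1),  # A
         nrow = 4L)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  write_config(res$config, f("config.txt"))
  write_tsv(data.frame(feature = names(res$partition),
                       module = unname(res$partition),
                       own_kme = vapply(names(res$partition), function(g)
                         if (res$partition[[g]] == "grey") NA_real_
                         else res$kme[g, res$partition[[g]]], numeric(1))),
            f("partition.tsv"))
  eg <- res$eigengenes$eigengenes
  write_tsv(data.frame(sample_id = rownames(eg), eg,
                       check.names = FALSE), f("eigengenes.tsv"))
  write_tsv(res$associations, f("module_trait_associations.tsv"))
  write_tsv(res$preservation, f("preservation.tsv"))
  write_tsv(res$trajectory$classification, f("trajectory_classification.tsv"))
  write_tsv(res$enrichment$fisher, f("enrichment_fisher.tsv"))
  write_tsv(res$enrichment$permutation, f("enrichment_permutation.tsv"))
  write_tsv(res$tfbs, f("tfbs_enrichment.tsv"))
  writeLines(res$predicted_targets, f("predicted_targets.txt"))
  write_tsv(res$chip, f("chip_validation.tsv"))
  write_tsv(res$outliers, f("outlier_samples.tsv"))
  writeLines(c(paste("rng_seed:", res$config$rng_seed),
               paste("n_features:", nrow(res$expr)),
               paste("n_samples:", ncol(res$expr)),
               paste("n_modules:",
                     length(setdiff(unique(res$partition), "grey"))),
               paste("module_recovery_ari:",
                     format(res$ari, digits = 15))),
             f("run_report.txt"))
  invisible(out_dir)
}
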