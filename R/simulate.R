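#' Default study design: progenitors, resting and depolarized neurons
#'
#' Builds a sample metadata table emulating a case/control iPSC
#' differentiation study: 12 neural progenitor samples, 15 resting neuron
#' samples and 9 KCl-depolarized neuron samples, derived from control
#' subjects (including one embryonic stem cell line coded as an additional
#' control) and one Timothy-syndrome (TS) patient with multiple clones.
#' `pair_id` links each progenitor sample to the neuron sample(s)
#' differentiated from the same clone in the same experiment; depolarized
#' neurons share the clone but are never members of a differentiation pair.
#'
#' @return A data.frame with columns `sample_id`, `cell_type`
#'   (progenitor/neuron), `depolarized` (0/1), `genotype` (control/TS),
#'   `subject_id`, `clone_id`, `pair_id` (NA when unpaired).
#' @export
default_design <- function() {
  # differentiation experiments: clone x experiment defines a pair
  prog <- data.frame(
    sample_id = c("P_A1", "P_A2", "P_B1", "P_B2", "P_H9",
                  "P_A1b", "P_B1b",
                  "P_T1", "P_T2", "P_T3", "P_T1b", "P_T2b"),
    cell_type = "progenitor", depolarized = 0L,
    genotype = c(rep("control", 7L), rep("TS", 5L)),
    subject_id = c("ctrlA", "ctrlA", "ctrlB", "ctrlB", "H9",
                   "ctrlA", "ctrlB", rep("TS1", 5L)),
    clone_id = c("A1", "A2", "B1", "B2", "H9", "A1", "B1",
                 "T1", "T2", "T3", "T1", "T2"),
    pair_id = c("A1.e1", "A2.e1", "B1.e1", "B2.e1", "H9.e1",
                "A1.e2", "B1.e2",
                "T1.e1", "T2.e1", "T3.e1", "T1.e2", "T2.e2"),
    stringsAsFactors = FALSE)
  neur <- data.frame(
    sample_id = c("N_A1", "N_A2", "N_B1", "N_B2", "N_H9",
                  "N_A1b", "N_B1b", "N_A2b", "N_B2b",
                  "N_T1", "N_T2", "N_T3", "N_T1b", "N_T2b", "N_T3b"),
    cell_type = "neuron", depolarized = 0L,
    genotype = c(rep("control", 9L), rep("TS", 6L)),
    subject_id = c("ctrlA", "ctrlA", "ctrlB", "ctrlB", "H9",
                   "ctrlA", "ctrlB", "ctrlA", "ctrlB", rep("TS1", 6L)),
    clone_id = c("A1", "A2", "B1", "B2", "H9", "A1", "B1", "A2", "B2",
                 "T1", "T2", "T3", "T1", "T2", "T3"),
    pair_id = c("A1.e1", "A2.e1", "B1.e1", "B2.e1", "H9.e1",
                "A1.e2", "B1.e2", NA, NA,
                "T1.e1", "T2.e1", "T3.e1", "T1.e2", "T2.e2", NA),
    stringsAsFactors = FALSE)
  dep <- data.frame(
    sample_id = c("D_A1", "D_A2", "D_B1", "D_B2", "D_H9",
                  "D_T1", "D_T2", "D_T3", "D_T1b"),
    cell_type = "neuron", depolarized = 1L,
    genotype = c(rep("control", 5L), rep("TS", 4L)),
    subject_id = c("ctrlA", "ctrlA", "ctrlB", "ctrlB", "H9",
                   rep("TS1", 4L)),
    clone_id = c("A1", "A2", "B1", "B2", "H9", "T1", "T2", "T3", "T1"),
    pair_id = NA_character_,
    stringsAsFactors = FALSE)
  rbind(prog, neur, dep)
}

#' Trait design matrix from a sample design table
#'
#' Codes the three binary biological traits: `differentiation` (1 for
#' neurons, resting or depolarized), `depolarization` (1 for KCl-treated
#' samples) and `TSmutation` (1 for TS-genotype samples).
#'
#' @param design Design table as from [default_design()].
#' @return Numeric sample x trait matrix with sample_id rownames.
#' @export
trait_table <- function(design) {
  m <- cbind(differentiation = as.numeric(design$cell_type == "neuron"),
             depolarization = as.numeric(design$depolarized == 1),
             TSmutation = as.numeric(design$genotype == "TS"))
  rownames(m) <- design$sample_id
  m
}

#' Specification of one planted co-expression module
#'
#' @param module_id Unique module identifier string.
#' @param size Number of genes (>= 2).
#' @param trait_weights Named numeric vector of weights for
#'   `differentiation`, `depolarization`, `TSmutation` (missing traits
#'   default to 0): the module's latent factor is their linear combination
#'   plus Gaussian noise.
#' @param loading_range Length-2 range (low, high) in (0, 1] for per-gene
#'   loadings on the latent factor.
#' @param noise_sd Per-gene residual standard deviation (log2 units).
#' @return A `module_spec` list.
#' @export
module_spec <- function(module_id, size,
                        trait_weights = c(differentiation = 0,
                                          depolarization = 0,
                                          TSmutation = 0),
                        loading_range = c(0.6, 0.95),
                        noise_sd = 0.25) {
  if (size < 2L) stop("module size must be >= 2", call. = FALSE)
  w <- c(differentiation = 0, depolarization = 0, TSmutation = 0)
  w[names(trait_weights)] <- trait_weights
  if (any(loading_range <= 0) || any(loading_range > 1) ||
      loading_range[1L] > loading_range[2L])
    stop("loading_range must satisfy 0 < low <= high <= 1", call. = FALSE)
  structure(list(module_id = module_id, size = as.integer(size),
                 trait_weights = w, loading_range = loading_range,
                 noise_sd = noise_sd),
            class = "module_spec")
}

#' Default five-module scenario
#'
#' Five planted modules, sizes 50-200, loadings 0.6-0.95: differentiation-up
#' and -down modules, a depolarization module, a TS-mutation module, and one
#' trait-null module with purely latent co-expression.
#'
#' @param noise_sd Per-gene residual SD passed to every module.
#' @return List of [module_spec()] objects.
#' @export
default_module_specs <- function(noise_sd = 0.25) {
  list(
    module_spec("mod1", 200L, c(differentiation = 0.8), noise_sd = noise_sd),
    module_spec("mod2", 150L, c(differentiation = -0.8), noise_sd = noise_sd),
    module_spec("mod3", 120L, c(depolarization = 0.8), noise_sd = noise_sd),
    module_spec("mod4", 100L, c(TSmutation = 0.7), noise_sd = noise_sd),
    module_spec("mod5", 50L, noise_sd = noise_sd)
  )
}

#' Specification of planted differentiation-trajectory genes
#'
#' Genes in the four trajectory categories get genotype-specific
#' differentiation effects: e.g. `control_up` genes gain `effect` log2 units
#' upon differentiation in control samples only. `none` plants pure-noise
#' genes used for type-I-error calibration of the paired and interaction
#' tests.
#'
#' @param n_per_category Named integer vector over
#'   `control_up`, `control_down`, `ts_up`, `ts_down`, `none`.
#' @param effect Differentiation effect size (log2 units).
#' @param noise_sd Residual SD for trajectory genes.
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(n_per_category = c(control_up = 50L,
                                               control_down = 50L,
                                               ts_up = 50L, ts_down = 50L,
                                               none = 0L),
                            effect = 1.0, noise_sd = 0.3) {
  cats <- c("control_up", "control_down", "ts_up", "ts_down", "none")
  n <- stats::setNames(integer(5L), cats)
  n[names(n_per_category)] <- as.integer(n_per_category)
  structure(list(n_per_category = n, effect = effect, noise_sd = noise_sd),
            class = "trajectory_spec")
}

#' Generate a synthetic expression study with known ground truth
#'
#' The generative model is a latent-factor Gaussian model: module `m` has a
#' latent factor `f_m(s) = sum_t w_mt x_t(s) + e_s`, `e ~ N(0, 0.3)` across
#' samples `s` with binary trait design `x`; gene `g` of module `m` is
#' `lambda_g f_m(s) + N(0, sigma)` on the log2 scale, on top of a per-gene
#' baseline. Background genes are iid Gaussian noise. Trajectory-category
#' genes receive genotype-specific differentiation shifts. Detection-P
#' values are < 0.05 in at least half the samples for every expressed
#' feature, while `n_low_detection` planted features fail that filter by
#' construction.
#'
#' @param design Sample design table ([default_design()]).
#' @param modules List of [module_spec()] objects.
#' @param n_background Number of iid-noise background genes.
#' @param trajectory Optional [trajectory_spec()].
#' @param n_low_detection Number of planted low-detection features.
#' @param latent_sd SD of the latent-factor noise term (default 0.3).
#' @param baseline_range Range of per-gene baseline log2 intensity.
#' @param seed Integer RNG seed.
#' @return A list with `log2` (feature x sample log2 matrix), `raw`
#'   (`2^log2` intensities), `detectionP`, and `truth` (list: `module` named
#'   gene -> module-id vector with "background" for noise genes, `loading`,
#'   `factors` sample x module latent factors, `trajectory` named gene ->
#'   category vector, `low_detection` feature ids, `traits` the trait
#'   matrix).
#' @export
generate_expression <- function(design = default_design(),
                                modules = default_module_specs(),
                                n_background = 2300L,
                                trajectory = NULL,
                                n_low_detection = 0L,
                                latent_sd = 0.3,
                                baseline_range = c(7, 11),
                                seed = 1L) {
  if (!nrow(design)) stop("empty design", call. = FALSE)
  ids <- vapply(modules, `[[`, character(1), "module_id")
  if (anyDuplicated(ids))
    stop("duplicate module ids: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "), call. = FALSE)
  set.seed(seed)
  ns <- nrow(design)
  traits <- trait_table(design)
  ctrl <- design$genotype == "control"
  diff_t <- traits[, "differentiation"]

  blocks <- list(); gene_mod <- character(0); load_vec <- numeric(0)
  factors <- matrix(0, ns, length(modules),
                    dimnames = list(design$sample_id, ids))
  for (k in seq_along(modules)) {
    m <- modules[[k]]
    f <- as.numeric(traits %*% m$trait_weights) +
      stats::rnorm(ns, 0, latent_sd)
    factors[, k] <- f
    lam <- stats::runif(m$size, m$loading_range[1L], m$loading_range[2L])
    sig <- outer(lam, f) +
      matrix(stats::rnorm(m$size * ns, 0, m$noise_sd), m$size, ns)
    rownames(sig) <- sprintf("%s_g%03d", m$module_id, seq_len(m$size))
    blocks[[length(blocks) + 1L]] <- sig
    gene_mod <- c(gene_mod,
                  stats::setNames(rep(m$module_id, m$size), rownames(sig)))
    load_vec <- c(load_vec, stats::setNames(lam, rownames(sig)))
  }

  traj_cat <- character(0)
  if (!is.null(trajectory)) {
    stopifnot(inherits(trajectory, "trajectory_spec"))
    for (cat in names(trajectory$n_per_category)) {
      nc <- trajectory$n_per_category[[cat]]
      if (nc == 0L) next
      shift <- switch(cat,
        control_up   = trajectory$effect * diff_t * ctrl,
        control_down = -trajectory$effect * diff_t * ctrl,
        ts_up        = trajectory$effect * diff_t * !ctrl,
        ts_down      = -trajectory$effect * diff_t * !ctrl,
        none         = rep(0, ns))
      sig <- matrix(rep(shift, each = nc), nc, ns) +
        matrix(stats::rnorm(nc * ns, 0, trajectory$noise_sd), nc, ns)
      rownames(sig) <- sprintf("traj_%s_g%03d", cat, seq_len(nc))
      blocks[[length(blocks) + 1L]] <- sig
      traj_cat <- c(traj_cat, stats::setNames(rep(cat, nc), rownames(sig)))
    }
  }

  if (n_background > 0L) {
    bg <- matrix(stats::rnorm(n_background * ns, 0, 0.3), n_background, ns)
    rownames(bg) <- sprintf("bg_g%04d", seq_len(n_background))
    blocks[[length(blocks) + 1L]] <- bg
    gene_mod <- c(gene_mod, stats::setNames(rep("background", n_background),
                                            rownames(bg)))
  }

  lowdet_ids <- character(0)
  if (n_low_detection > 0L) {
    ld <- matrix(stats::rnorm(n_low_detection * ns, 0, 0.3),
                 n_low_detection, ns)
    rownames(ld) <- sprintf("lowdet_g%04d", seq_len(n_low_detection))
    blocks[[length(blocks) + 1L]] <- ld
    lowdet_ids <- rownames(ld)
  }

  signal <- do.call(rbind, blocks)
  nf <- nrow(signal)
  baseline <- stats::runif(nf, baseline_range[1L], baseline_range[2L])
  log2_mat <- signal + baseline
  colnames(log2_mat) <- design$sample_id

  # detection P: expressed features pass "< 0.05 in >= half" with margin,
  # planted low-detection features miss the threshold by exactly one sample
  need <- ceiling(ns / 2)
  detP <- matrix(stats::runif(nf * ns, 0.1, 1), nf, ns,
                 dimnames = dimnames(log2_mat))
  for (i in seq_len(nf)) {
    if (rownames(log2_mat)[i] %in% lowdet_ids) {
      pass <- sample.int(ns, need - 1L)
    } else {
      pass <- sample.int(ns, min(ns, ceiling(0.75 * ns)))
    }
    detP[i, pass] <- stats::runif(length(pass), 0, 0.04)
  }

  list(log2 = log2_mat,
       raw = 2^log2_mat,
       detectionP = detP,
       truth = list(module = gene_mod,
                    loading = load_vec,
                    factors = factors,
                    trajectory = traj_cat,
                    low_detection = lowdet_ids,
                    traits = traits,
                    design = design))
}

random_dna <- function(n, len, freqs) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i)
    paste(sample(bases, len, replace = TRUE, prob = freqs), collapse = ""),
    character(1))
}

sample_motif_instance <- function(pwm) {
  bases <- rownames(pwm$probs)
  paste(vapply(seq_len(ncol(pwm$probs)), function(j)
    sample(bases, 1L, prob = pwm$probs[, j]), character(1)), collapse = "")
}

#' Generate promoter sequences with planted motif occurrences
#'
#' Unplanted promoters are iid draws from the background base frequencies;
#' planted promoters additionally carry `occurrences` motif instances
#' sampled from the PWM, inserted at non-overlapping uniform positions on a
#' uniformly chosen strand.
#'
#' @param genes Character vector of gene ids (one promoter each).
#' @param pwm A [new_pwm()] object.
#' @param planted_genes Subset of `genes` receiving motif instances.
#' @param occurrences Motif instances per planted promoter.
#' @param bg_freqs Length-4 base frequencies (A, C, G, T).
#' @param length Promoter length in bp.
#' @param seed Integer RNG seed.
#' @return A [Biostrings::DNAStringSet] named by gene, with attribute
#'   `"planted"` listing the planted gene ids.
#' @export
generate_promoters <- function(genes, pwm, planted_genes = character(0),
                               occurrences = 1L,
                               bg_freqs = rep(0.25, 4L),
                               length = 1000L, seed = 1L) {
  if (!all(planted_genes %in% genes))
    stop("planted_genes must be a subset of genes", call. = FALSE)
  w <- pwm_width(pwm)
  if (length < w) stop("promoter length < motif width", call. = FALSE)
  if (occurrences * w > length)
    stop("occurrences x width exceeds promoter length", call. = FALSE)
  set.seed(seed)
  seqs <- random_dna(base::length(genes), length, bg_freqs)
  names(seqs) <- genes
  for (g in planted_genes) {
    if (occurrences == 0L) break
    # non-overlapping starts by rejection over the uniform grid
    starts <- integer(0)
    while (base::length(starts) < occurrences) {
      cand <- sample.int(length - w + 1L, 1L)
      if (all(abs(cand - starts) >= w)) starts <- c(starts, cand)
    }
    s <- strsplit(seqs[[g]], "")[[1L]]
    for (st in starts) {
      inst <- sample_motif_instance(pwm)
      if (stats::runif(1) < 0.5)
        inst <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(inst)))
      s[st:(st + w - 1L)] <- strsplit(inst, "")[[1L]]
    }
    seqs[[g]] <- paste(s, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  attr(out, "planted") <- planted_genes
  out
}

#' Generate three synthetic background sequence pools
#'
#' Analogues of the genome-scale backgrounds used for motif-enrichment
#' nulls: a uniform-composition pool, a GC-rich pool (CpG-island-like), and
#' a mixed pool (half uniform, half GC-rich).
#'
#' @param n_seq Sequences per pool.
#' @param length Sequence length (bp).
#' @param seed Integer RNG seed.
#' @return Named list of three [Biostrings::DNAStringSet] pools
#'   (`uniform`, `gc_rich`, `mixed`).
#' @export
generate_backgrounds <- function(n_seq = 500L, length = 1000L, seed = 1L) {
  set.seed(seed)
  uni <- random_dna(n_seq, length, rep(0.25, 4L))
  gc <- random_dna(n_seq, length, c(0.17, 0.33, 0.33, 0.17))
  mix <- c(random_dna(ceiling(n_seq / 2), length, rep(0.25, 4L)),
           random_dna(floor(n_seq / 2), length, c(0.17, 0.33, 0.33, 0.17)))
  lapply(list(uniform = uni, gc_rich = gc, mixed = mix),
         function(x) Biostrings::DNAStringSet(
           stats::setNames(x, sprintf("bgseq%04d", seq_along(x)))))
}

#' Generate a disease gene set and a ChIP target list with known truth
#'
#' The disease set draws `round(overlap_fraction * set_size)` members from
#' one target module and the rest uniformly from background genes. The ChIP
#' list mixes truly motif-planted genes with `decoy_count` decoys drawn from
#' unplanted genes.
#'
#' @param module_genes Character vector: genes of the target module.
#' @param background_genes Character vector: genes outside the target module.
#' @param set_size Size of the disease set.
#' @param overlap_fraction Fraction of the disease set drawn from the module.
#' @param planted_genes Genes carrying a planted motif (may be empty).
#' @param decoy_count Number of decoy genes added to the ChIP list.
#' @param seed Integer RNG seed.
#' @return List with `disease_set`, `chip_targets`, and `truth` (the module
#'   members actually included).
#' @export
generate_genesets_and_chip <- function(module_genes, background_genes,
                                       set_size = 40L,
                                       overlap_fraction = 0.5,
                                       planted_genes = character(0),
                                       decoy_count = 0L, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  n_in <- round(overlap_fraction * set_size)
  n_out <- set_size - n_in
  if (n_in > length(module_genes) || n_out > length(background_genes))
    stop("requested set size exceeds universe", call. = FALSE)
  set.seed(seed)
  inside <- sample(module_genes, n_in)
  outside <- sample(background_genes, n_out)
  decoy_pool <- setdiff(c(module_genes, background_genes), planted_genes)
  if (decoy_count > length(decoy_pool))
    stop("decoy_count exceeds available unplanted genes", call. = FALSE)
  chip <- unique(c(planted_genes,
                   if (decoy_count > 0L) sample(decoy_pool, decoy_count)))
  list(disease_set = c(inside, outside),
       chip_targets = chip,
       truth = list(module_members = inside))
}
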