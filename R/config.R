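#' Run configuration
#'
#' Bundles every tunable parameter of the pipeline in one validated object.
#' Defaults follow the conventional choices for signed co-expression network
#' analysis of microarray data: soft-thresholding power 12, minimum module
#' size 40 genes, module-eigengene merge height 0.25, hub selection at
#' kME > 0.6 capped at the top 200 genes, permutation counts of 200
#' (preservation), 10,000 (annotation enrichment) and 1,000 (motif background
#' draws), and 1,000-bp promoters.
#'
#' @param soft_power Soft-thresholding power beta for the signed adjacency.
#' @param min_module_size Smallest cluster retained as a module; smaller
#'   clusters are assigned to "grey".
#' @param merge_height Eigengene dissimilarity (1 - cor) below which two
#'   modules are merged.
#' @param kme_hub_threshold Own-module kME above which a gene is a hub
#'   candidate.
#' @param hub_cap Maximum number of hub genes reported per module.
#' @param de_alpha Per-test significance level for differential expression
#'   and the interaction test.
#' @param fdr_alpha Benjamini-Hochberg FDR level for module-trait calls.
#' @param n_perm_preservation Permutations for the preservation null.
#' @param n_perm_enrichment Permutations for annotation enrichment.
#' @param n_bg_draws Random background draws per motif-enrichment null.
#' @param promoter_length Promoter window, bp upstream of the TSS.
#' @param rng_seed Integer seed propagated to every stochastic stage.
#' @return An object of class `coex_config` (a named list).
#' @export
#' @examples
#' cfg <- coex_config(rng_seed = 1)
#' cfg$soft_power
coex_config <- function(soft_power = 12L,
                        min_module_size = 40L,
                        merge_height = 0.25,
                        kme_hub_threshold = 0.6,
                        hub_cap = 200L,
                        de_alpha = 0.05,
                        fdr_alpha = 0.05,
                        n_perm_preservation = 200L,
                        n_perm_enrichment = 10000L,
                        n_bg_draws = 1000L,
                        promoter_length = 1000L,
                        rng_seed = 1L) {
  cfg <- list(
    soft_power = as.integer(soft_power),
    min_module_size = as.integer(min_module_size),
    merge_height = as.numeric(merge_height),
    kme_hub_threshold = as.numeric(kme_hub_threshold),
    hub_cap = as.integer(hub_cap),
    de_alpha = as.numeric(de_alpha),
    fdr_alpha = as.numeric(fdr_alpha),
    n_perm_preservation = as.integer(n_perm_preservation),
    n_perm_enrichment = as.integer(n_perm_enrichment),
    n_bg_draws = as.integer(n_bg_draws),
    promoter_length = as.integer(promoter_length),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "coex_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c("soft_power", "min_module_size", "hub_cap",
              "n_perm_preservation", "n_perm_enrichment", "n_bg_draws",
              "promoter_length")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("config field '", f, "' must be a positive count", call. = FALSE)
  }
  levels <- c("merge_height", "kme_hub_threshold", "de_alpha", "fdr_alpha")
  for (f in levels) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) ||
        cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("config field '", f, "' must lie in (0, 1)", call. = FALSE)
  }
  if (length(cfg$rng_seed) != 1L || is.na(cfg$rng_seed))
    stop("config field 'rng_seed' must be a single integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.coex_config <- function(x, ...) {
  cat("coexnet run configuration\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Write/read a run configuration as a plain key:value text file
#'
#' The on-disk format is one `key: value` pair per line, diff-able and
#' language-neutral. `read_config()` inverts `write_config()` exactly.
#'
#' @param cfg A `coex_config` object.
#' @param path File path.
#' @return `read_config()` returns a `coex_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "coex_config"))
  lines <- vapply(names(cfg), function(f) {
    paste0(f, ": ", format(cfg[[f]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+):[ \t]*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  defaults <- coex_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- as.list(defaults)
  for (i in seq_along(keys)) args[[keys[i]]] <- as.numeric(vals[i])
  do.call(coex_config, args)
}
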