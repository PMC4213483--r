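DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

encode_seq <- function(s) {
  v <- DNA_CODE[strsplit(toupper(as.character(s)), "")[[1L]]]
  v[is.na(v)] <- 0L  # any ambiguity code treated like N
  unname(v)
}

revcomp_codes <- function(codes) {
  comp <- c(0L, 4L, 3L, 2L, 1L)  # N,A,C,G,T -> N,T,G,C,A
  rev(comp[codes + 1L])
}

# per-position log likelihood ratios of one strand; N bases contribute
# a neutral factor (LR = 1) so position counts stay comparable
position_loglr <- function(codes, logp) {
  w <- ncol(logp)
  npos <- length(codes) - w + 1L
  if (npos < 1L) return(numeric(0))
  ll <- rbind(0, logp)  # row 1 = N -> log LR contribution 0
  s <- numeric(npos)
  for (j in seq_len(w))
    s <- s + ll[codes[j:(j + npos - 1L)] + 1L, j]
  s
}

pwm_loglr_matrix <- function(pwm, bg_freqs) {
  log(pwm$probs) - log(bg_freqs)
}

#' Extract promoter sequences from a genome and TSS annotations
#'
#' Promoters are the `length` bp upstream of each transcription start
#' site: for a plus-strand gene with 0-based TSS `t` the window is
#' `[t - length, t)`; for a minus-strand gene, `[t + 1, t + 1 + length)`
#' reverse-complemented. Windows are truncated at contig boundaries and the
#' truncation recorded.
#'
#' @param tss A BED-style data.frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; 0-based half-open) or a path to a BED file. The
#'   strand-aware start of each interval is taken as the TSS.
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path) keyed by
#'   contig name.
#' @param length Promoter length in bp.
#' @return A [Biostrings::DNAStringSet] named by the BED `name` column,
#'   with attribute `"truncated"` (named logical).
#' @export
extract_promoters <- function(tss, genome, length = 1000L) {
  if (is.character(tss) && base::length(tss) == 1L) tss <- read_bed(tss)
  if (is.character(genome) && base::length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("[ \t].*$", "", names(genome))
  out <- character(nrow(tss))
  trunc <- logical(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    chrom <- tss$chrom[i]
    if (!chrom %in% names(genome))
      stop("contig '", chrom, "' for gene '", tss$name[i],
           "' absent from genome FASTA", call. = FALSE)
    clen <- Biostrings::width(genome[chrom])
    if (identical(tss$strand[i], "-")) {
      t0 <- tss$end[i] - 1L                    # 0-based TSS
      from <- t0 + 2L; to <- t0 + 1L + length  # 1-based inclusive
    } else {
      t0 <- tss$start[i]
      from <- t0 - length + 1L; to <- t0       # 1-based inclusive
    }
    cf <- max(1L, from); ct <- min(clen, to)
    trunc[i] <- cf != from || ct != to
    if (ct < cf) { out[i] <- ""; next }
    s <- Biostrings::subseq(genome[[chrom]], cf, ct)
    if (identical(tss$strand[i], "-"))
      s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  res <- Biostrings::DNAStringSet(stats::setNames(out, tss$name))
  attr(res, "truncated") <- stats::setNames(trunc, tss$name)
  res
}

#' Read a BED file (0-based half-open, with strand)
#'
#' @param path Path to a BED file with at least 3 columns; columns 4-6 are
#'   `name`, `score`, `strand` when present.
#' @return A data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  colnames(df) <- cols[seq_len(min(ncol(df), 6L))]
  if (!"name" %in% colnames(df)) df$name <- paste0("region", seq_len(nrow(df)))
  if (!"strand" %in% colnames(df)) df$strand <- "+"
  df
}

#' Per-sequence motif scores
#'
#' For one sequence, the likelihood ratio of the PWM against background
#' base frequencies is computed at every position on both strands; the
#' sequence score is the log of the arithmetic mean of those ratios. A
#' sequence matching the motif well in at least one place scores high; a
#' background-like sequence scores near 0.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or character vector).
#' @param pwm A [new_pwm()] object.
#' @param bg_freqs Length-4 background base frequencies (A, C, G, T).
#' @return Named numeric vector of per-sequence scores; sequences shorter
#'   than the motif are dropped with a warning.
#' @export
score_sequences <- function(seqs, pwm, bg_freqs = rep(0.25, 4L)) {
  logp <- pwm_loglr_matrix(pwm, bg_freqs)
  w <- ncol(logp)
  sq <- as.character(seqs)
  lens <- nchar(sq)
  if (any(lens < w)) {
    warning(sum(lens < w), " sequence(s) shorter than the motif excluded")
    sq <- sq[lens >= w]
  }
  vapply(sq, function(s) {
    codes <- encode_seq(s)
    lr <- c(position_loglr(codes, logp),
            position_loglr(revcomp_codes(codes), logp))
    # log of the arithmetic mean of LRs, computed stably
    m <- max(lr)
    m + log(mean(exp(lr - m)))
  }, numeric(1), USE.NAMES = TRUE)
}

#' Raw motif set score of a promoter set
#'
#' Mean of the per-sequence scores of [score_sequences()] over the set.
#'
#' @inheritParams score_sequences
#' @return A single number `U`; 0 is the background expectation scale.
#' @export
motif_set_score <- function(seqs, pwm, bg_freqs = rep(0.25, 4L)) {
  if (!base::length(seqs)) stop("empty promoter set", call. = FALSE)
  mean(score_sequences(seqs, pwm, bg_freqs))
}

base_frequencies <- function(seqs) {
  tab <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                       baseOnly = TRUE, collapse = TRUE)
  f <- tab[c("A", "C", "G", "T")]
  f / sum(f)
}

#' Empirical motif enrichment against background sequence pools
#'
#' For each background pool, the module's set score is compared against a
#' null distribution of `n_draws` replicate sets, each with the same number
#' and lengths of sequences as the module promoter set, drawn with
#' replacement from the pool (random windows are cut when pool sequences
#' are longer than required). Background base frequencies for the
#' likelihood ratio are estimated from each pool, so observed and null
#' scores are always computed under the same background model.
#' `P = (1 + #\{U_null >= U_obs\}) / (1 + n_draws)`; the motif is called
#' significant only when `P < 0.05` in every background.
#'
#' @param module_promoters [Biostrings::DNAStringSet] of module promoters.
#' @param pwm A [new_pwm()] object.
#' @param backgrounds Named list of background pools
#'   ([Biostrings::DNAStringSet]), e.g. from [generate_backgrounds()].
#' @param n_draws Random draws per background.
#' @param seed Integer RNG seed.
#' @param alpha Per-background significance level.
#' @return A one-row data.frame: `motif`, `U` (raw set score under uniform
#'   background), one `p_<background>` column per pool, `significant`,
#'   `n_draws`.
#' @export
empirical_motif_enrichment <- function(module_promoters, pwm, backgrounds,
                                       n_draws = 1000L, seed = 1L,
                                       alpha = 0.05) {
  if (is.null(names(backgrounds)))
    names(backgrounds) <- paste0("bg", seq_along(backgrounds))
  set.seed(seed)
  need_len <- nchar(as.character(module_promoters))
  w <- pwm_width(pwm)
  ps <- stats::setNames(numeric(length(backgrounds)), names(backgrounds))
  for (b in names(backgrounds)) {
    pool <- backgrounds[[b]]
    pool_len <- Biostrings::width(pool)
    if (any(max(pool_len) < need_len))
      stop("background '", b, "' cannot supply windows of the required ",
           "length", call. = FALSE)
    freqs <- base_frequencies(pool)
    u_obs <- motif_set_score(module_promoters, pwm, freqs)
    uniform_len <- length(unique(need_len)) == 1L &&
      all(pool_len == need_len[1L])
    if (uniform_len) {
      # whole pool sequences are valid draws: score each once, then draws
      # are means of sampled per-sequence scores
      pool_scores <- score_sequences(pool, pwm, freqs)
      draws <- matrix(sample.int(length(pool_scores),
                                 n_draws * length(need_len), replace = TRUE),
                      n_draws)
      u_null <- rowMeans(matrix(pool_scores[draws], n_draws))
    } else {
      eligible <- which(pool_len >= max(need_len))
      u_null <- vapply(seq_len(n_draws), function(i) {
        pick <- sample(eligible, length(need_len), replace = TRUE)
        segs <- vapply(seq_along(pick), function(j) {
          L <- need_len[j]
          st <- sample.int(pool_len[pick[j]] - L + 1L, 1L)
          as.character(Biostrings::subseq(pool[[pick[j]]], st, st + L - 1L))
        }, character(1))
        motif_set_score(Biostrings::DNAStringSet(segs), pwm, freqs)
      }, numeric(1))
    }
    ps[b] <- (1 + sum(u_null >= u_obs)) / (1 + n_draws)
  }
  data.frame(motif = pwm$id,
             U = motif_set_score(module_promoters, pwm),
             as.list(stats::setNames(ps, paste0("p_", names(ps)))),
             significant = all(ps < alpha), n_draws = n_draws,
             stringsAsFactors = FALSE)
}

#' Predicted motif target genes
#'
#' A gene is a predicted target when its promoter contains at least one
#' site, on either strand, whose log-likelihood-ratio score reaches
#' `threshold_frac` of the maximal attainable site score for the PWM.
#'
#' @param promoters Named [Biostrings::DNAStringSet].
#' @param pwm A [new_pwm()] object.
#' @param threshold_frac Fraction of the maximal attainable site score.
#' @param bg_freqs Background base frequencies for the likelihood ratio.
#' @return Character vector of predicted target gene ids.
#' @export
predicted_targets <- function(promoters, pwm, threshold_frac = 0.9,
                              bg_freqs = rep(0.25, 4L)) {
  logp <- pwm_loglr_matrix(pwm, bg_freqs)
  maxscore <- sum(apply(logp, 2L, max))
  thr <- threshold_frac * maxscore
  hits <- vapply(as.character(promoters), function(s) {
    codes <- encode_seq(s)
    if (length(codes) < ncol(logp)) return(FALSE)
    any(position_loglr(codes, logp) >= thr) ||
      any(position_loglr(revcomp_codes(codes), logp) >= thr)
  }, logical(1), USE.NAMES = FALSE)
  names(promoters)[hits]
}
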