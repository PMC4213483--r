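# Shared fixture builders; everything is generated in code at test time.

options(coexnet.quiet = TRUE)

# Block-structured expression: each block shares a latent factor so that
# the within-block correlation is approximately `within_cor`; blocks are
# mutually independent. Returns a feature x sample matrix with block truth
# in attribute "block".
make_block_expr <- function(sizes, within_cor = 0.9, n_samples = 36L,
                            n_noise = 0L, seed = 1L) {
  set.seed(seed)
  lambda <- 1
  sigma <- sqrt(lambda^2 * (1 - within_cor) / within_cor)
  # exactly orthogonal factors so blocks never merge by chance
  fs <- qr.Q(qr(matrix(rnorm(n_samples * length(sizes)), n_samples)))
  fs <- fs * sqrt(n_samples)
  blocks <- lapply(seq_along(sizes), function(b) {
    f <- fs[, b]
    m <- outer(rep(lambda, sizes[b]), f) +
      matrix(rnorm(sizes[b] * n_samples, 0, sigma), sizes[b], n_samples)
    rownames(m) <- sprintf("blk%d_g%03d", b, seq_len(sizes[b]))
    m
  })
  if (n_noise > 0L) {
    m <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
    rownames(m) <- sprintf("noise_g%03d", seq_len(n_noise))
    blocks <- c(blocks, list(m))
  }
  out <- do.call(rbind, blocks)
  colnames(out) <- sprintf("s%02d", seq_len(n_samples))
  attr(out, "block") <- rep(c(sprintf("blk%d", seq_along(sizes)),
                              if (n_noise > 0L) "noise"),
                            c(sizes, if (n_noise > 0L) n_noise))
  out
}

# A sharply determined 8-bp PWM (consensus TGGAAACA by default).
make_test_pwm <- function(id = "TEST_MOTIF", consensus = "TGGAAACA",
                          strength = 1000) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  counts <- vapply(cons, function(b) {
    v <- rep(0, 4)
    v[match(b, bases)] <- strength
    v
  }, numeric(4))
  new_pwm(id, counts)
}

# Minimal paired case/control design: n_pairs per genotype, one progenitor
# and one resting neuron per pair.
make_paired_design <- function(n_ctrl = 6L, n_ts = 6L) {
  mk <- function(geno, n, tag) {
    pid <- sprintf("%s%02d", tag, seq_len(n))
    rbind(
      data.frame(sample_id = paste0("P_", pid), cell_type = "progenitor",
                 depolarized = 0L, genotype = geno, subject_id = geno,
                 clone_id = pid, pair_id = pid, stringsAsFactors = FALSE),
      data.frame(sample_id = paste0("N_", pid), cell_type = "neuron",
                 depolarized = 0L, genotype = geno, subject_id = geno,
                 clone_id = pid, pair_id = pid, stringsAsFactors = FALSE))
  }
  rbind(mk("control", n_ctrl, "c"), mk("TS", n_ts, "t"))
}

expect_file_identical <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}
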