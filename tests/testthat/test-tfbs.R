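toy_genome <- function() {
  Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 500), collapse = ""),   # 2000 bp
    chr2 = "ACGTACGTACGTACGTACGT"))                  # 20 bp
}

test_that("plus-strand promoters are the upstream window [t-L, t)", {
  bed <- data.frame(chrom = "chr1", start = 1000L, end = 1500L,
                    name = "geneA", score = 0, strand = "+",
                    stringsAsFactors = FALSE)
  g <- toy_genome()
  p <- extract_promoters(bed, g, length = 1000)
  expect_equal(Biostrings::width(p), 1000)
  expect_identical(as.character(p[["geneA"]]),
                   as.character(Biostrings::subseq(g[["chr1"]], 1, 1000)))
  expect_false(attr(p, "truncated")[["geneA"]])
})

test_that("minus-strand promoters are reverse-complemented downstream", {
  # 20-bp toy contig, gene on the minus strand covering [4, 10): the TSS
  # is base 9 (0-based); the promoter is [10, 16) reverse-complemented
  bed <- data.frame(chrom = "chr2", start = 4L, end = 10L,
                    name = "geneB", score = 0, strand = "-",
                    stringsAsFactors = FALSE)
  g <- toy_genome()
  p <- extract_promoters(bed, g, length = 6)
  by_hand <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(g[["chr2"]], 11, 16)))
  expect_identical(as.character(p[["geneB"]]), by_hand)
})

test_that("contig edges truncate promoters and flag them", {
  bed <- data.frame(chrom = "chr1", start = 5L, end = 100L,
                    name = "geneC", score = 0, strand = "+",
                    stringsAsFactors = FALSE)
  p <- extract_promoters(bed, toy_genome(), length = 1000)
  expect_equal(Biostrings::width(p)[[1]], 5)
  expect_true(attr(p, "truncated")[["geneC"]])
  bad <- data.frame(chrom = "chrX", start = 10L, end = 20L,
                    name = "geneD", score = 0, strand = "+",
                    stringsAsFactors = FALSE)
  expect_error(extract_promoters(bad, toy_genome()), "geneD")
})

test_that("BED files round-trip into the promoter extractor", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1500\tgeneA\t0\t+", f)
  bed <- read_bed(f)
  expect_identical(bed$name, "geneA")
  expect_identical(bed$start, 1000L)
  p <- extract_promoters(f, toy_genome(), length = 50)
  expect_equal(Biostrings::width(p), 50)
})

test_that("a hand-computed two-position motif scores exactly", {
  # PWM: position 1 always A, position 2 always C (huge counts so the
  # pseudocount is negligible); uniform background
  pwm <- new_pwm("AC2", matrix(c(1e9, 0, 0, 0, 0, 1e9, 0, 0), 4),
                 pseudocount = 0.25)
  seqs <- Biostrings::DNAStringSet(c(s1 = "AC"))
  p_a <- pwm$probs[1, 1]; p_c <- pwm$probs[2, 2]
  # positions: AC forward (LR = p_a p_c / 0.0625) and the reverse
  # complement GT scanned forward (LR ~ 0)
  lr_fwd <- p_a * p_c / 0.0625
  lr_rc <- pwm$probs[3, 1] * pwm$probs[4, 2] / 0.0625
  by_hand <- log(mean(c(lr_fwd, lr_rc)))
  expect_equal(motif_set_score(seqs, pwm), by_hand)
})

test_that("a background-equal PWM scores exactly zero", {
  pwm <- new_pwm("NULL4", matrix(1, 4, 5))
  set.seed(80)
  seqs <- generate_promoters(letters[1:5], pwm, character(0),
                             occurrences = 0, length = 60, seed = 81)
  expect_equal(motif_set_score(seqs, pwm), 0)
})

test_that("N bases contribute neutrally", {
  pwm <- new_pwm("W1", matrix(c(9, 1, 1, 1), 4))
  u_n <- score_sequences(Biostrings::DNAStringSet("N"), pwm)
  expect_equal(unname(u_n), 0)
})

test_that("planting more motif instances never lowers the set score", {
  pwm <- make_test_pwm()
  genes <- sprintf("g%02d", 1:30)
  us <- vapply(0:3, function(k) {
    pr <- generate_promoters(genes, pwm, genes, occurrences = k,
                             length = 300, seed = 82)
    motif_set_score(pr, pwm)
  }, numeric(1))
  expect_true(all(diff(us) > 0))
})

test_that("the set score is order- and strand-invariant", {
  pwm <- make_test_pwm()
  pr <- generate_promoters(sprintf("g%02d", 1:20), pwm,
                           sprintf("g%02d", 1:10), occurrences = 1,
                           length = 200, seed = 83)
  u <- motif_set_score(pr, pwm)
  expect_equal(motif_set_score(rev(pr), pwm), u)
  expect_equal(motif_set_score(Biostrings::reverseComplement(pr), pwm), u)
})

test_that("short sequences are excluded with a warning; empty set errors", {
  pwm <- make_test_pwm()
  seqs <- Biostrings::DNAStringSet(c(a = "ACGTACGTACGT", b = "ACG"))
  expect_warning(u <- score_sequences(seqs, pwm), "shorter")
  expect_length(u, 1)
  expect_error(motif_set_score(Biostrings::DNAStringSet(), pwm), "empty")
})

test_that("predicted targets require a near-maximal site", {
  pwm <- make_test_pwm(strength = 1e6)
  genes <- sprintf("g%02d", 1:40)
  planted <- genes[1:20]
  pr <- generate_promoters(genes, pwm, planted, occurrences = 1,
                           length = 400, seed = 84)
  hits <- predicted_targets(pr, pwm, threshold_frac = 0.9)
  expect_gte(length(intersect(hits, planted)) / 20, 0.95)
  expect_lte(length(setdiff(hits, planted)) / 20, 0.1)
  expect_length(predicted_targets(pr, pwm, threshold_frac = 1.5), 0)
})

test_that("empirical enrichment flags a planted motif, reproducibly", {
  pwm <- make_test_pwm()
  genes <- sprintf("g%02d", 1:30)
  pr <- generate_promoters(genes, pwm, genes[1:24], occurrences = 1,
                           length = 500, seed = 85)
  bgs <- generate_backgrounds(n_seq = 150, length = 500, seed = 86)
  res <- empirical_motif_enrichment(pr, pwm, bgs, n_draws = 300, seed = 87)
  expect_true(res$significant)
  expect_equal(unname(unlist(res[paste0("p_", names(bgs))])),
               rep(1 / 301, 3))
  res2 <- empirical_motif_enrichment(pr, pwm, bgs, n_draws = 300,
                                     seed = 87)
  expect_identical(res, res2)
})

test_that("modules drawn from the background itself are unenriched", {
  pwm <- make_test_pwm()
  bgs <- generate_backgrounds(n_seq = 200, length = 300, seed = 88)
  ps <- vapply(1:20, function(i) {
    set.seed(100 + i)
    pick <- sample(200, 30)
    res <- empirical_motif_enrichment(bgs$uniform[pick], pwm,
                                      bgs["uniform"], n_draws = 300,
                                      seed = 200 + i)
    res$p_uniform
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("windows are cut when pool sequences are longer than needed", {
  pwm <- make_test_pwm()
  pr <- generate_promoters(sprintf("g%d", 1:10), pwm, character(0),
                           occurrences = 0, length = 100, seed = 89)
  long_pool <- generate_backgrounds(n_seq = 50, length = 400, seed = 90)
  res <- empirical_motif_enrichment(pr, pwm, long_pool["uniform"],
                                    n_draws = 100, seed = 91)
  expect_true(res$p_uniform > 1 / 101)
  short_pool <- generate_backgrounds(n_seq = 50, length = 50, seed = 92)
  expect_error(empirical_motif_enrichment(pr, pwm, short_pool["uniform"],
                                          n_draws = 100, seed = 93),
               "length")
})
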