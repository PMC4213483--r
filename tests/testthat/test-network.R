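test_that("signed adjacency hits its closed-form values", {
  x <- c(1, 2, 3, 4)
  expr <- rbind(g1 = x, g2 = 2 * x,            # cor  1 -> a = 1
                g3 = -x,                       # cor -1 -> a = 0
                g4 = c(1, -1, 1, -1) * sqrt(5))
  colnames(expr) <- paste0("s", 1:4)
  a <- signed_adjacency(expr, beta = 12)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0, tolerance = 1e-25)
  # orthogonal pair: cor = 0 -> 0.5^12
  expr2 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  colnames(expr2) <- paste0("s", 1:4)
  a2 <- signed_adjacency(expr2, beta = 12)
  expect_identical(a2["g1", "g2"], 0.000244140625)
  expect_true(isSymmetric(unname(a)))
  expect_equal(unname(diag(a)), rep(1, 4))
})

test_that("zero-variance features are rejected by name", {
  expr <- rbind(g1 = c(1, 2, 3), flatgene = c(5, 5, 5))
  colnames(expr) <- paste0("s", 1:3)
  expect_error(signed_adjacency(expr), "flatgene")
})

test_that("raising beta weakens every imperfect connection", {
  set.seed(6)
  expr <- matrix(rnorm(120), 12, 10)
  rownames(expr) <- paste0("g", 1:12)
  a6 <- signed_adjacency(expr, 6)
  a12 <- signed_adjacency(expr, 12)
  off <- upper.tri(a6)
  imperfect <- off & a6 < 1
  expect_true(all(a12[imperfect] < a6[imperfect]))
})

test_that("TOM agrees with a brute-force triple loop", {
  tom_oracle <- function(a) {
    n <- nrow(a)
    k <- rowSums(a) - diag(a)
    t_ <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      t_[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    t_
  }
  set.seed(7)
  m <- matrix(runif(400), 20, 20)
  a <- (m + t(m)) / 2
  diag(a) <- 1
  expect_lt(max(abs(topological_overlap(a) - tom_oracle(a))), 1e-12)
})

test_that("TOM closed forms: two features and the complete module", {
  for (x in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(1, x, x, 1), 2)
    expect_equal(topological_overlap(a)[1, 2], x)
  }
  ones <- matrix(1, 5, 5)
  expect_equal(unname(topological_overlap(ones)), matrix(1, 5, 5))
  bad <- matrix(runif(9), 3); diag(bad) <- 1
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("static cut recovers planted blocks and honours min size", {
  expr <- make_block_expr(c(50, 50), within_cor = 0.9, n_samples = 30,
                          seed = 8)
  tom <- topological_overlap(signed_adjacency(expr, 6))
  part <- cluster_and_cut(tom, min_module_size = 40)
  sizes <- table(part[part != "grey"])
  expect_length(sizes, 2)
  expect_equal(as.integer(sort(sizes)), c(50L, 50L))
  # module labels align exactly with the planted blocks
  expect_equal(adjusted_rand_index(attr(expr, "block"), part), 1)
  expect_true(all(cluster_and_cut(tom, min_module_size = 51) == "grey"))
  # a module of exactly min_module_size sits on the boundary and is kept
  two <- make_block_expr(c(40, 60), within_cor = 0.9, seed = 9)
  tom1 <- topological_overlap(signed_adjacency(two, 6))
  p1 <- cluster_and_cut(tom1, min_module_size = 40)
  expect_equal(sum(p1 == "blue"), 40)
})

test_that("module labels follow the conventional size-ranked palette", {
  expr <- make_block_expr(c(60, 45, 80), within_cor = 0.9, seed = 10)
  tom <- topological_overlap(signed_adjacency(expr, 6))
  part <- cluster_and_cut(tom, min_module_size = 40)
  sizes <- sort(table(part[part != "grey"]), decreasing = TRUE)
  expect_identical(names(sizes), c("turquoise", "blue", "brown"))
  expect_equal(as.integer(sizes), c(80L, 60L, 45L))
})

test_that("eigengene of coherent modules is the shared profile", {
  set.seed(21)
  prof <- rnorm(20)
  expr <- matrix(rep(prof, each = 10), 10, 20)  # every gene = the profile
  expr <- expr * seq(1, 2, length.out = 10) + seq(0, 9)  # scales, means
  rownames(expr) <- paste0("g", 1:10)
  colnames(expr) <- paste0("s", 1:20)
  part <- setNames(rep("blue", 10), rownames(expr))
  eg <- module_eigengenes(expr, part)
  expect_equal(abs(cor(eg$eigengenes[, "blue"], prof)), 1)
  expect_gt(cor(eg$eigengenes[, "blue"], prof), 0)  # sign convention
  expect_equal(unname(eg$var_explained["blue"]), 1)
})

test_that("sign convention survives half-negated modules", {
  set.seed(11)
  prof <- rnorm(16)
  expr <- rbind(matrix(rep(prof, each = 5), 5),
                matrix(rep(-prof, each = 5), 5))
  rownames(expr) <- paste0("g", 1:10)
  colnames(expr) <- paste0("s", 1:16)
  part <- setNames(rep("m1", 10), rownames(expr))
  eg <- module_eigengenes(expr, part)
  expect_equal(abs(cor(eg$eigengenes[, 1], prof)), 1)
})

test_that("eigengenes track the planted latent factors", {
  for (seed in 1:5) {
    mods <- default_module_specs()[c(1, 4)]
    sim <- generate_expression(modules = mods, n_background = 0,
                               seed = seed)
    part <- setNames(sim$truth$module, names(sim$truth$module))
    eg <- module_eigengenes(sim$log2, part)
    for (m in colnames(eg$eigengenes))
      expect_gt(cor(eg$eigengenes[, m], sim$truth$factors[, m])^2, 0.9)
  }
})

test_that("constant genes are dropped from the SVD with a warning", {
  expr <- rbind(g1 = rnorm(10), g2 = rnorm(10), g3 = rep(2, 10))
  colnames(expr) <- paste0("s", 1:10)
  part <- setNames(rep("m", 3), rownames(expr))
  expect_warning(module_eigengenes(expr, part), "constant")
})

test_that("close eigengenes merge; distant ones do not; merge is idempotent", {
  set.seed(12)
  n <- 40
  f <- rnorm(n)
  # two modules sharing a factor (ME cor ~ 0.95) and one independent
  mk <- function(f, k, sd) {
    m <- outer(rep(1, k), f) + matrix(rnorm(k * n, 0, sd), k, n)
    m
  }
  expr <- rbind(mk(f, 30, 0.2), mk(f, 30, 0.2), mk(rnorm(n), 30, 0.2))
  rownames(expr) <- paste0("g", 1:90)
  colnames(expr) <- paste0("s", 1:n)
  part <- setNames(rep(c("blue", "brown", "turquoise"), each = 30),
                   rownames(expr))
  merged <- merge_close_modules(expr, part, merge_height = 0.25)
  mods <- setdiff(unique(merged$partition), "grey")
  expect_length(mods, 2)
  expect_equal(sum(merged$partition == "turquoise"), 30)
  again <- merge_close_modules(expr, merged$partition, 0.25)
  expect_identical(again$partition, merged$partition)
  # orthogonal factors (ME dissimilarity ~ 1) never merge
  expr2 <- rbind(mk(f, 30, 0.2), mk(rnorm(n), 30, 0.2))
  rownames(expr2) <- paste0("h", 1:60)
  colnames(expr2) <- paste0("s", 1:n)
  part2 <- setNames(rep(c("blue", "brown"), each = 30), rownames(expr2))
  expect_length(setdiff(unique(merge_close_modules(expr2, part2,
                                                   0.25)$partition),
                        "grey"), 2)
})

test_that("kME is the gene-eigengene correlation", {
  set.seed(13)
  expr <- make_block_expr(30, within_cor = 0.8, n_samples = 24, seed = 13)
  part <- setNames(rep("blue", 30), rownames(expr))
  eg <- module_eigengenes(expr, part)
  me <- eg$eigengenes[, "blue"]
  expr2 <- rbind(expr, me_gene = me, anti_me = -me)
  part2 <- c(part, me_gene = "grey", anti_me = "grey")
  kme <- compute_kme(expr2, eg)
  expect_equal(kme["me_gene", "blue"], 1)
  expect_equal(kme["anti_me", "blue"], -1)
  expect_equal(unname(kme[rownames(expr), "blue"]),
               unname(cor(t(expr), me)[, 1]))
})

test_that("random genes rarely reach |kME| 0.5 at 36 samples", {
  set.seed(14)
  me <- rnorm(36)
  genes <- matrix(rnorm(1000 * 36), 1000, 36)
  kme <- cor(t(genes), me)
  expect_gte(mean(abs(kme) < 0.5), 0.95)
})

test_that("hub selection takes the smaller of threshold and cap sets", {
  set.seed(15)
  n <- 250
  kme <- matrix(runif(n, 0.61, 0.99), n, 1,
                dimnames = list(sprintf("g%03d", 1:n), "blue"))
  part <- setNames(rep("blue", n), rownames(kme))
  hubs <- hub_genes(kme, part, "blue", threshold = 0.6, cap = 200)
  expect_length(hubs, 200)
  expect_identical(hubs, names(sort(kme[, 1], decreasing = TRUE))[1:200])
  kme37 <- kme; kme37[38:n, 1] <- 0.1
  h37 <- hub_genes(kme37, part, "blue")
  expect_length(h37, 37)
  # ties at the cap boundary break lexicographically
  kme_tie <- matrix(0.8, 5, 1,
                    dimnames = list(c("gB", "gA", "gD", "gC", "gE"), "m"))
  pt <- setNames(rep("m", 5), rownames(kme_tie))
  expect_identical(hub_genes(kme_tie, pt, "m", cap = 3),
                   c("gA", "gB", "gC"))
})

test_that("scale-free fit scores an exact power law highly", {
  # degree sequence with freq(k) proportional to k^-2
  ks <- rep(1:40, times = round(4000 * (1:40)^-2))
  expect_gt(coexnet:::scale_free_r2(ks, n_bins = 10), 0.95)
  expect_true(is.na(coexnet:::scale_free_r2(rep(3, 50))))
  expr <- make_block_expr(c(50, 50), within_cor = 0.7, seed = 16)
  sweep <- scale_free_fit(expr, betas = c(2, 6, 12))
  expect_identical(sweep$beta, c(2, 6, 12))
  expect_true(all(diff(sweep$mean_k) < 0))
})

test_that("pinning the power bypasses the sweep", {
  expr <- make_block_expr(30, within_cor = 0.8, seed = 17)
  adj <- signed_adjacency(expr, beta = coex_config()$soft_power)
  expect_identical(attr(adj, "beta"), 12L)
})

test_that("kME refinement prunes weak members and dissolves remnants", {
  expr <- make_block_expr(c(50), within_cor = 0.9, n_noise = 30, seed = 18)
  part <- setNames(c(rep("blue", 50), rep("blue", 30)), rownames(expr))
  refined <- reassign_by_kme(expr, part, prune_kme = 0.5,
                             min_module_size = 40)
  expect_true(all(refined[sprintf("noise_g%03d", 1:30)] == "grey"))
  expect_true(all(refined[sprintf("blk1_g%03d", 1:50)] == "blue"))
})

test_that("partitions are stable across identical reruns", {
  expr <- make_block_expr(c(45, 55), within_cor = 0.85, n_noise = 50,
                          seed = 19)
  r1 <- detect_modules(expr, beta = 6)
  r2 <- detect_modules(expr, beta = 6)
  expect_identical(r1$partition, r2$partition)
  expect_identical(r1$eigengenes$eigengenes, r2$eigengenes$eigengenes)
})

test_that("adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(20)
  for (i in 1:5) {
    a <- sample(letters[1:4], 60, replace = TRUE)
    b <- sample(letters[1:3], 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
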