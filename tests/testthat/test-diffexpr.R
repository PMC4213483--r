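test_that("constant paired differences recover the shift exactly", {
  design <- make_paired_design(4, 4)
  genes <- sprintf("g%03d", 1:300)
  set.seed(60)
  expr <- matrix(rnorm(300 * nrow(design)), 300, nrow(design),
                 dimnames = list(genes, design$sample_id))
  neurons <- design$sample_id[design$cell_type == "neuron" &
                                design$genotype == "control"]
  progs <- design$sample_id[design$cell_type == "progenitor" &
                              design$genotype == "control"]
  expr[, neurons] <- expr[, progs] + 0.7
  res <- fit_paired_differentiation(expr, design, "control")
  expect_equal(unname(res$logFC), rep(0.7, 300))
  expect_equal(attr(res, "n_pairs"), 4L)
})

test_that("alternating differences give near-zero logFC, not significant", {
  design <- make_paired_design(6, 2)
  expr <- matrix(0, 50, nrow(design),
                 dimnames = list(sprintf("g%02d", 1:50), design$sample_id))
  set.seed(61)
  expr[] <- rnorm(length(expr), 0, 0.2)
  neurons <- design$sample_id[design$cell_type == "neuron" &
                                design$genotype == "control"]
  # alternating +1/-1 on top of noise for the first feature
  expr[1, neurons] <- expr[1, neurons] + rep(c(1, -1), 3)
  res <- fit_paired_differentiation(expr, design, "control")
  expect_lt(abs(res$logFC[1]), 0.5)
  expect_false(res$significant[1])
})

test_that("pairing preconditions are enforced", {
  design <- make_paired_design(1, 3)
  expr <- matrix(rnorm(10 * nrow(design)), 10, nrow(design),
                 dimnames = list(paste0("g", 1:10), design$sample_id))
  expect_error(fit_paired_differentiation(expr, design, "control"),
               "2 complete")
  only_ts <- design[design$genotype == "TS", ]
  expect_error(fit_interaction(expr[, only_ts$sample_id], only_ts),
               "control and TS")
})

test_that("moderated and plain tests agree on effects, oracle on the t", {
  design <- make_paired_design(6, 6)
  sim_design <- design
  set.seed(62)
  expr <- matrix(rnorm(500 * nrow(design), 0, 0.3), 500, nrow(design),
                 dimnames = list(sprintf("g%03d", 1:500),
                                 design$sample_id))
  mod <- fit_paired_differentiation(expr, sim_design, "control",
                                    moderated = TRUE)
  plain <- fit_paired_differentiation(expr, sim_design, "control",
                                      moderated = FALSE)
  expect_equal(mod$logFC, plain$logFC)
  # plain-t oracle computed by hand from the difference matrix
  D <- coexnet:::paired_differences(expr, sim_design, "control")
  t_hand <- rowMeans(D) / (apply(D, 1, sd) / sqrt(ncol(D)))
  expect_equal(unname(plain$t), unname(t_hand))
  expect_gt(cor(mod$t, plain$t), 0.9)
  expect_gt(cor(rank(mod$p), rank(plain$p)), 0.9)
})

test_that("interaction test is null when both groups shift together", {
  design <- make_paired_design(6, 6)
  set.seed(63)
  expr <- matrix(rnorm(2000 * nrow(design), 0, 0.3), 2000, nrow(design),
                 dimnames = list(sprintf("g%04d", 1:2000),
                                 design$sample_id))
  neurons <- design$sample_id[design$cell_type == "neuron"]
  expr[, neurons] <- expr[, neurons] + 1  # identical effect in both groups
  res <- fit_interaction(expr, design)
  expect_lte(mean(res$p < 0.05), 0.07)
  # and strongly non-null for a genotype-specific effect
  cn <- design$sample_id[design$cell_type == "neuron" &
                           design$genotype == "control"]
  expr2 <- expr
  expr2[1:100, cn] <- expr2[1:100, cn] + 1
  res2 <- fit_interaction(expr2, design)
  expect_gte(mean(res2$p[1:100] < 0.05), 0.9)
})

test_that("zero-variance features get an error-coded missing P", {
  design <- make_paired_design(3, 3)
  expr <- matrix(rnorm(5 * nrow(design)), 5, nrow(design),
                 dimnames = list(paste0("g", 1:5), design$sample_id))
  expr[3, ] <- 7
  res <- fit_interaction(expr, design)
  expect_true(is.na(res$p[3]))
})

test_that("trajectory categories follow the two-criterion rule", {
  mk <- function(p, lfc) data.frame(feature = c("a", "b", "c", "d"),
                                    group = "x", logFC = lfc, t = 0,
                                    p = p, significant = p < 0.05,
                                    stringsAsFactors = FALSE)
  ctrl <- mk(c(0.01, 0.01, 0.60, 0.01), c(1, -1, 0.2, 1))
  ts <- mk(c(0.60, 0.60, 0.01, 0.01), c(0.1, 0.1, -2, 1))
  inter <- data.frame(feature = c("a", "b", "c", "d"), delta = 0, t = 0,
                      p = c(0.01, 0.20, 0.01, 0.01),
                      stringsAsFactors = FALSE)
  cls <- classify_trajectories(ctrl, ts, inter)
  expect_identical(cls$category,
                   c("control_up",  # ctrl sig up, ts not, interaction sig
                     "none",        # interaction not significant
                     "ts_down",     # ts sig down only
                     "none"))       # significant in both groups
})

test_that("swapping group labels swaps the categories exactly", {
  design <- make_paired_design(5, 5)
  sim <- generate_expression(design, modules = list(),
                             n_background = 200,
                             trajectory = trajectory_spec(
                               c(control_up = 20, ts_down = 20)),
                             seed = 64)
  res <- trajectory_analysis(sim$log2, design)
  swapped_design <- design
  swapped_design$genotype <- ifelse(design$genotype == "TS", "control",
                                    "TS")
  res2 <- trajectory_analysis(sim$log2, swapped_design)
  map <- c(control_up = "ts_up", control_down = "ts_down",
           ts_up = "control_up", ts_down = "control_down", none = "none")
  expect_identical(unname(map[res$classification$category]),
                   res2$classification$category)
})

test_that("classification counts equal a brute-force recount", {
  design <- make_paired_design(6, 6)
  sim <- generate_expression(design, modules = list(), n_background = 500,
                             trajectory = trajectory_spec(),
                             seed = 65)
  res <- trajectory_analysis(sim$log2, design)
  cls <- res$classification
  sig_c <- res$control$p < 0.05
  sig_t <- res$ts$p < 0.05
  sig_i <- res$interaction$p[match(res$control$feature,
                                   res$interaction$feature)] < 0.05
  expected_n <- sum(xor(sig_c, sig_t) & sig_i, na.rm = TRUE)
  expect_equal(sum(cls$category != "none"), expected_n)
})
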