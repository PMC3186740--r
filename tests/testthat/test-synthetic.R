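test_that("ground truth honours degenerate mixtures and validates input", {
  gt_u <- generate_ground_truth(10, TISSUES5, breadth_params(1, 0, 0), seed = 3)
  expect_true(all(gt_u$truth == 1L))

  gt_s <- generate_ground_truth(10, TISSUES5, breadth_params(0, 1, 0), seed = 3)
  expect_true(all(rowSums(gt_s$truth) == 1L))

  gt_i <- generate_ground_truth(50, TISSUES5, breadth_params(0, 0, 1), seed = 3)
  expect_true(all(rowSums(gt_i$truth) >= 2 & rowSums(gt_i$truth) <= 4))

  expect_error(generate_ground_truth(10, "heart", breadth_params(1, 0, 0)),
               "2 unique tissue")
  expect_error(breadth_params(0.5, 0.4, 0.2), "sum to 1")
  expect_error(breadth_params(-0.1, 1.1, 0), "non-negative")
  expect_error(generate_ground_truth(10, c("a", "b"), breadth_params(0, 0, 1)),
               ">= 4 tissues")
})

test_that("empirical mixture fractions converge to the planted weights", {
  gt <- generate_ground_truth(1e5, TISSUES5, breadth_params(0.4, 0.2, 0.4),
                              seed = 11)
  b <- rowSums(gt$truth)
  expect_equal(mean(b == 5), 0.4, tolerance = 0.01 / 0.4)
  expect_equal(mean(b == 1), 0.2, tolerance = 0.01 / 0.2)
})

test_that("generators are deterministic given the seed", {
  gt <- generate_ground_truth(200, TISSUES5, seed = 5)
  p <- platform_model("arr", "pma_calls", 0.8, 0.05)
  expect_identical(simulate_pma_calls(gt, p, seed = 9),
                   simulate_pma_calls(gt, p, seed = 9))
  d <- platform_model("ex", "detection_pvalues", 0.8, 0.05)
  expect_identical(simulate_detection_pvalues(gt, d, seed = 9),
                   simulate_detection_pvalues(gt, d, seed = 9))
  r <- platform_model("rs", "rpkm", 0.8, 0.05)
  expect_identical(simulate_rpkm(gt, r, seed = 9), simulate_rpkm(gt, r, seed = 9))
  expect_identical(generate_network(gt$genes, 300, seed = 2),
                   generate_network(gt$genes, 300, seed = 2))
  expect_identical(generate_complexes(gt$genes, 40, seed = 2),
                   generate_complexes(gt$genes, 40, seed = 2))
  expect_identical(simulate_study(n_genes = 100, seed = 4),
                   simulate_study(n_genes = 100, seed = 4))
})

test_that("P/M/A slot-level detection rate matches the planted sensitivity", {
  gt <- generate_ground_truth(6000, TISSUES5, breadth_params(1, 0, 0), seed = 21)
  p <- platform_model("arr", "pma_calls", sensitivity = 0.9,
                      false_positive_rate = 0.05, m_fraction = 0.1)
  sim <- simulate_pma_calls(gt, p, seed = 22)
  # all slots are truly expressed (universal truth): >= 1e5 slots
  expect_gte(nrow(sim$calls), 1e5)
  rate <- mean(sim$calls$call %in% c("P", "M"))
  expect_equal(rate, 0.9, tolerance = 0.01 / 0.9)
  expect_gt(mean(sim$calls$call == "M"), 0)  # marginal calls exist
})

test_that("noiseless P/M/A platform reproduces truth; zero sensitivity yields all A", {
  gt <- generate_ground_truth(100, TISSUES5, seed = 8)
  p0 <- platform_model("arr", "pma_calls", sensitivity = 1e-12,
                       false_positive_rate = 0, m_fraction = 0)
  sim0 <- simulate_pma_calls(gt, p0, seed = 1)
  expect_true(all(sim0$calls$call == "A"))

  p1 <- platform_model("arr", "pma_calls", sensitivity = 1,
                       false_positive_rate = 0, m_fraction = 0)
  sim1 <- simulate_pma_calls(gt, p1, seed = 1)
  m <- pma_gene_calls(sim1$calls, sim1$mapping, "arr")
  expect_identical(unclass(m)[gt$genes, gt$tissues],
                   gt$truth[gt$genes, gt$tissues])
})

test_that("detection p-values live in [0,1] and median-call rate matches sensitivity", {
  gt <- generate_ground_truth(2000, TISSUES5, breadth_params(1, 0, 0), seed = 13)
  d <- platform_model("ex", "detection_pvalues", sensitivity = 0.8,
                      false_positive_rate = 0.05)
  pv <- simulate_detection_pvalues(gt, d, seed = 14)
  expect_true(all(pv$pvalue >= 0 & pv$pvalue <= 1))
  m <- dabg_gene_calls(pv, call_thresholds(), "ex")
  # 1e4 truly expressed gene x tissue cells
  expect_equal(mean(m == 1L), 0.8, tolerance = 0.02 / 0.8)
})

test_that("RPKM cells match the planted tail probability after thresholding", {
  gt <- generate_ground_truth(2000, TISSUES5, breadth_params(1, 0, 0), seed = 17)
  r <- platform_model("rs", "rpkm", sensitivity = 0.9, false_positive_rate = 0.02)
  x <- simulate_rpkm(gt, r, seed = 18)
  expect_true(all(x >= 0))
  expect_identical(colnames(x), paste(TISSUES5, 1, sep = "."))
  expect_equal(mean(x >= 1), 0.9, tolerance = 0.02 / 0.9)  # 1e4 expressed cells
})

test_that("noiseless RPKM separates expressed from unexpressed exactly", {
  gt <- generate_ground_truth(300, TISSUES5, seed = 19)
  r <- platform_model("rs", "rpkm", sensitivity = 1, false_positive_rate = 0)
  x <- simulate_rpkm(gt, r, seed = 20)
  expect_true(all(x[gt$truth == 1L] >= 1))
  expect_true(all(x[gt$truth == 0L] < 1))
})

test_that("increasing sensitivity never decreases expected present calls", {
  gt <- generate_ground_truth(2000, TISSUES5, seed = 23)
  rates <- vapply(c(0.3, 0.6, 0.9), function(s) {
    d <- platform_model("ex", "detection_pvalues", s, 0.01)
    m <- dabg_gene_calls(simulate_detection_pvalues(gt, d, seed = 24),
                         platform = "ex")
    sum(m)
  }, 0)
  expect_true(all(diff(rates) > 0))
})

test_that("random networks are simple graphs of the requested size", {
  genes <- sprintf("g%03d", 1:50)
  expect_equal(nrow(generate_network(genes, 0, seed = 1)), 0L)
  net2 <- generate_network(c("a", "b"), 1, seed = 1)
  expect_identical(unname(c(net2$gene_a, net2$gene_b)), c("a", "b"))

  net <- generate_network(genes, 100, seed = 5)
  expect_equal(nrow(net), 100L)
  expect_true(all(net$gene_a != net$gene_b))
  expect_false(anyDuplicated(paste(net$gene_a, net$gene_b)) > 0)
  expect_true(all(net$gene_a < net$gene_b))  # canonical orientation
  expect_error(generate_network(c("a", "b"), 2), "exceeds")
})

test_that("random complexes have valid sizes and injected duplicates", {
  genes <- sprintf("g%03d", 1:200)
  expect_length(generate_complexes(genes, 0, seed = 1), 0L)
  cs3 <- generate_complexes(genes, 50, size_probs = c(1), seed = 2)
  expect_true(all(lengths(cs3) == 3L))
  cs <- generate_complexes(genes, 1000, duplicate_rate = 0.2, seed = 3)
  n_unique <- length(unique(vapply(cs, paste, "", collapse = ",")))
  # ~200 injected duplicates, binomial sd ~ sqrt(1000*.2*.8) ~ 12.6
  expect_equal(n_unique, 800, tolerance = 50 / 800)
})
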