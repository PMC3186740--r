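test_that("interaction filtering keeps exactly the fully measured edges", {
  genes <- sprintf("g%02d", 1:10)
  net <- interaction_network(data.frame(
    gene_a = c("g01", "g02", "g03", "g04"),
    gene_b = c("g02", "g03", "g09", "g10")))
  a <- tiny_call_matrix(genes[1:8], c("heart", "liver"), list(), "a")
  b <- tiny_call_matrix(genes, c("heart", "liver"), list(), "b")
  kept <- filter_interactions(net, list(a, b))
  # g09/g10 are missing from platform a: those edges drop
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$gene_b, c("g02", "g03"))
  expect_equal(nrow(filter_interactions(kept, list(a, b))), 2L)  # idempotent
  empty <- interaction_network(data.frame(gene_a = character(0),
                                          gene_b = character(0)))
  expect_equal(nrow(filter_interactions(empty, list(a))), 0L)
})

test_that("planted exclusions are filtered at the planted rate", {
  genes <- sprintf("g%03d", 1:100)
  net <- generate_network(genes, 100, seed = 71)
  # exclude from one platform every gene appearing in the first 30 edges
  excluded <- unique(c(net$gene_a[1:30], net$gene_b[1:30]))
  a <- tiny_call_matrix(setdiff(genes, excluded), c("heart",  "liver"), list(), "a")
  b <- tiny_call_matrix(genes, c("heart", "liver"), list(), "b")
  kept <- filter_interactions(net, list(a, b))
  touches <- net$gene_a %in% excluded | net$gene_b %in% excluded
  expect_equal(nrow(kept), 100L - sum(touches))
})

test_that("interaction presence requires both partners expressed", {
  genes <- c("A", "B", "C")
  m <- tiny_call_matrix(genes, c("heart", "liver", "testis"), list(
    heart = c("A"), liver = c("A", "B"), testis = c("B", "C")), "toy")
  net <- interaction_network(data.frame(gene_a = "A", gene_b = "B"))
  pres <- interaction_presence(net, m)
  # A in {heart, liver}, B in {liver, testis}: edge present only in liver
  expect_equal(pres$edges$breadth, 1L)
  expect_equal(pres$per_tissue$present_count,
               c(heart = 0, liver = 1, testis = 0), ignore_attr = TRUE)
  expect_true(all(pres$per_tissue$present_count +
                  pres$per_tissue$absent_count == nrow(net)))

  both_univ <- tiny_call_matrix(genes, c("heart", "liver"),
                                list(heart = genes, liver = genes), "toy")
  expect_equal(interaction_presence(net, both_univ)$edges$breadth, 2L)

  nowhere <- tiny_call_matrix(genes, c("heart", "liver"),
                              list(heart = "B", liver = "B"), "toy")
  expect_equal(interaction_presence(net, nowhere)$edges$breadth, 0L)

  bad_net <- interaction_network(data.frame(gene_a = "A", gene_b = "Z"))
  expect_error(interaction_presence(bad_net, m), "missing from the call matrix")
})

test_that("complex filtering drops small, unmeasured and duplicate complexes", {
  genes <- sprintf("g%02d", 1:12)
  cs <- complex_set(list(
    ok = c("g01", "g02", "g03"),
    too_small = c("g01", "g02"),
    unmeasured = c("g01", "g02", "g12"),
    dup_of_ok = c("g03", "g02", "g01"),
    ok2 = c("g04", "g05", "g06", "g07")))
  m <- tiny_call_matrix(genes[1:11], c("heart", "liver"), list(), "a")
  kept <- filter_complexes(cs, list(m))
  expect_setequal(names(kept), c("ok", "ok2"))  # first name wins on duplicates
  # min_size is configurable
  kept2 <- filter_complexes(cs, list(m), min_size = 4)
  expect_identical(names(kept2), "ok2")
})

test_that("complex classification matches the truth-table over all member patterns", {
  tissues <- "t1"
  for (n_members in 3:5) {
    members <- sprintf("m%d", seq_len(n_members))
    cs <- complex_set(stats::setNames(list(members), "cx"))
    for (pattern in 0:(2^n_members - 1)) {
      bits <- as.integer(intToBits(pattern))[seq_len(n_members)]
      m <- call_matrix(matrix(bits, n_members, 1,
                              dimnames = list(members, tissues)), "p")
      cls <- classify_complexes(cs, m)
      k <- sum(bits)
      expected <- if (k == n_members) "complete" else if (k <= 1) "absent" else "partial"
      expect_equal(cls$class, expected)
      expect_equal(cls$n_expressed, k)
      expect_equal(cls$detection_percentage, 100 * k / n_members)
    }
  }
})

test_that("flipping a member call to present never demotes a complex", {
  rank <- c(absent = 1, partial = 2, complete = 3)
  set.seed(81)
  members <- sprintf("m%d", 1:4)
  cs <- complex_set(list(cx = members))
  for (i in 1:20) {
    bits <- sample(0:1, 4, replace = TRUE)
    if (all(bits == 1)) bits[1] <- 0
    m0 <- call_matrix(matrix(bits, 4, 1, dimnames = list(members, "t")), "p")
    j <- sample(which(bits == 0), 1)
    bits1 <- bits; bits1[j] <- 1
    m1 <- call_matrix(matrix(bits1, 4, 1, dimnames = list(members, "t")), "p")
    c0 <- classify_complexes(cs, m0); c1 <- classify_complexes(cs, m1)
    expect_gte(rank[c1$class], rank[c0$class])
    expect_gte(c1$detection_percentage, c0$detection_percentage)
  }
})

test_that("a complete 3-member complex implies its within-complex edges are present", {
  st <- simulate_study(n_genes = 150, n_edges = 400, n_complexes = 60, seed = 33)
  m <- derive_calls(st)$rna_seq
  cs <- filter_complexes(st$complexes, list(m))
  cls <- classify_complexes(cs, m)
  pres <- interaction_presence(st$network, m)
  edge_present <- pres$edges
  key <- paste(edge_present$gene_a, edge_present$gene_b)
  complete <- cls[cls$class == "complete", ]
  for (i in seq_len(min(nrow(complete), 50))) {
    members <- cs[[complete$complex_name[i]]]
    pairs <- utils::combn(sort(members), 2)
    in_net <- match(paste(pairs[1, ], pairs[2, ]), key)
    in_net <- in_net[!is.na(in_net)]
    if (length(in_net))
      expect_true(all(edge_present[in_net, complete$tissue[i]] == 1))
  }
})

test_that("complex concordance is 1 for identical inputs and flags constant vectors", {
  st <- simulate_study(n_genes = 200, n_complexes = 40, seed = 35)
  m <- derive_calls(st)$gene_atlas   # mid-sensitivity: percentages vary
  cs <- filter_complexes(st$complexes, list(m))
  cls <- classify_complexes(cs, m)
  same <- complex_concordance(cls, cls)
  ok <- !same$per_tissue$degenerate
  expect_true(any(ok))
  expect_true(all(same$per_tissue$correlation[ok] == 1))
  expect_equal(same$summary$mean_correlation, 1)

  # constant detection percentages on one side: degenerate, excluded
  all_on <- call_matrix(matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m)),
                        "allon")
  cls_const <- classify_complexes(cs, all_on)
  deg <- complex_concordance(cls_const, cls_const)
  expect_true(all(deg$per_tissue$degenerate))
  expect_true(is.na(deg$summary$mean_correlation))
})

test_that("diverging sensitivities lower the complex-detection correlation", {
  st <- simulate_study(n_genes = 400, n_complexes = 80, seed = 37)
  gt <- st$truth
  run <- function(s, seed) {
    pf <- platform_model("p", "rpkm", s, 0.01)
    rpkm_gene_calls(simulate_rpkm(gt, pf, seed = seed), platform = "p")
  }
  m_hi <- run(1.0, 91); m_mid <- run(0.8, 92); m_lo <- run(0.5, 93)
  cs <- filter_complexes(st$complexes, list(m_hi))
  cor_of <- function(a, b) complex_concordance(classify_complexes(cs, a),
                                               classify_complexes(cs, b))$summary$mean_correlation
  c_close <- cor_of(m_hi, m_mid)
  c_far <- cor_of(m_hi, m_lo)
  expect_gt(c_close, 0); expect_lt(c_close, 1)
  expect_lt(c_far, c_close)
})
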