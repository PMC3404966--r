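test_that("bh_adjust matches hand and brute-force step-up computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  for (n in c(3, 17, 1000)) {
    set.seed(n)
    p <- runif(n)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("build_network keeps exactly the rows at or below the threshold", {
  scores <- data.frame(mirna_id = c("m1", "m1"), gene_id = c("g1", "g2"),
                       coefficient = c(0.4, 0.2), pvalue = c(0.001, 0.04),
                       qvalue = c(0.01, 0.05))
  expect_identical(nrow(build_network(scores, 0.02)), 1L)
  expect_identical(nrow(build_network(scores, 1.0)), 2L)
  # smoothed p-values are strictly positive, so a zero threshold empties it
  expect_identical(nrow(build_network(scores, 0)), 0L)
  dup <- rbind(scores, scores[1, ])
  expect_error(build_network(dup, 1), "duplicate")
})

test_that("bipartite handshake: connectivities on each side sum to the edges", {
  set.seed(12)
  scores <- expand.grid(mirna_id = paste0("m", 1:4),
                        gene_id = paste0("g", 1:6),
                        stringsAsFactors = FALSE)
  scores$coefficient <- runif(nrow(scores))
  scores$pvalue <- runif(nrow(scores))
  scores$qvalue <- bh_adjust(scores$pvalue)
  edges <- build_network(scores, 0.8)
  k <- node_connectivity(edges)
  expect_identical(sum(k$k[k$node_class == "miRNA"]), nrow(edges))
  expect_identical(sum(k$k[k$node_class == "gene"]), nrow(edges))
})

test_that("hub cutoff arithmetic follows the 0.75 x max rule per class", {
  edges <- data.frame(
    mirna_id = c(rep("m1", 80), rep("m2", 75), rep("m3", 10)),
    gene_id = paste0("g", c(1:80, 1:75, 1:10)))
  rand <- data.frame(mirna_id = rep(paste0("r", 1:10), each = 10),
                     gene_id = paste0("g", rep(1:10, 10)))
  # randomized max miRNA connectivity is 100 after inflating one node
  rand$mirna_id[1:10] <- "r1"
  rand <- rbind(rand, data.frame(mirna_id = "r1", gene_id = paste0("h", 1:90)))
  h <- detect_hubs(edges, rand)
  expect_identical(max(node_connectivity(rand)$k[
    node_connectivity(rand)$node_class == "miRNA"]), 100L)
  hm <- h[h$node_class == "miRNA", ]
  expect_true(hm$is_hub[hm$node_id == "m1"])    # 80 > 75
  expect_false(hm$is_hub[hm$node_id == "m2"])   # 75 not > 75
  expect_false(hm$is_hub[hm$node_id == "m3"])
  expect_equal(unique(hm$cutoff_used), 75)
})

test_that("hand-computed toy network, alternative rule, and edge cases", {
  edges <- data.frame(mirna_id = c("m1", "m1", "m2"),
                      gene_id = c("g1", "g2", "g1"))
  rand <- data.frame(mirna_id = c("rm1", "rm2"), gene_id = c("rg1", "rg1"))
  h <- detect_hubs(edges, rand)
  # randomized miRNA max = 1 -> cutoff 0.75; randomized gene max = 2 -> 1.5
  expect_identical(h$is_hub[h$node_id == "m1" & h$node_class == "miRNA"], TRUE)
  expect_identical(h$is_hub[h$node_id == "m2" & h$node_class == "miRNA"], TRUE)
  expect_identical(h$is_hub[h$node_id == "g1" & h$node_class == "gene"], TRUE)
  expect_identical(h$is_hub[h$node_id == "g2" & h$node_class == "gene"], FALSE)

  h75 <- detect_hubs(edges, rand, rule = "percentile75")
  expect_true(all(h75$cutoff_used[h75$node_class == "miRNA"] == 1))

  empty <- edges[0, ]
  expect_identical(nrow(detect_hubs(empty, rand)), 0L)
  expect_warning(h0 <- detect_hubs(edges, empty), "empty randomized")
  expect_true(all(h0$is_hub))

  # hub sets shrink as the randomized maximum grows
  bigger <- rbind(rand, data.frame(mirna_id = rep("rm3", 3),
                                   gene_id = paste0("rg", 1:3)))
  h2 <- detect_hubs(edges, bigger)
  expect_lte(sum(h2$is_hub), sum(h$is_hub))
})

test_that("cumulative-hit curves count truth pairs among top ranks", {
  ranked <- data.frame(mirna_id = c("m1", "m1", "m2"),
                       gene_id = c("gA", "gB", "gC"),
                       rank = 1:3)
  truth <- data.frame(mirna_id = "m1", gene_id = "gB")
  curve <- rank_evaluation(ranked, truth)
  expect_equal(curve$hits, c(0, 1, 1))

  # a truth pair outside the universe is logged and never hit
  truth2 <- rbind(truth, data.frame(mirna_id = "mX", gene_id = "gX"))
  expect_message(curve2 <- rank_evaluation(ranked, truth2), "absent")
  expect_equal(curve2$hits, c(0, 1, 1))

  expect_error(rank_evaluation(transform(ranked, rank = c(1, 1, 2)), truth),
               "unique")
})

test_that("merging takes the best rank per pair and re-ranks", {
  m1 <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                   rank = c(5, 1))
  m2 <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                   rank = c(2, 4))
  merged <- merge_ranks(list(m1, m2))
  expect_equal(merged$best_rank[merged$mirna_id == "m1"], 2)
  expect_identical(merged$rank, 1:2)
  expect_identical(merged$mirna_id[1], "m2")  # best_rank 1 wins
})

test_that("random rankings hit near the hypergeometric expectation", {
  # 100 pairs, 10 truths: E[hits in top 10] = 10 * 10 / 100 = 1
  pairs <- data.frame(mirna_id = "m", gene_id = paste0("g", 1:100))
  truth <- pairs[1:10, ]
  set.seed(30)
  hits10 <- vapply(1:300, function(r) {
    ranked <- pairs[sample.int(100), ]
    ranked$rank <- 1:100
    rank_evaluation(ranked, truth)$hits[10]
  }, numeric(1))
  expect_equal(mean(hits10), 1, tolerance = 0.2)
})

test_that("SIF export writes one line per edge", {
  edges <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"))
  p <- write_sif(edges, tempfile(fileext = ".sif"))
  expect_identical(readLines(p), c("m1\ttargets\tg1", "m2\ttargets\tg2"))
})
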