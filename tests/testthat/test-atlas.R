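test_that("UPGMA dendrogram reproduces the hand-computed merge sequence", {
  # d(1,2) = 0.1, d(1,3) = 0.5, d(2,3) = 0.6
  sim <- 1 - matrix(c(0, 0.1, 0.5,
                      0.1, 0, 0.6,
                      0.5, 0.6, 0), 3, 3)
  dend <- build_dendrogram(sim)
  expect_equal(dend$hclust$height, c(0.1, 0.55))
  expect_equal(sort(dend$hclust$merge[1, ]), c(-2, -1))
})

test_that("two-block similarity yields the planted 2-cut", {
  tb <- two_block_similarity()
  part <- cut_dendrogram(build_dendrogram(tb$similarity), 2)
  # agreement up to label swap, verified against every ROI pair
  same_pred <- unname(outer(part, part, `==`))
  same_true <- outer(tb$labels, tb$labels, `==`)
  expect_identical(same_pred, same_true)
})

test_that("dendrogram is equivariant under ROI permutation", {
  set.seed(3)
  for (rep in 1:5) {
    s <- stats::cov2cor(crossprod(matrix(rnorm(100), 10)))
    perm <- sample(10)
    p1 <- cut_dendrogram(build_dendrogram(s), 3)
    p2 <- cut_dendrogram(build_dendrogram(s[perm, perm]), 3)
    expect_identical(unname(outer(p1[perm], p1[perm], `==`)),
                     unname(outer(p2, p2, `==`)))
  }
})

test_that("tree cuts are nested and hit the degenerate levels", {
  set.seed(11)
  s <- stats::cov2cor(crossprod(matrix(rnorm(30 * 12), 30)))
  dend <- build_dendrogram(s)
  expect_equal(unname(cut_dendrogram(dend, 1)), rep(1, 12))
  expect_equal(length(unique(cut_dendrogram(dend, 12))), 12)
  expect_error(cut_dendrogram(dend, 0), "M must lie")
  expect_error(cut_dendrogram(dend, 13), "M must lie")
  for (m in 1:11) {
    coarse <- cut_dendrogram(dend, m)
    fine <- cut_dendrogram(dend, m + 1)
    # each fine module maps into exactly one coarse module
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
})

test_that("Newman modularity matches closed forms and igraph", {
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
  expect_equal(newman_modularity(adj, rep(1:2, each = 4)), 0.5)
  expect_equal(newman_modularity(adj, rep(1, 8)), 0)
  expect_error(newman_modularity(matrix(0, 4, 4), rep(1, 4)), "edgeless")
  # independent cross-check on weighted random graphs
  set.seed(7)
  for (rep in 1:5) {
    w <- matrix(runif(15 * 15), 15); w <- w * t(w); diag(w) <- 0
    labs <- sample(1:3, 15, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(newman_modularity(w, labs),
                 igraph::modularity(g, labs, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("random partitions of an ER graph have near-zero modularity", {
  set.seed(21)
  for (rep in 1:100) {
    a <- matrix(rbinom(60 * 60, 1, 0.3), 60)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]; diag(a) <- 0
    q <- newman_modularity(a, sample(1:4, 60, replace = TRUE))
    expect_lt(abs(q), 0.05)
  }
})

test_that("Sorensen similarity handles hand cases and invariances", {
  e1 <- rbind(c(1, 2), c(2, 3))
  e2 <- rbind(c(3, 2), c(3, 4))   # shares edge {2,3} after canonicalization
  expect_equal(sorensen_similarity(e1, e1), 1)
  expect_equal(sorensen_similarity(e1, rbind(c(5, 6))), 0)
  expect_equal(sorensen_similarity(e1, e2), 0.5)
  expect_equal(sorensen_similarity(e1, e2), sorensen_similarity(e2, e1))
  expect_error(sorensen_similarity(NULL, NULL), "empty")
  # node relabeling leaves S unchanged
  relab <- c(10, 20, 30, 40, 50, 60)
  r1 <- matrix(relab[e1], ncol = 2); r2 <- matrix(relab[e2], ncol = 2)
  expect_equal(sorensen_similarity(r1, r2), 0.5)
})

test_that("cross-modularity is exact on a perfect block pair and invariant
           to relabeling", {
  pb <- perfect_block_pair(k = 4, n_per_block = 5)
  rep4 <- cross_modularity(pb$pair, 4)
  expect_equal(rep4$mean_sorensen, 1)
  expect_equal(rep4$q_structural, 0.75)   # 4 equal disconnected blocks
  expect_equal(rep4$q_functional, 0.75)
  expect_equal(rep4$cross_modularity, (0.75 * 0.75 * 1)^(1 / 3))
  perm <- sample(nrow(pb$pair$sc))
  pp <- connectome_pair(pb$pair$sc[perm, perm], pb$pair$fc[perm, perm])
  expect_equal(cross_modularity(pp, 4)$cross_modularity,
               rep4$cross_modularity)
})

test_that("shuffling functional edges lowers cross-modularity", {
  set.seed(13)
  worse <- 0
  for (rep in 1:20) {
    sim <- simulate_multimodal_connectome(n_roi = 60, m_coarse = 4,
                                          m_fine = 4, p_in = 0.6,
                                          p_out = 0.05, seed = rep)
    x_match <- cross_modularity(sim$pair, 4)$cross_modularity
    perm <- sample(60)
    fc_shuf <- sim$pair$fc[perm, perm]   # destroys SC/FC alignment
    x_shuf <- cross_modularity(connectome_pair(sim$pair$sc, fc_shuf),
                               4)$cross_modularity
    worse <- worse + (x_shuf < x_match)
  }
  expect_gte(worse, 18)
})

test_that("select_optimal_level recovers a planted 4-module pair and
           breaks ties toward small M", {
  sim <- simulate_multimodal_connectome(n_roi = 80, m_coarse = 4,
                                        m_fine = 4, p_in = 0.6,
                                        p_out = 0.05, seed = 5)
  sel <- select_optimal_level(sim$pair, 2:8)
  expect_equal(sel$m_star, 4)
  xs <- sel$cross_modularity
  expect_equal(sel$m_star, as.integer(names(xs)[which.max(xs)]))
  expect_error(select_optimal_level(sim$pair, integer()), "empty")
})

test_that("a nested 2-in-4 hierarchy scores at least as high at M = 4 as
           at M = 3 on average", {
  x3 <- x4 <- numeric(8)
  for (s in 1:8) {
    sim <- simulate_multimodal_connectome(n_roi = 80, m_coarse = 2,
                                          m_fine = 4, p_in = 0.6,
                                          p_out = 0.05, seed = 100 + s)
    x3[s] <- cross_modularity(sim$pair, 3)$cross_modularity
    x4[s] <- cross_modularity(sim$pair, 4)$cross_modularity
  }
  expect_gte(mean(x4), mean(x3))
})

test_that("connectome_pair validates its invariants", {
  sc <- matrix(c(0, 2, 2, 0), 2); fc <- diag(2)
  expect_s3_class(connectome_pair(sc, fc), "connectome_pair")
  expect_error(connectome_pair(sc + 0.5, fc), "integer")
  expect_error(connectome_pair(-sc, fc), "nonnegative")
  expect_error(connectome_pair(sc, fc * 2), "diagonal")
  bad <- sc; bad[1, 2] <- 5
  expect_error(connectome_pair(bad, fc), "symmetric")
})
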