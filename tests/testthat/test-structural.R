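test_that("binarization is correct, idempotent and validates input", {
  expect_equal(binarize_connectome(matrix(c(0, 3, 3, 0), 2)),
               matrix(c(0, 1, 1, 0), 2))
  z <- matrix(0, 3, 3)
  expect_equal(binarize_connectome(z), z)
  set.seed(1)
  m <- matrix(rpois(25, 1), 5); m <- m + t(m); diag(m) <- 0
  expect_identical(binarize_connectome(binarize_connectome(m)),
                   binarize_connectome(m))
  expect_error(binarize_connectome(-m), "nonnegative")
})

test_that("inter-module connectivity matches the hand-counted toy", {
  a <- matrix(0, 4, 4)
  a[1, 3] <- a[3, 1] <- 1   # crosses modules
  a[2, 4] <- a[4, 2] <- 1   # crosses modules
  a[1, 2] <- a[2, 1] <- 1   # inside module 1
  mg <- intermodule_connectivity(a, c(1, 1, 2, 2))
  expect_equal(mg$weights[1, 2], 2)
  expect_equal(mg$weights[2, 1], 2)
  expect_equal(unname(mg$intra), c(1, 0))
  expect_equal(unname(module_degree(mg)), c(2, 2))
  expect_error(intermodule_connectivity(a, c(1, 1, 2)), "labels length")
  # degenerate partitions
  mg0 <- intermodule_connectivity(matrix(0, 4, 4), c(1, 1, 2, 2))
  expect_true(all(mg0$weights == 0) && all(mg0$intra == 0))
  mg1 <- intermodule_connectivity(a, rep(1, 4))
  expect_equal(sum(mg1$weights), 0)
  expect_equal(unname(mg1$intra), 3)
})

test_that("degree profiles obey the handshake identity at every level", {
  set.seed(2)
  for (rep in 1:10) {
    sim <- simulate_multimodal_connectome(n_roi = 60, m_coarse = 3,
                                          m_fine = 6, p_in = 0.5,
                                          p_out = 0.1, seed = rep)
    b <- binarize_connectome(sim$pair$sc)
    for (labels in list(sim$hierarchy$roi_coarse, sim$hierarchy$roi_fine)) {
      mg <- intermodule_connectivity(b, labels)
      expect_equal(sum(module_degree(mg)),
                   2 * sum(mg$weights[upper.tri(mg$weights)]))
    }
  }
})

test_that("fine-level module graphs aggregate exactly to the coarse level", {
  sim <- simulate_multimodal_connectome(n_roi = 40, m_coarse = 2,
                                        m_fine = 4, p_in = 0.6,
                                        p_out = 0.1, seed = 9)
  b <- binarize_connectome(sim$pair$sc)
  hier <- sim$hierarchy
  mg_f <- intermodule_connectivity(b, hier$roi_fine)
  mg_c <- intermodule_connectivity(b, hier$roi_coarse)
  # summing fine weights by coarse membership reproduces coarse weights;
  # fine links inside one coarse module become intra-module
  agg <- rowsum(t(rowsum(mg_f$weights, hier$coarse_of_fine)),
                hier$coarse_of_fine)
  expect_equal(unname(agg[1, 2]), unname(mg_c$weights[1, 2]))
  intra_from_fine <- sum(mg_f$intra) +
    sum(mg_f$weights[upper.tri(mg_f$weights)] *
          outer(hier$coarse_of_fine, hier$coarse_of_fine,
                `==`)[upper.tri(mg_f$weights)])
  expect_equal(intra_from_fine, sum(mg_c$intra))
})

test_that("an isolated module has zero degree", {
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 1] <- 1
  mg <- intermodule_connectivity(a, c(1, 2, 3, 3, 3, 3))
  expect_equal(unname(module_degree(mg)), c(1, 1, 0))
})

test_that("flipping group labels negates every structural t", {
  set.seed(3)
  coh <- data.frame(group = rep(c("control", "tbi"), c(8, 6)),
                    age = rnorm(14), eddy_motion_mean = rlnorm(14))
  y <- matrix(rnorm(14 * 5), 14)
  dsn <- make_design(coh, c("age", "eddy_motion_mean"))
  coh_flip <- coh
  coh_flip$group <- ifelse(coh$group == "control", "tbi", "control")
  dsn_flip <- make_design(coh_flip, c("age", "eddy_motion_mean"))
  r1 <- structural_group_comparison(y, dsn, n_perm = 50, seed = 4)
  r2 <- structural_group_comparison(y, dsn_flip, n_perm = 50, seed = 4)
  expect_equal(r2$t, -r1$t)
})

test_that("group comparison output mirrors the effect-report contract", {
  set.seed(6)
  coh <- data.frame(group = rep(c("control", "tbi"), c(10, 8)),
                    age = rnorm(18), eddy_motion_mean = rlnorm(18))
  dsn <- make_design(coh, c("age", "eddy_motion_mean"))
  y <- matrix(rnorm(18 * 3), 18,
              dimnames = list(NULL, paste0("module_", 1:3)))
  rep_ <- structural_group_comparison(y, dsn, n_perm = 99, seed = 1)
  expect_named(rep_, c("feature", "t", "df", "p_param", "p_perm", "g",
                       "ci_low", "ci_high", "discarded"))
  expect_true(all(sign(rep_$g) == sign(rep_$t) | rep_$t == 0))
  expect_true(all(rep_$p_perm > 0 & rep_$p_perm <= 1))
  expect_identical(rep_$discarded, rep_$p_perm >= 0.05)
})
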