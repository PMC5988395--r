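test_that("connectome simulation is seeded and validates parameters", {
  s1 <- simulate_multimodal_connectome(n_roi = 40, m_coarse = 2,
                                       m_fine = 4, seed = 3)
  s2 <- simulate_multimodal_connectome(n_roi = 40, m_coarse = 2,
                                       m_fine = 4, seed = 3)
  expect_identical(s1$pair$sc, s2$pair$sc)
  expect_identical(s1$pair$fc, s2$pair$fc)
  expect_error(simulate_multimodal_connectome(p_in = 0.1, p_out = 0.5),
               "p_in")
  expect_error(crossmod:::make_hierarchy(40, 4, 2), "infeasible")
})

test_that("structureless pairs score low and flat in cross-modularity", {
  flat <- simulate_multimodal_connectome(n_roi = 60, m_coarse = 4,
                                         m_fine = 4, p_in = 0.3,
                                         p_out = 0.3, coupling = 0.05,
                                         seed = 2)
  xs <- select_optimal_level(flat$pair, 2:6)$cross_modularity
  struct <- simulate_multimodal_connectome(n_roi = 60, m_coarse = 4,
                                           m_fine = 4, p_in = 0.6,
                                           p_out = 0.05, seed = 2)
  x4 <- cross_modularity(struct$pair, 4)$cross_modularity
  expect_lt(max(xs), x4)
})

test_that("sway trajectories obey the protocol contract", {
  flat <- simulate_sway(0, protocol = "sot", seed = 1)
  expect_equal(nrow(flat), 2000)        # 20 s at 100 Hz
  expect_equal(path_length(flat), 0)
  set.seed(4)
  pl <- sapply(c(0.02, 0.05, 0.1), function(s)
    mean(replicate(30, path_length(simulate_sway(s, duration = 2)))))
  expect_true(all(diff(pl) > 0))
  expect_error(simulate_sway(-1), "sway_sd")
  # goal-directed protocols drift toward the target
  los <- simulate_sway(0.05, duration = 3, protocol = "los",
                       target = c(0, 1), seed = 5)
  expect_gt(directional_control(los, c(0, 1)), 50)
})

test_that("cohort generation records ground truth and validates effects", {
  coh <- simulate_cohort(null_effect_spec(), n_control = 5, n_tbi = 3,
                         n_roi = 40, m_coarse = 4, m_fine = 8,
                         grid = c(6, 6, 6), t_len = 60, seed = 1)
  expect_equal(nrow(coh$cohort), 8)
  expect_length(coh$connectomes, 8)
  expect_length(coh$bold, 8)
  expect_equal(dim(coh$bold[[1]]), c(60, 216))
  expect_equal(nrow(coh$scores), 8)
  expect_named(coh$truth$effects, names(effect_spec()), ignore.order = TRUE)
  expect_length(coh$truth$variance_descriptor, 8)
  expect_error(simulate_cohort(effect_spec(degree_deficit_modules = 99),
                               n_roi = 40, m_coarse = 4, m_fine = 8,
                               grid = c(6, 6, 6), t_len = 60),
               "coarse modules")
  # determinism under the master seed
  coh2 <- simulate_cohort(null_effect_spec(), n_control = 5, n_tbi = 3,
                          n_roi = 40, m_coarse = 4, m_fine = 8,
                          grid = c(6, 6, 6), t_len = 60, seed = 1)
  expect_identical(coh$scores, coh2$scores)
  expect_identical(coh$connectomes[[3]]$sc, coh2$connectomes[[3]]$sc)
})

test_that("planted degree injections shift exactly the named modules", {
  eff <- effect_spec(degree_deficit_modules = 2, degree_deficit_d = 1,
                     degree_surplus_module = 1, degree_surplus_d = 0,
                     variance_surplus_module = 1, variance_surplus_d = 0,
                     frontal_amplitude = 0, behavior_r = 0)
  coh <- simulate_cohort(eff, n_control = 12, n_tbi = 12, n_roi = 80,
                         m_coarse = 4, m_fine = 8, grid = c(6, 6, 6),
                         t_len = 60, seed = 2)
  deg <- cohort_module_degrees(coh$connectomes, coh$hierarchy$roi_coarse)
  ctrl <- coh$cohort$group == "control"
  gap <- colMeans(deg[ctrl, ]) - colMeans(deg[!ctrl, ])
  k_planted <- round(coh$truth$sd_coarse[2])
  expect_gt(gap[2], 0.5 * k_planted)
  expect_lt(max(abs(gap[-2])), gap[2])
})

test_that("IO round-trips: connectome TSV, NIfTI volumes, config YAML", {
  tmp <- withr::local_tempdir()
  m <- matrix(rpois(16, 3), 4); m <- m + t(m); diag(m) <- 0
  colnames(m) <- paste0("roi", 1:4)
  p1 <- file.path(tmp, "sc.tsv")
  write_connectome_tsv(m, p1)
  m2 <- read_connectome_tsv(p1)
  expect_equal(unname(m2), unname(m))
  labs <- sample(1:4, 27, replace = TRUE)
  p2 <- file.path(tmp, "parc.nii.gz")
  write_parcellation_nifti(labs, c(3, 3, 3), p2)
  expect_equal(as.vector(read_parcellation_nifti(p2)), labs)
  x <- matrix(rnorm(10 * 27), 10)
  p3 <- file.path(tmp, "bold.nii.gz")
  write_bold_nifti(x, c(3, 3, 3), p3)
  expect_equal(read_bold_nifti(p3), x, tolerance = 1e-6)
  cfg <- analysis_config(n_perm = 250, alpha = 0.01)
  p4 <- file.path(tmp, "config.yaml")
  write_config(cfg, p4)
  expect_equal(read_config(p4), cfg)
})

test_that("trajectory TSV reader reconstructs trials", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    t = rep(seq(0, 0.04, by = 0.01), 2),
    x = c(0:4, 0:4 * 2), y = 0,
    trial = rep(1:2, each = 5),
    protocol = rep(c("sot", "los"), each = 5),
    condition = rep(c(1, 3), each = 5),
    fall = FALSE, target_x = 1, target_y = 0)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  trials <- read_trajectories_tsv(tmp)
  expect_equal(nrow(trials), 2)
  expect_equal(trials$protocol, c("sot", "los"))
  expect_equal(path_length(trials$traj[[1]]), 4)
  expect_equal(directional_control(trials$traj[[2]], trials$target[[2]]),
               100)
})
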