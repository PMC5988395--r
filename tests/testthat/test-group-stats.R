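test_that("GLM contrast t equals the classical pooled two-sample t", {
  set.seed(1)
  for (rep in 1:50) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    y <- rnorm(n1 + n2)
    grp <- rep(c("control", "tbi"), c(n1, n2))
    dsn <- make_design(data.frame(group = grp))
    t_glm <- glm_contrast_ttest(y, dsn$X, dsn$contrasts$control_minus_tbi)$t
    t_ref <- t.test(y[grp == "control"], y[grp == "tbi"],
                    var.equal = TRUE)$statistic
    expect_equal(t_glm, unname(t_ref), tolerance = 1e-10)
  }
})

test_that("GLM contrast edge cases: zero contrast, confounds, negation,
           rank deficiency", {
  set.seed(2)
  grp <- rep(c("control", "tbi"), c(10, 10))
  # age confound: TBI subjects older, y driven purely by age
  age <- rnorm(20) + 2 * (grp == "tbi")
  y <- 3 * age + rnorm(20, sd = 0.5)
  dsn <- make_design(data.frame(group = grp, age = age), "age")
  res0 <- glm_contrast_ttest(y, dsn$X, c(0, 0, 0))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_param, 1)
  dsn_no <- make_design(data.frame(group = grp))
  t_naive <- glm_contrast_ttest(y, dsn_no$X,
                                dsn_no$contrasts$control_minus_tbi)$t
  resg <- glm_contrast_ttest(y, dsn$X, dsn$contrasts$control_minus_tbi)
  expect_gt(abs(t_naive), 3)                # spurious effect without age
  expect_lt(abs(resg$t), qt(0.995, resg$df))  # removed with age in the model
  resn <- glm_contrast_ttest(y, dsn$X, dsn$contrasts$tbi_minus_control)
  expect_equal(resn$t, -resg$t)
  expect_equal(resn$p_param, resg$p_param)
  X_bad <- cbind(dsn$X, age2 = dsn$X[, "age"])
  expect_error(glm_contrast_ttest(y, X_bad, c(1, -1, 0, 0)), "age2")
})

test_that("permutation p handles constant, extreme and monotone cases", {
  grp <- rep(c("control", "tbi"), each = 10)
  expect_error(permutation_pvalue(function(p) 1, 20, n_perm = 0), "n_perm")
  p_const <- permutation_pvalue(function(p) 1, 20, n_perm = 99, seed = 1)
  expect_equal(p_const, 1)
  # planted 5-pooled-SD effect: every permuted stat falls below observed
  y <- c(rnorm(10), rnorm(10) + 5)
  stat <- function(perm) {
    g <- grp[perm]
    mean(y[g == "tbi"]) - mean(y[g == "control"])
  }
  p_min <- permutation_pvalue(stat, 20, n_perm = 200, seed = 2)
  expect_equal(p_min, 1 / 201)
  # invariance under monotone transform of |T|
  p_cube <- permutation_pvalue(function(perm) stat(perm)^3, 20,
                               n_perm = 200, seed = 2)
  expect_equal(p_cube, p_min)
})

test_that("permutation test is calibrated under the null", {
  set.seed(3)
  grp <- rep(c("control", "tbi"), each = 10)
  rej <- replicate(200, {
    y <- rnorm(20)
    stat <- function(perm) {
      g <- grp[perm]
      mean(y[g == "tbi"]) - mean(y[g == "control"])
    }
    permutation_pvalue(stat, 20, n_perm = 99,
                       seed = sample.int(1e6, 1)) < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("pooled t reproduces the behavioral worked example and raw-data
           oracle", {
  # iPL-SOT group summaries: 106.72 +/- 8.41 (n=27) vs 88.63 +/- 28.80 (n=14)
  t_sum <- pooled_two_sample_t(106.72, 8.41, 27, 88.63, 28.80, 14)
  expect_equal(t_sum, 3.054, tolerance = 0.01 / 3.054)
  expect_equal(pooled_two_sample_t(5, 1, 10, 5, 2, 12), 0)
  expect_error(pooled_two_sample_t(1, 0, 5, 2, 0, 5), "infinite")
  # raw samples constructed to have those exact summaries
  mk <- function(n, m, s) {
    z <- scale(rnorm(n))
    as.numeric(m + s * z)
  }
  set.seed(4)
  a <- mk(27, 106.72, 8.41); b <- mk(14, 88.63, 28.80)
  expect_equal(pooled_two_sample_t(mean(a), sd(a), 27, mean(b), sd(b), 14),
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("Hedges g is odd in t and its interval brackets g", {
  h <- hedges_g(2.2, 27, 14)
  hneg <- hedges_g(-2.2, 27, 14)
  expect_equal(hneg$g, -h$g)
  expect_equal(hedges_g(0, 27, 14)$g, 0)
  expect_lt(h$ci[1], h$g); expect_gt(h$ci[2], h$g)
  expect_equal(h$J, 1 - 3 / (4 * 39 - 1))
})

test_that("adjusted association: linearity, rank preservation, confound
           recovery", {
  x <- seq(-3, 3, length.out = 20)
  lin <- adjusted_association(x, 2 * x, residualize = "both")
  expect_equal(lin$pearson_r, 1)
  expect_equal(lin$spearman_s, 1)
  cub <- adjusted_association(x, x^3, residualize = "both")
  expect_equal(cub$spearman_s, 1)
  expect_lt(cub$pearson_r, 1)
  expect_error(adjusted_association(rep(1, 10), rnorm(10)), "zero-variance")
  # planted partial correlation 0.8 behind a shared age confound
  set.seed(5)
  for (rep in 1:20) {
    age <- rnorm(200)
    u <- rnorm(200)
    xx <- 2 * age + u
    yy <- 3 * age + 0.8 * u + sqrt(1 - 0.8^2) * rnorm(200)
    r <- adjusted_association(xx, yy, data.frame(age = age),
                              residualize = "both")$pearson_r
    expect_gte(r, 0.7); expect_lte(r, 0.9)
  }
})
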