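#' Build a two-group design matrix with covariates
#'
#' Constructs the cell-means design used throughout the group comparisons:
#' one indicator column per group (control, tbi) followed by covariate
#' columns. Group differences are then tested with a contrast over the two
#' indicator columns while covariate columns absorb confound variance.
#'
#' @param cohort Data frame with a `group` column (factor or character with
#'   levels `control` and `tbi`) and any covariate columns.
#' @param covariates Character vector of cohort column names to append as
#'   confound regressors (e.g. `c("age", "eddy_motion_mean")`). Covariates
#'   are mean-centred so the group indicators keep their interpretation as
#'   adjusted group means.
#' @return List with `X` (n x (2 + length(covariates)) design matrix),
#'   `groups` (the group factor) and the four standard contrast vectors
#'   `control`, `tbi`, `control_minus_tbi`, `tbi_minus_control`.
#' @export
make_design <- function(cohort, covariates = character()) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  g <- factor(cohort$group, levels = c("control", "tbi"))
  if (anyNA(g)) stop("group must be 'control' or 'tbi'")
  X <- cbind(control = as.numeric(g == "control"),
             tbi     = as.numeric(g == "tbi"))
  for (cv in covariates) {
    if (!cv %in% names(cohort)) stop("covariate not in cohort table: ", cv)
    v <- as.numeric(cohort[[cv]])
    if (anyNA(v)) stop("covariate contains NA: ", cv)
    X <- cbind(X, scale(v, scale = FALSE))
    colnames(X)[ncol(X)] <- cv
  }
  pad <- function(w) c(w, rep(0, length(covariates)))
  list(X = X, groups = g,
       contrasts = list(control           = pad(c(1, 0)),
                        tbi               = pad(c(0, 1)),
                        control_minus_tbi = pad(c(1, -1)),
                        tbi_minus_control = pad(c(-1, 1))))
}

#' GLM contrast t-test over features
#'
#' Ordinary least squares fit of each feature (column of `y`) on the design
#' matrix, followed by a t-test of a linear contrast of the coefficients:
#' t = c'b / se(c'b), with the two-sided p from the t distribution on the
#' residual degrees of freedom. With the two-indicator design and contrast
#' (1, -1) and no covariates this reduces exactly to the classical
#' pooled-variance two-sample t-test.
#'
#' @param y Numeric matrix (subjects x features) or vector.
#' @param X Design matrix (subjects x p), full column rank.
#' @param contrast Numeric contrast vector of length `ncol(X)`.
#' @return Data frame with one row per feature: `t`, `df`, `p_param`.
#' @export
glm_contrast_ttest <- function(y, X, contrast) {
  y <- as.matrix(y)
  X <- as.matrix(X)
  if (!is.numeric(y) || anyNA(y)) stop("y must be numeric with no NA")
  if (nrow(y) != nrow(X)) stop("y and design have different subject counts")
  if (length(contrast) != ncol(X))
    stop("contrast length ", length(contrast), " != design columns ", ncol(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df < 1) stop("not enough subjects for the design (df < 1)")
  beta <- qr.coef(qrX, y)                     # p x features
  resid <- y - X %*% beta
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  est <- drop(crossprod(contrast, beta))
  se <- sqrt(cvar * sigma2)
  tval <- ifelse(se > 0, est / se, 0)
  if (all(contrast == 0)) tval[] <- 0
  pval <- ifelse(tval == 0 & se == 0, 1, 2 * stats::pt(-abs(tval), df))
  data.frame(feature = colnames(y) %||% seq_len(ncol(y)),
             t = tval, df = df, p_param = pmin(pval, 1), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject-label permutation p-values
#'
#' Empirical two-sided p-values from random relabelings of the subjects.
#' The statistic function is re-evaluated under each permuted labeling
#' (covariates, if any, are refit inside `stat_fn`), and
#' p = (1 + #\{|T_perm| >= |T_obs|\}) / (1 + n_perm), the add-one estimator
#' that never returns zero.
#'
#' @param stat_fn Function taking a permutation index vector (subject order)
#'   and returning a numeric vector of statistics (one per feature).
#' @param n_subjects Number of subjects to permute.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; permutations are deterministic given it.
#' @return Numeric vector of permutation p-values, one per feature.
#' @export
permutation_pvalue <- function(stat_fn, n_subjects, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- abs(stat_fn(seq_len(n_subjects)))
  exceed <- numeric(length(obs))
  rng <- local_rng(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_subjects)
    exceed <- exceed + (abs(stat_fn(perm)) >= obs - 1e-12)
  }
  rng()
  (1 + exceed) / (1 + n_perm)
}

# Scoped RNG: installs a seed, returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' Pooled-variance two-sample t statistic from group summaries
#'
#' Classical Student t with pooled variance and df = n1 + n2 - 2, computed
#' from group means, standard deviations and sizes.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return The t statistic (group 1 minus group 2).
#' @export
pooled_two_sample_t <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2) return(0)
    stop("zero pooled variance with unequal means: t is infinite")
  }
  (m1 - m2) / se
}

#' Hedges g effect size from a two-sample t statistic
#'
#' Small-sample corrected standardized mean difference
#' g = J * t * sqrt(1/n1 + 1/n2) with J = 1 - 3 / (4 (n1 + n2 - 2) - 1),
#' and a normal-approximation 95% interval using
#' se(g) = sqrt((n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))).
#'
#' @param t Two-sample t statistic (pooled or GLM-contrast).
#' @param n1,n2 Group sizes (>= 2).
#' @return List with `g`, `ci` (length-2 numeric), `J`.
#' @export
hedges_g <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * t * sqrt(1 / n1 + 1 / n2)
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
  ci <- if (length(g) == 1) c(g - 1.96 * se, g + 1.96 * se) else
    cbind(low = g - 1.96 * se, high = g + 1.96 * se)
  list(g = g, ci = ci, J = J)
}

#' Covariate-adjusted Pearson and Spearman association
#'
#' Residualizes the imaging variable (and, optionally, the behavioral
#' variable) on an intercept plus covariates by least squares, then computes
#' Pearson and Spearman correlations on the residualized values. With
#' `residualize = "x"` only `x` is adjusted ("corrected" imaging variable
#' against the raw behavioral score); with `"both"` both variables are
#' partialled, giving the usual partial correlation.
#'
#' @param x Imaging variable (numeric, one value per subject).
#' @param y Behavioral variable, same length.
#' @param covariates Data frame or matrix of covariates (may be NULL).
#' @param residualize `"x"` (default) or `"both"`.
#' @return Data frame with `pearson_r`, `pearson_p`, `spearman_s`,
#'   `spearman_p`.
#' @export
adjusted_association <- function(x, y, covariates = NULL,
                                 residualize = c("x", "both")) {
  residualize <- match.arg(residualize)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4) stop("need at least 4 paired observations")
  res <- function(v) {
    if (is.null(covariates)) return(v - mean(v))
    Z <- cbind(1, as.matrix(covariates))
    if (qr(Z)$rank < ncol(Z)) stop("covariate matrix is rank deficient")
    stats::lsfit(Z, v, intercept = FALSE)$residuals
  }
  xr <- res(x)
  yr <- if (residualize == "both") res(y) else y
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0)
    stop("zero-variance residuals: association undefined")
  pe <- stats::cor.test(xr, yr, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(xr, yr, method = "spearman"))
  data.frame(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             spearman_s = unname(sp$estimate), spearman_p = sp$p.value)
}
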