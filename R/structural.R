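#' Binarize a streamline-count connectome
#'
#' Entry 1 wherever the count is positive, 0 elsewhere; the diagonal is
#' forced to zero. Idempotent.
#'
#' @param sc Symmetric nonnegative matrix of streamline counts.
#' @return Binary matrix of the same dimension.
#' @export
binarize_connectome <- function(sc) {
  sc <- as.matrix(sc)
  check_symmetric(sc, "sc")
  if (any(sc < 0)) stop("sc must be nonnegative")
  b <- (sc > 0) * 1
  diag(b) <- 0
  b
}

#' Inter-module connectivity from a binary connectome
#'
#' Aggregates binary ROI-level links to the module level: `weights[m, n]`
#' counts links with one endpoint in module m and the other in module n
#' (m != n); links inside a module are tallied separately in `intra`.
#'
#' @param sc_bin Binary symmetric ROI matrix.
#' @param labels Module labels covering every ROI of the matrix.
#' @return Object of class `module_graph` with fields `M`, `weights`
#'   (M x M, zero diagonal) and `intra` (length M).
#' @export
intermodule_connectivity <- function(sc_bin, labels) {
  sc_bin <- as.matrix(sc_bin)
  if (length(labels) != nrow(sc_bin))
    stop("labels length (", length(labels), ") != matrix size (",
         nrow(sc_bin), ")")
  labels <- as.integer(labels)
  M <- max(labels)
  Z <- matrix(0, length(labels), M)
  Z[cbind(seq_along(labels), labels)] <- 1
  cross <- t(Z) %*% sc_bin %*% Z       # link counts doubled off-diagonal
  intra <- diag(cross) / 2
  weights <- cross
  diag(weights) <- 0
  structure(list(M = M, weights = weights, intra = intra),
            class = "module_graph")
}

#' Module degree profile
#'
#' The weighted degree of each module: the total number of binary ROI links
#' reaching the module from any other module. Intra-module links are
#' excluded.
#'
#' @param mg `module_graph` from [intermodule_connectivity()].
#' @return Numeric vector of length M.
#' @export
module_degree <- function(mg) {
  stopifnot(inherits(mg, "module_graph"))
  rowSums(mg$weights)
}

#' Cohort-level module degree table
#'
#' @param connectomes List of structural count matrices (or
#'   `connectome_pair`s), one per subject.
#' @param labels Module labels shared across subjects.
#' @return Matrix (subjects x modules) of inter-module degrees.
#' @export
cohort_module_degrees <- function(connectomes, labels) {
  rows <- lapply(connectomes, function(cc) {
    sc <- if (inherits(cc, "connectome_pair")) cc$sc else cc
    module_degree(intermodule_connectivity(binarize_connectome(sc), labels))
  })
  out <- do.call(rbind, rows)
  colnames(out) <- paste0("module_", seq_len(ncol(out)))
  out
}

#' Covariate-adjusted, permutation-corrected group comparison of features
#'
#' Shared engine behind the structural-degree and dynamics-descriptor group
#' comparisons: a GLM contrast t per feature (control minus TBI, with
#' covariates), an empirical p from subject-label permutations in which the
#' full GLM (covariates included) is refit per permutation, and a Hedges g
#' with 95% interval derived from the t. Features with permutation
#' p >= alpha are flagged `discarded`.
#'
#' @param y Subjects x features matrix (degrees or descriptors).
#' @param design List from [make_design()].
#' @param contrast Contrast name (default `"control_minus_tbi"`) or vector.
#' @param n_perm Number of subject-label permutations.
#' @param seed Integer seed for the permutations.
#' @param alpha Discard threshold on the permutation p (default 0.05).
#' @return Data frame with columns `feature`, `t`, `df`, `p_param`,
#'   `p_perm`, `g`, `ci_low`, `ci_high`, `discarded`.
#' @export
group_comparison <- function(y, design, contrast = "control_minus_tbi",
                             n_perm = 1000, seed = 1, alpha = 0.05) {
  y <- as.matrix(y)
  X <- design$X
  cvec <- if (is.character(contrast)) design$contrasts[[contrast]] else contrast
  if (is.null(cvec)) stop("unknown contrast: ", contrast)
  tab <- table(design$groups)
  if (any(tab < 2)) stop("need at least 2 subjects per group")
  obs <- glm_contrast_ttest(y, X, cvec)
  p_perm <- permutation_pvalue(function(perm) {
    glm_contrast_ttest(y, X[perm, , drop = FALSE], cvec)$t
  }, n_subjects = nrow(y), n_perm = n_perm, seed = seed)
  hg <- hedges_g(obs$t, tab[["control"]], tab[["tbi"]])
  data.frame(feature = obs$feature, t = obs$t, df = obs$df,
             p_param = obs$p_param, p_perm = p_perm,
             g = hg$g,
             ci_low = hg$g - 1.96 * sqrt((sum(tab)) / prod(tab) +
                                           hg$g^2 / (2 * sum(tab))),
             ci_high = hg$g + 1.96 * sqrt((sum(tab)) / prod(tab) +
                                            hg$g^2 / (2 * sum(tab))),
             discarded = p_perm >= alpha, row.names = NULL)
}

#' Group comparison of structural module degrees
#'
#' @param degrees Subjects x modules degree matrix
#'   (see [cohort_module_degrees()]).
#' @inheritParams group_comparison
#' @return Per-module effect report (see [group_comparison()]).
#' @export
structural_group_comparison <- function(degrees, design, n_perm = 1000,
                                        seed = 1, alpha = 0.05) {
  group_comparison(degrees, design, "control_minus_tbi",
                   n_perm = n_perm, seed = seed, alpha = alpha)
}
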