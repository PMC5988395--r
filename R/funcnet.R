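#' PCA + fixed-point ICA components of a module
#'
#' Reduces a module's voxel timecourses to `n_pca` principal components and
#' unmixes them into `n_ica` independent timecourses by fixed-point ICA
#' (logcosh contrast, symmetric decorrelation) on the whitened subspace.
#' Components are scaled to unit sample variance and ordered by descending
#' energy of their back-projection into the data (the norm of the
#' associated mixing column), so the ordering is invariant to the ICA
#' permutation ambiguity. Deterministic given the seed.
#'
#' @param x T x V matrix of module voxel timecourses (V > n_pca,
#'   T > n_pca).
#' @param n_pca Number of principal components retained (default 20).
#' @param n_ica Number of independent components (default `n_pca`).
#' @param seed Integer seed for the random orthogonal initialisation.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return Object of class `component_set`: `components` (T x n_ica, unit
#'   variance), `mixing_energy`, `n_pca`, `seed`.
#' @export
module_ica_components <- function(x, n_pca = 20, n_ica = n_pca, seed = 1,
                                  max_iter = 500, tol = 1e-8) {
  x <- as.matrix(x)
  T_ <- nrow(x); V <- ncol(x)
  if (V <= n_pca) stop("module has ", V, " voxels; needs more than n_pca = ",
                       n_pca, " (reduce n_pca)")
  if (T_ <= n_pca) stop("too few time points for n_pca = ", n_pca)
  if (n_ica > n_pca) stop("n_ica cannot exceed n_pca")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = n_pca, nv = 0)
  if (sv$d[n_pca] < 1e-10 * sv$d[1])
    stop("data rank below n_pca = ", n_pca, "; use a smaller n_pca")
  # Whitened PC scores: T x n_pca with identity covariance (up to 1/(T-1)).
  Zw <- sv$u[, seq_len(n_pca), drop = FALSE] * sqrt(T_ - 1)

  rng <- local_rng(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n_pca * n_ica), n_pca, n_ica)))
  rng()
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    U <- Zw %*% W                       # T x n_ica current estimates
    gU <- tanh(U)
    gpU <- colMeans(1 - gU^2)
    W_new <- crossprod(Zw, gU) / T_ - sweep(W, 2, gpU, `*`)
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(colSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  S <- Zw %*% W                         # unit-variance sources
  # Mixing column energy in original PC coordinates: A = D V' ... here the
  # back-projection energy is d_k weights through W.
  d <- sv$d[seq_len(n_pca)] / sqrt(T_ - 1)
  energy <- sqrt(colSums((W * d)^2))
  ord <- order(energy, decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  # Deterministic sign: positive skewness (falls back to largest excursion).
  for (k in seq_len(ncol(S))) {
    sk <- mean(S[, k]^3)
    flip <- if (abs(sk) > 1e-12) sk < 0 else max(S[, k]) < -min(S[, k])
    if (flip) S[, k] <- -S[, k]
  }
  S <- scale(S, center = TRUE, scale = apply(S, 2, stats::sd))
  structure(list(components = S, mixing_energy = energy[ord],
                 n_pca = n_pca, seed = seed),
            class = "component_set")
}

#' Whole-brain spatial map of each component
#'
#' For every brain voxel, regresses its timecourse jointly on all
#' component timecourses; the spatial map of a component holds that
#' component's regression coefficient at each voxel.
#'
#' @param brain T x V_brain matrix of whole-brain voxel timecourses.
#' @param components `component_set` (or T x C matrix of regressors).
#' @return C x V_brain matrix of spatial maps (one row per component).
#' @export
component_spatial_map <- function(brain, components) {
  C <- if (inherits(components, "component_set")) components$components
       else as.matrix(components)
  brain <- as.matrix(brain)
  if (nrow(brain) != nrow(C)) stop("time dimension mismatch")
  X <- cbind(1, C)
  q <- qr(X)
  if (q$rank < ncol(X)) stop("collinear components: spatial maps undefined")
  beta <- qr.coef(q, brain)
  maps <- beta[-1, , drop = FALSE]
  rownames(maps) <- paste0("component_", seq_len(nrow(maps)))
  maps
}

#' Cluster pooled spatial maps into most representative clusters
#'
#' k-means clustering of spatial maps under the 1 - Pearson spatial
#' correlation distance. Maps are row-standardized (mean 0, SD 1), where
#' the correlation distance is a fixed affine function of squared
#' Euclidean distance, so standard k-means minimises exactly the intended
#' within-cluster dissimilarity. Centroids are returned unit-normalized.
#' Deterministic given the seed; the best of `n_restarts` random starts is
#' kept.
#'
#' @param maps n_maps x V matrix of pooled spatial maps.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @param provenance Optional data frame (one row per map: module, subject,
#'   component) carried through to the assignment.
#' @return Object of class `mrc_assignment`: `labels` (1..k per map),
#'   `centroids` (k x V, unit norm), `withinss`, `provenance`.
#' @export
cluster_spatial_maps <- function(maps, k = 5, seed = 1, n_restarts = 10,
                                 provenance = NULL) {
  maps <- as.matrix(maps)
  if (nrow(maps) < k) stop("fewer maps than clusters")
  sds <- apply(maps, 1, stats::sd)
  if (any(sds == 0))
    stop("degenerate constant map(s): ",
         paste(utils::head(which(sds == 0), 5), collapse = ", "))
  z <- t(scale(t(maps)))                # row-standardize
  rng <- local_rng(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_restarts, iter.max = 100)
  rng()
  cent <- km$centers / sqrt(rowSums(km$centers^2))
  structure(list(labels = km$cluster, centroids = cent,
                 withinss = km$tot.withinss, k = k,
                 provenance = provenance),
            class = "mrc_assignment")
}

#' Group-contrast t-maps for one MRC within one module
#'
#' Averages each subject's spatial maps belonging to the given MRC and
#' module (so every subject contributes at most one observation), then
#' computes voxel-wise GLM t-maps for the four standard contrasts:
#' control mean, TBI mean, control minus TBI, and TBI minus control.
#'
#' @param maps n_maps x V pooled spatial-map matrix.
#' @param provenance Data frame with columns `subject` (index into the
#'   design rows) and rows aligned with `maps`.
#' @param keep Logical or integer index selecting the maps of this
#'   MRC/module.
#' @param design List from [make_design()] covering all subjects.
#' @return List of four t-map vectors (`control`, `tbi`,
#'   `control_minus_tbi`, `tbi_minus_control`), plus `df` and the subject
#'   index used.
#' @export
mrc_group_contrast <- function(maps, provenance, keep, design) {
  sel <- if (is.logical(keep)) which(keep) else keep
  if (length(sel) == 0) stop("no maps selected for this MRC/module")
  sub <- provenance$subject[sel]
  groups <- design$groups
  present <- unique(sub)
  for (g in c("control", "tbi")) {
    if (!any(groups[present] == g))
      stop("group '", g, "' contributes no maps to this MRC/module")
  }
  agg <- rowsum(maps[sel, , drop = FALSE], group = sub) /
    as.vector(table(factor(sub, levels = sort(unique(sub)))))
  subj_idx <- sort(unique(sub))
  Xs <- design$X[subj_idx, , drop = FALSE]
  out <- lapply(design$contrasts, function(cv)
    glm_contrast_ttest(agg, Xs, cv)$t)
  out$df <- nrow(agg) - qr(Xs)$rank
  out$subjects <- subj_idx
  out
}
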