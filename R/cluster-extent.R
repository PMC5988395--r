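# Monte-Carlo cluster-extent family-wise error control on 3D grids,
# in the spirit of AFNI's 3dClustSim: simulate smooth Gaussian noise
# fields, threshold voxel-wise, and record the maximum cluster size.

# Separable Gaussian smoothing of a 3D array; fwhm in voxels. Zero-padded
# convolution, then restandardized empirically to unit variance so the
# voxel-forming z threshold keeps its nominal rate away from the edges.
smooth_field <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  dims <- dim(arr)
  conv_axis1 <- function(a) {
    # a: array with the convolution axis first, flattened to a matrix
    m <- matrix(a, nrow = dim(a)[1])
    n <- nrow(m)
    padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- stats::filter(padded, kern, sides = 2)
    array(out[(half + 1):(half + n), , drop = FALSE], dim = dim(a))
  }
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    arr <- aperm(conv_axis1(aperm(arr, perm)), order(perm))
  }
  arr / stats::sd(arr)
}

# Connected components of a logical 3D mask under a 6/18/26 neighbor
# rule. Returns list(index = linear voxel indices of TRUE voxels,
# membership = component id per TRUE voxel).
label_clusters <- function(mask, connect = 6) {
  stopifnot(connect %in% c(6, 18, 26))
  idx <- which(mask)
  if (length(idx) == 0) return(list(index = integer(), membership = integer()))
  dims <- dim(mask)
  coord <- arrayInd(idx, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nonzero <- rowSums(offsets != 0)
  offsets <- switch(as.character(connect),
                    "6"  = offsets[nonzero == 1, , drop = FALSE],
                    "18" = offsets[nonzero >= 1 & nonzero <= 2, , drop = FALSE],
                    "26" = offsets[nonzero >= 1, , drop = FALSE])
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)           # voxel -> node id
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(coord, 2, offsets[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
      (nb[ok, 3] - 1) * dims[1] * dims[2]
    hit <- pos[lin] > 0
    if (any(hit))
      edges[[length(edges) + 1]] <- cbind(which(ok)[hit], pos[lin[hit]])
  }
  if (length(edges) == 0)
    return(list(index = idx, membership = seq_along(idx)))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  extra <- length(idx) - igraph::vcount(g)
  if (extra > 0) g <- igraph::add_vertices(g, extra)
  list(index = idx, membership = igraph::components(g)$membership)
}

cluster_sizes <- function(mask, connect = 6) {
  cm <- label_clusters(mask, connect)
  if (length(cm$index) == 0) return(integer())
  as.integer(table(cm$membership))
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimum cluster size controlling the family-wise error of
#' a voxel-wise two-sided test on a 3D grid: simulates `n_iter` Gaussian
#' noise fields smoothed to the requested FWHM, thresholds them two-sided
#' at `voxel_p`, records the maximum cluster size per iteration (positive
#' and negative excursions clustered separately), and returns the smallest
#' size `s` with `P(max cluster >= s) <= alpha`.
#'
#' @param grid Integer vector of 3 grid dimensions.
#' @param fwhm Smoothness of the simulated fields, in voxels (>= 0).
#' @param voxel_p Two-sided voxel-forming p threshold (0 < p < 1).
#' @param alpha Cluster-level FWE (default 0.05).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param connect Neighbor rule: 6 (faces, default), 18 or 26.
#' @param seed Integer seed.
#' @return Object of class `cluster_extent_null` with `min_size`, the
#'   sampled `max_sizes`, and the simulation parameters.
#' @export
cluster_extent_threshold <- function(grid, fwhm = 0, voxel_p = 0.005,
                                     alpha = 0.05, n_iter = 10000,
                                     connect = 6, seed = 1) {
  if (length(grid) != 3 || any(grid < 2)) stop("grid must be 3 dimensions >= 2")
  if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (fwhm < 0) stop("fwhm must be >= 0")
  grid <- as.integer(grid)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  rng <- local_rng(seed)
  max_sizes <- integer(n_iter)
  for (b in seq_len(n_iter)) {
    f <- array(stats::rnorm(prod(grid)), dim = grid)
    f <- smooth_field(f, fwhm)
    sz <- c(cluster_sizes(f > zthr, connect),
            cluster_sizes(f < -zthr, connect))
    max_sizes[b] <- if (length(sz)) max(sz) else 0L
  }
  rng()
  s <- 1L
  while (mean(max_sizes >= s) > alpha) s <- s + 1L
  structure(list(min_size = s, max_sizes = max_sizes, grid = grid,
                 fwhm = fwhm, voxel_p = voxel_p, alpha = alpha,
                 n_iter = n_iter, connect = connect, seed = seed),
            class = "cluster_extent_null")
}

#' Apply cluster-extent correction to a t-map
#'
#' Thresholds the t-map two-sided at the voxel-forming p (using the t
#' distribution with `df` degrees of freedom), forms connected components
#' per sign under the null's neighbor rule, and keeps clusters at least as
#' large as the null's minimum surviving size.
#'
#' @param tmap Numeric 3D array (or vector reshaped to `null$grid`).
#' @param df Degrees of freedom of the t-map.
#' @param null `cluster_extent_null` from [cluster_extent_threshold()].
#' @param voxel_p Voxel-forming threshold; defaults to the null's.
#' @return Data frame of surviving clusters: `sign`, `size`, `peak_t`,
#'   `peak_index` (linear voxel index); attribute `voxel_index` holds the
#'   member voxels of each surviving cluster.
#' @export
apply_cluster_correction <- function(tmap, df, null, voxel_p = null$voxel_p) {
  if (!inherits(null, "cluster_extent_null"))
    stop("null must come from cluster_extent_threshold()")
  if (!is.array(tmap)) tmap <- array(tmap, dim = null$grid)
  if (!isTRUE(all.equal(dim(tmap), null$grid)))
    stop("t-map geometry does not match the null grid")
  tthr <- stats::qt(1 - voxel_p / 2, df)
  out <- list(); vox <- list()
  for (sgn in c(1, -1)) {
    cm <- label_clusters(sgn * tmap > tthr, null$connect)
    if (length(cm$index) == 0) next
    for (cl in unique(cm$membership)) {
      members <- cm$index[cm$membership == cl]
      if (length(members) >= null$min_size) {
        pk <- members[which.max(abs(tmap[members]))]
        out[[length(out) + 1]] <- data.frame(
          sign = if (sgn > 0) "positive" else "negative",
          size = length(members), peak_t = tmap[pk], peak_index = pk)
        vox[[length(vox) + 1]] <- members
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sign = character(), size = integer(), peak_t = numeric(),
               peak_index = integer())
  attr(res, "voxel_index") <- vox
  res
}
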