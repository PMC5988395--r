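#' Construct a multimodal connectome pair
#'
#' Bundles a subject's (or cohort-average) structural streamline-count
#' matrix and functional correlation matrix over a shared ROI ordering.
#'
#' @param sc Symmetric nonnegative integer matrix (streamline counts,
#'   zero diagonal).
#' @param fc Symmetric correlation matrix (unit diagonal, entries in
#'   [-1, 1]).
#' @param roi_ids Optional ROI identifiers; defaults to row names or
#'   `1..N`.
#' @return Object of class `connectome_pair`.
#' @export
connectome_pair <- function(sc, fc, roi_ids = NULL) {
  sc <- as.matrix(sc); fc <- as.matrix(fc)
  n <- nrow(sc)
  if (!isTRUE(all.equal(dim(sc), dim(fc))) || n != ncol(sc))
    stop("sc and fc must be square matrices of the same size")
  check_symmetric(sc, "sc")
  check_symmetric(fc, "fc")
  if (any(sc < 0)) stop("sc must be nonnegative")
  if (any(abs(sc - round(sc)) > 1e-8)) stop("sc must hold integer counts")
  if (any(diag(sc) != 0)) stop("sc diagonal must be zero")
  if (max(abs(diag(fc) - 1)) > 1e-8) stop("fc diagonal must be 1")
  if (max(abs(fc)) > 1 + 1e-8) stop("fc entries must lie in [-1, 1]")
  roi_ids <- roi_ids %||% rownames(sc) %||% as.character(seq_len(n))
  dimnames(sc) <- dimnames(fc) <- list(roi_ids, roi_ids)
  structure(list(sc = sc, fc = fc, roi_ids = roi_ids),
            class = "connectome_pair")
}

check_symmetric <- function(m, name) {
  if (!all(is.finite(m))) stop(name, " contains non-finite values")
  if (max(abs(m - t(m))) > 1e-8) stop(name, " is not symmetric")
  invisible(TRUE)
}

#' Build an agglomerative dendrogram over ROIs
#'
#' Average-linkage (UPGMA) agglomerative clustering of a similarity matrix,
#' using dissimilarity 1 - similarity. The merge sequence is deterministic
#' for a given input; heights are non-decreasing (guaranteed by UPGMA).
#'
#' @param similarity Symmetric finite similarity matrix (N >= 2). Larger
#'   values mean more similar; for functional input pass the correlation
#'   matrix, for structural input a binary or min-max-scaled count matrix.
#' @param modality Tag, `"functional"` or `"structural"`.
#' @return Object of class `roi_dendrogram` wrapping the `hclust` tree.
#' @export
build_dendrogram <- function(similarity,
                             modality = c("functional", "structural")) {
  modality <- match.arg(modality)
  similarity <- as.matrix(similarity)
  if (nrow(similarity) < 2) stop("need at least 2 ROIs")
  check_symmetric(similarity, "similarity")
  d <- stats::as.dist(1 - similarity)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, modality = modality,
                 leaves = rownames(similarity) %||%
                   as.character(seq_len(nrow(similarity)))),
            class = "roi_dendrogram")
}

#' Cut a dendrogram into M modules
#'
#' Cuts the tree so that exactly `M` modules remain. Cuts of the same tree
#' are nested: each module at level M + 1 is contained in exactly one
#' module at level M.
#'
#' @param dend `roi_dendrogram` from [build_dendrogram()].
#' @param M Module count, `1 <= M <= N`.
#' @return Integer vector of module labels in `1..M`, named by ROI.
#' @export
cut_dendrogram <- function(dend, M) {
  stopifnot(inherits(dend, "roi_dendrogram"))
  n <- length(dend$hclust$order)
  if (M < 1 || M > n) stop("M must lie in [1, ", n, "]")
  labels <- stats::cutree(dend$hclust, k = M)
  names(labels) <- dend$leaves
  labels
}

#' Newman modularity of a partition
#'
#' Q = sum_m (e_mm - a_m^2), where e is the (weighted) fraction of edges
#' falling between each pair of modules and a_m its row sums. Evaluates
#' the quality of a given partition; no optimization is performed.
#'
#' @param adjacency Symmetric nonnegative (weighted) adjacency matrix with
#'   at least one edge; the diagonal is ignored.
#' @param labels Module labels, one per node.
#' @return Q in [-1, 1].
#' @export
newman_modularity <- function(adjacency, labels) {
  adjacency <- as.matrix(adjacency)
  check_symmetric(adjacency, "adjacency")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  diag(adjacency) <- 0
  if (length(labels) != nrow(adjacency))
    stop("labels length does not match adjacency size")
  w <- sum(adjacency)
  if (w == 0) stop("edgeless graph: modularity undefined")
  labels <- as.integer(factor(labels))
  k <- max(labels)
  Z <- matrix(0, length(labels), k)
  Z[cbind(seq_along(labels), labels)] <- 1
  e <- t(Z) %*% adjacency %*% Z / w    # edge-fraction matrix
  sum(diag(e)) - sum(rowSums(e)^2)
}

#' Sorensen similarity of two edge sets
#'
#' S = 2 |A intersect B| / (|A| + |B|) over canonicalized undirected edges.
#'
#' @param edges_a,edges_b Two-column matrices (or data frames) of node
#'   pairs over a shared node universe. Edge direction is ignored.
#' @return S in [0, 1]. Raises an error when both sets are empty.
#' @export
sorensen_similarity <- function(edges_a, edges_b) {
  a <- canonical_edges(edges_a)
  b <- canonical_edges(edges_b)
  if (length(a) == 0 && length(b) == 0)
    stop("both edge sets are empty: Sorensen similarity undefined")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

canonical_edges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0) return(character())
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  unique(paste(lo, hi, sep = "--"))
}

# Edges inside one module of a binary graph, as a 2-column matrix.
module_edge_set <- function(adjacency, labels, module) {
  idx <- which(labels == module)
  sub <- adjacency[idx, idx, drop = FALSE]
  w <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
  cbind(idx[w[, 1]], idx[w[, 2]])
}

#' Cross-modularity of a connectome pair at level M
#'
#' Builds the functional dendrogram from the correlation matrix and the
#' structural dendrogram from the binarized streamline matrix, cuts both at
#' `M` modules, and combines three partition-quality factors: structural
#' modularity Q_s (binary structural graph), functional modularity Q_f
#' (positive-correlation weighted graph), and the mean best-match Sorensen
#' similarity <S> between intramodule edge sets of the two partitions
#' (greedy best match, symmetrized over both directions). The index is the
#' geometric mean X = (Q_s Q_f <S>)^(1/3), clipped to 0 when any factor is
#' negative.
#'
#' @param pair `connectome_pair`.
#' @param M Module count, `2 <= M <= N`.
#' @param fc_edge_threshold Correlations above this value count as
#'   functional edges when forming intramodule edge sets (default 0).
#' @return List of class `modularity_report`: `M`, `q_structural`,
#'   `q_functional`, `mean_sorensen`, `cross_modularity`, and the two
#'   cut label vectors.
#' @export
cross_modularity <- function(pair, M, fc_edge_threshold = 0) {
  stopifnot(inherits(pair, "connectome_pair"))
  n <- nrow(pair$sc)
  if (M < 2 || M > n) stop("M must lie in [2, ", n, "]")
  sc_bin <- binarize_connectome(pair$sc)
  if (sum(sc_bin) == 0) stop("structural matrix has no edges")
  fc_pos <- pair$fc
  diag(fc_pos) <- 0
  fc_pos[fc_pos < 0] <- 0
  if (sum(fc_pos) == 0) stop("functional matrix has no positive edges")

  dend_s <- build_dendrogram(sc_bin, "structural")
  dend_f <- build_dendrogram(pair$fc, "functional")
  part_s <- cut_dendrogram(dend_s, M)
  part_f <- cut_dendrogram(dend_f, M)

  q_s <- newman_modularity(sc_bin, part_s)
  q_f <- newman_modularity(fc_pos, part_f)

  fc_bin <- (pair$fc > fc_edge_threshold) * 1
  diag(fc_bin) <- 0
  es <- lapply(seq_len(M), function(m) module_edge_set(sc_bin, part_s, m))
  ef <- lapply(seq_len(M), function(m) module_edge_set(fc_bin, part_f, m))
  s_mean <- (best_match_sorensen(es, ef) + best_match_sorensen(ef, es)) / 2

  x <- if (q_s < 0 || q_f < 0 || s_mean < 0) 0 else (q_s * q_f * s_mean)^(1 / 3)
  structure(list(M = M, q_structural = q_s, q_functional = q_f,
                 mean_sorensen = s_mean, cross_modularity = x,
                 partition_structural = part_s, partition_functional = part_f),
            class = "modularity_report")
}

# Mean over modules of A of the best Sorensen match against modules of B.
# Module pairs where both edge sets are empty contribute similarity 0.
best_match_sorensen <- function(sets_a, sets_b) {
  best <- vapply(sets_a, function(a) {
    max(vapply(sets_b, function(b) {
      if (NROW(a) == 0 && NROW(b) == 0) 0 else sorensen_similarity(a, b)
    }, numeric(1)))
  }, numeric(1))
  mean(best)
}

#' Select the optimal hierarchy level by cross-modularity
#'
#' Evaluates [cross_modularity()] over a range of module counts and returns
#' the level with the largest index; ties are broken toward the smallest M.
#'
#' @param pair `connectome_pair`.
#' @param m_range Integer vector of candidate module counts (each in
#'   `[2, N]`).
#' @param ... Passed to [cross_modularity()].
#' @return List with `m_star` and `reports` (one `modularity_report` per
#'   candidate level).
#' @export
select_optimal_level <- function(pair, m_range, ...) {
  if (length(m_range) == 0) stop("m_range is empty")
  m_range <- sort(unique(as.integer(m_range)))
  reports <- lapply(m_range, function(m) cross_modularity(pair, m, ...))
  xs <- vapply(reports, `[[`, numeric(1), "cross_modularity")
  list(m_star = m_range[which.max(xs)], reports = reports,
       cross_modularity = stats::setNames(xs, m_range))
}
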