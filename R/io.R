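# Readers and writers for the pipeline's external formats: dense TSV
# connectome matrices, cohort tables, sway-trajectory tables, module
# tables, and NIfTI volumes (via RNifti).

#' Read / write a dense connectome matrix as TSV
#'
#' The TSV is a dense square matrix with a header row of ROI identifiers.
#'
#' @param path File path.
#' @return `read_connectome_tsv` returns a numeric matrix with ROI
#'   dimnames.
#' @export
read_connectome_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("connectome TSV is not square: ", path)
  rownames(m) <- colnames(m)
  m
}

#' @rdname read_connectome_tsv
#' @param m Square matrix with column names.
#' @export
write_connectome_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' Expects a TSV with columns `subject`, `group` (control/tbi), `age`,
#' `sex`, `fd_mean`, `eddy_motion_mean`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "age", "sex", "fd_mean", "eddy_motion_mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$group %in% c("control", "tbi")))
    stop("group must be 'control' or 'tbi'")
  df
}

#' Read sway trajectories from a TSV
#'
#' Expects columns `t`, `x`, `y`, `trial`, `protocol`, `condition`,
#' `fall`; optional `target_x`, `target_y` for goal-directed protocols.
#' Returns the trial table consumed by [aggregate_scores()].
#'
#' @param path File path.
#' @return Data frame with list-columns `traj` and `target`.
#' @export
read_trajectories_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "trial", "protocol", "condition", "fall")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trajectory table missing columns: ",
                         paste(miss, collapse = ", "))
  ids <- unique(df$trial)
  rows <- lapply(ids, function(id) {
    d <- df[df$trial == id, , drop = FALSE]
    d <- d[order(d$t), , drop = FALSE]
    tgt <- if (all(c("target_x", "target_y") %in% names(d)))
      c(d$target_x[1], d$target_y[1]) else NULL
    list(protocol = d$protocol[1], condition = d$condition[1],
         fall = as.logical(d$fall[1]),
         traj = cbind(d$x, d$y), target = tgt)
  })
  out <- data.frame(
    protocol = vapply(rows, `[[`, character(1), "protocol"),
    condition = vapply(rows, `[[`, numeric(1), "condition"),
    fall = vapply(rows, `[[`, logical(1), "fall"))
  out$traj <- lapply(rows, `[[`, "traj")
  out$target <- lapply(rows, `[[`, "target")
  out
}

#' Write / read an integer-labeled parcellation volume as NIfTI
#'
#' @param labels Integer vector of module labels, one per voxel (column
#'   order), or a 3D array.
#' @param grid Grid dimensions when `labels` is a vector.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_parcellation_nifti <- function(labels, grid, path) {
  arr <- if (is.array(labels)) labels else array(as.integer(labels),
                                                 dim = grid)
  RNifti::writeNifti(arr, path)
  invisible(path)
}

#' @rdname write_parcellation_nifti
#' @export
read_parcellation_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.integer(arr), dim = dim(arr))
}

#' Read a 4D BOLD NIfTI as a T x V matrix
#'
#' Voxels are vectorized in column-major order, matching the parcellation
#' reader, so `voxel_labels = as.vector(parcellation)` aligns.
#'
#' @param path NIfTI path.
#' @return T x V numeric matrix.
#' @export
read_bold_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  if (length(d) != 4) stop("expected a 4D BOLD volume: ", path)
  t(matrix(as.numeric(arr), prod(d[1:3]), d[4]))
}

#' @rdname read_bold_nifti
#' @param x T x V matrix.
#' @param grid 3D grid dimensions with `prod(grid) == ncol(x)`.
#' @export
write_bold_nifti <- function(x, grid, path) {
  stopifnot(prod(grid) == ncol(x))
  RNifti::writeNifti(array(t(x), dim = c(grid, nrow(x))), path)
  invisible(path)
}

#' Write a module table (module id, ROI ids)
#'
#' @param labels Named or plain integer module labels per ROI.
#' @param path Output TSV.
#' @export
write_module_table <- function(labels, path) {
  df <- data.frame(module = as.integer(labels),
                   roi = names(labels) %||% seq_along(labels))
  utils::write.table(df[order(df$module), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
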