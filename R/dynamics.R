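#' Scrub and interpolate high-motion frames
#'
#' Frames whose framewise displacement exceeds `threshold` are replaced by
#' natural cubic-spline interpolation through the unflagged frames. Flagged
#' frames at the series boundary (before the first or after the last clean
#' frame) are held at the nearest clean value rather than extrapolated.
#'
#' @param series Numeric timecourse, or a T x V matrix (columns scrubbed
#'   with the same motion trace).
#' @param motion Nonnegative framewise-displacement trace (mm), same length.
#' @param threshold Scrubbing threshold (default 0.5).
#' @return Scrubbed series of the same shape.
#' @export
scrub_interpolate <- function(series, motion, threshold = 0.5) {
  motion <- as.numeric(motion)
  if (any(!is.finite(motion)) || any(motion < 0))
    stop("motion trace must be finite and nonnegative")
  mat <- is.matrix(series)
  x <- if (mat) series else matrix(series, ncol = 1)
  if (nrow(x) != length(motion))
    stop("series and motion trace have different lengths")
  bad <- motion > threshold
  if (!any(bad)) return(series)
  good <- which(!bad)
  if (length(good) < 4) stop("fewer than 4 clean frames: cannot interpolate")
  idx_bad <- which(bad)
  interior <- idx_bad[idx_bad > min(good) & idx_bad < max(good)]
  for (v in seq_len(ncol(x))) {
    col <- x[, v]
    if (length(interior) > 0)
      col[interior] <- stats::spline(good, x[good, v], xout = interior,
                                     method = "natural")$y
    col[idx_bad[idx_bad < min(good)]] <- x[min(good), v]
    col[idx_bad[idx_bad > max(good)]] <- x[max(good), v]
    x[, v] <- col
  }
  if (mat) x else drop(x)
}

#' First principal component timecourse of a module
#'
#' Column-centres the module's voxel (or ROI) timecourses and extracts the
#' leading principal component scores as the module's representative
#' timecourse, with the fraction of variance it explains. The component
#' sign is fixed so its correlation with the module-mean timecourse is
#' nonnegative.
#'
#' @param x T x V matrix of timecourses for one module (V >= 2).
#' @param tr Repetition time in seconds (metadata only).
#' @return List of class `module_timecourse`: `timecourse` (length T),
#'   `explained_variance`, `tr`.
#' @export
first_principal_timecourse <- function(x, tr = 3) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 voxels/ROIs")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) stop("constant module: no principal component")
  sv <- svd(xc, nu = 1, nv = 0)
  pc <- sv$u[, 1] * sv$d[1]
  mu <- rowMeans(xc)
  if (sum(pc * mu) < 0) pc <- -pc
  structure(list(timecourse = pc,
                 explained_variance = sv$d[1]^2 / sum(sv$d^2),
                 tr = tr),
            class = "module_timecourse")
}

#' BOLD dynamics descriptors of a timecourse
#'
#' Four summaries of a representative module timecourse: sample variance
#' (n - 1 denominator), skewness (3rd standardized moment), kurtosis
#' (4th standardized moment, Gaussian reference 3), and the point-process
#' peak count: the number of time points strictly above mean + 1 sample SD.
#'
#' @param ts Numeric timecourse (length >= 8, nonconstant), or a
#'   `module_timecourse`.
#' @param ppa_z Threshold in SD units for the peak count (default 1).
#' @return Data frame with `variance`, `skewness`, `kurtosis`, `ppa_count`.
#' @export
dynamics_descriptors <- function(ts, ppa_z = 1) {
  if (inherits(ts, "module_timecourse")) ts <- ts$timecourse
  ts <- as.numeric(ts)
  n <- length(ts)
  if (n < 8) stop("timecourse too short (need >= 8 points)")
  s <- stats::sd(ts)
  if (s == 0) stop("constant timecourse: descriptors undefined")
  m <- mean(ts)
  z <- (ts - m) / s
  data.frame(variance = s^2,
             skewness = mean(z^3),
             kurtosis = mean(z^4),
             ppa_count = sum(ts > m + ppa_z * s))
}

#' Per-module dynamics descriptors for a cohort
#'
#' Extracts the first-principal-component timecourse of every module for
#' every subject (after optional motion scrubbing) and computes the four
#' dynamics descriptors.
#'
#' @param bold List (one per subject) of T x V voxel/ROI matrices.
#' @param voxel_labels Module label per column of the BOLD matrices.
#' @param motion Optional list of framewise-displacement traces; when
#'   given, series are scrubbed with [scrub_interpolate()].
#' @param fd_threshold Scrubbing threshold.
#' @param tr Repetition time (s).
#' @return List with `descriptors` (a long data frame: subject, module,
#'   variance, skewness, kurtosis, ppa_count, explained_variance) and
#'   `matrix(descriptor)` accessor via [descriptor_matrix()].
#' @export
cohort_dynamics <- function(bold, voxel_labels, motion = NULL,
                            fd_threshold = 0.5, tr = 3) {
  modules <- sort(unique(voxel_labels))
  rows <- list()
  for (s in seq_along(bold)) {
    x <- as.matrix(bold[[s]])
    if (!is.null(motion)) x <- scrub_interpolate(x, motion[[s]], fd_threshold)
    for (m in modules) {
      pc <- first_principal_timecourse(x[, voxel_labels == m, drop = FALSE],
                                       tr = tr)
      d <- dynamics_descriptors(pc)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject = s, module = m,
                   explained_variance = pc$explained_variance), d)
    }
  }
  do.call(rbind, rows)
}

#' Subjects x modules matrix of one dynamics descriptor
#'
#' @param descriptors Long data frame from [cohort_dynamics()].
#' @param descriptor One of `"variance"`, `"skewness"`, `"kurtosis"`,
#'   `"ppa_count"`, `"explained_variance"`.
#' @return Matrix (subjects x modules).
#' @export
descriptor_matrix <- function(descriptors, descriptor = "variance") {
  if (!descriptor %in% names(descriptors)) stop("unknown descriptor: ",
                                                descriptor)
  subjects <- sort(unique(descriptors$subject))
  modules <- sort(unique(descriptors$module))
  out <- matrix(NA_real_, length(subjects), length(modules),
                dimnames = list(subjects, paste0("module_", modules)))
  for (i in seq_len(nrow(descriptors)))
    out[match(descriptors$subject[i], subjects),
        match(descriptors$module[i], modules)] <- descriptors[[descriptor]][i]
  out
}

#' Group comparison of a dynamics descriptor
#'
#' @param descriptors Long data frame from [cohort_dynamics()] (subject
#'   order must match the design).
#' @param design List from [make_design()].
#' @param descriptor Descriptor name to compare.
#' @inheritParams group_comparison
#' @return Per-module effect report (see [group_comparison()]).
#' @export
dynamics_group_comparison <- function(descriptors, design,
                                      descriptor = "variance",
                                      n_perm = 1000, seed = 1, alpha = 0.05) {
  y <- descriptor_matrix(descriptors, descriptor)
  group_comparison(y, design, "control_minus_tbi",
                   n_perm = n_perm, seed = seed, alpha = alpha)
}
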