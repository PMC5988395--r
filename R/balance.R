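#' Path length and inverse path length of a sway trajectory
#'
#' The center-of-pressure path length is the sum of Euclidean distances
#' between successive samples; the inverse path length (iPL) is its
#' reciprocal, so larger iPL reflects less body sway.
#'
#' @param traj Two-column matrix (x, y, in mm) of ordered COP samples.
#' @return Path length in mm; `inverse_path_length` returns 1/mm.
#' @export
path_length <- function(traj) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 2 || ncol(traj) != 2)
    stop("trajectory needs >= 2 samples of (x, y)")
  if (any(!is.finite(traj))) stop("trajectory has non-finite coordinates")
  steps <- diff(traj)
  sum(sqrt(rowSums(steps^2)))
}

#' @rdname path_length
#' @export
inverse_path_length <- function(traj) {
  pl <- path_length(traj)
  if (pl == 0) stop("zero path length: inverse path length undefined")
  1 / pl
}

#' Directional control of a goal-directed trajectory
#'
#' Decomposes every displacement increment into its component along the
#' target direction (on-target movement, absolute projection magnitude)
#' and the orthogonal remainder (off-target movement), and scores
#' DC = (on - off) / on x 100. A straight path toward the target scores
#' exactly 100.
#'
#' @param traj Two-column matrix of ordered COP/COG samples.
#' @param target Direction vector toward the target (need not be unit).
#' @param on_target One of `"summed"` (default: sum of absolute projection
#'   magnitudes per increment) or `"net"` (magnitude of the summed signed
#'   projection), switching how oscillatory paths are credited.
#' @return DC as a percentage (at most 100).
#' @export
directional_control <- function(traj, target, on_target = c("summed", "net")) {
  on_target <- match.arg(on_target)
  traj <- as.matrix(traj)
  if (nrow(traj) < 2 || ncol(traj) != 2)
    stop("trajectory needs >= 2 samples of (x, y)")
  nrm <- sqrt(sum(target^2))
  if (nrm == 0) stop("target direction is the zero vector")
  u <- target / nrm
  steps <- diff(traj)
  proj <- drop(steps %*% u)
  ortho <- steps - outer(proj, u)
  on <- if (on_target == "summed") sum(abs(proj)) else abs(sum(proj))
  off <- sum(sqrt(rowSums(ortho^2)))
  if (on == 0) stop("zero on-target movement: DC undefined")
  (on - off) / on * 100
}

#' Aggregate trial scores into per-subject balance indexes
#'
#' Implements the trial-aggregation protocol: SOT trials are scored by
#' inverse path length, averaged over the (up to three) non-fall trials of
#' each of the four sensory conditions and then averaged over conditions;
#' LOS trials are scored by directional control and averaged over the
#' eight target directions; RWS trials are averaged over the six
#' speed-by-direction combinations. Fall-flagged trials are excluded; a
#' condition or direction left with no valid trial is an error.
#'
#' @param trials Data frame with one row per trial: columns `protocol`
#'   (`"sot"`, `"los"`, `"rws"`), `condition` (SOT condition 1-4, LOS
#'   direction 1-8, RWS combination 1-6), `fall` (logical) and a
#'   list-column `traj` of two-column sample matrices; LOS/RWS rows also
#'   need a list-column `target` of direction vectors.
#' @return One-row data frame with `ipl_sot`, `dc_los`, `dc_rws`
#'   (protocols absent from `trials` yield NA).
#' @export
aggregate_scores <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("protocol", "condition", "fall", "traj") %in% names(trials)))
  score_protocol <- function(proto, expected, fn) {
    rows <- trials[trials$protocol == proto, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_real_)
    per_cond <- vapply(expected, function(cond) {
      sel <- rows$condition == cond & !rows$fall
      if (!any(sel)) {
        if (!any(rows$condition == cond))
          stop(proto, " condition missing: ", cond)
        stop(proto, " condition ", cond, ": all trials are falls")
      }
      mean(vapply(which(sel), fn, numeric(1), rows = rows))
    }, numeric(1))
    mean(per_cond)
  }
  ipl <- score_protocol("sot", 1:4, function(i, rows)
    inverse_path_length(rows$traj[[i]]))
  dc_fn <- function(i, rows)
    directional_control(rows$traj[[i]], rows$target[[i]])
  dc_los <- score_protocol("los", 1:8, dc_fn)
  dc_rws <- score_protocol("rws", 1:6, dc_fn)
  data.frame(ipl_sot = ipl, dc_los = dc_los, dc_rws = dc_rws)
}

#' Association between an imaging descriptor and a balance score
#'
#' Covariate-adjusted Pearson and Spearman correlation between a
#' per-subject imaging descriptor (e.g. the corrected first-component
#' variance of a module) and a balance score, adjusting the imaging
#' variable for age and head motion by default.
#'
#' @param descriptor Numeric imaging variable, one value per subject.
#' @param score Numeric balance score, same order.
#' @param covariates Data frame of confounds (e.g. age, mean FD).
#' @param residualize `"x"` (adjust imaging only, default) or `"both"`.
#' @return See [adjusted_association()].
#' @export
behavior_brain_association <- function(descriptor, score, covariates = NULL,
                                       residualize = c("x", "both")) {
  adjusted_association(descriptor, score, covariates,
                       residualize = match.arg(residualize))
}
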