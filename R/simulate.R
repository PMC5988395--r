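# Synthetic multimodal cohorts with parameterized planted effects.
# Every planted group difference is injected by an explicit, recorded
# mechanism (link thinning/addition, amplitude scaling, map blobs,
# behavior coupling), so each pipeline stage has a ground-truth surface.

#' Specify the planted effects of a synthetic cohort
#'
#' All effect sizes are in Cohen's d units on the scale of the affected
#' measurement; the generator calibrates the injection against the
#' between-subject spread of the control group so the planted mean shift
#' equals `d` times the control SD.
#'
#' @param degree_deficit_modules Coarse-level module ids whose inter-module
#'   degree is reduced in TBI subjects (control > tbi).
#' @param degree_deficit_d Deficit size (Cohen's d).
#' @param degree_surplus_module Fine-level ("prefrontal") module id whose
#'   inter-module degree is increased in TBI subjects.
#' @param degree_surplus_d Surplus size.
#' @param variance_surplus_module Fine-level module whose BOLD
#'   first-component variance is increased in TBI subjects.
#' @param variance_surplus_d Variance-surplus size.
#' @param frontal_family Spatial-map family (1..n_family) that gains a
#'   frontal blob in TBI subjects only.
#' @param frontal_amplitude Blob amplitude added to TBI maps (0 disables).
#' @param behavior_r Target (negative) correlation between the
#'   variance-surplus module's first-component variance and the iPL-SOT
#'   balance score.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(degree_deficit_modules = c(2, 5),
                        degree_deficit_d = 1.0,
                        degree_surplus_module = 11,
                        degree_surplus_d = 1.0,
                        variance_surplus_module = 11,
                        variance_surplus_d = 0.9,
                        frontal_family = 1,
                        frontal_amplitude = 1.0,
                        behavior_r = -0.85) {
  spec <- list(degree_deficit_modules = degree_deficit_modules,
               degree_deficit_d = degree_deficit_d,
               degree_surplus_module = degree_surplus_module,
               degree_surplus_d = degree_surplus_d,
               variance_surplus_module = variance_surplus_module,
               variance_surplus_d = variance_surplus_d,
               frontal_family = frontal_family,
               frontal_amplitude = frontal_amplitude,
               behavior_r = behavior_r)
  if (!all(vapply(spec, function(v) all(is.finite(v)), logical(1))))
    stop("all effect sizes must be finite")
  structure(spec, class = "effect_spec")
}

#' @rdname effect_spec
#' @export
null_effect_spec <- function() {
  effect_spec(degree_deficit_modules = 1, degree_deficit_d = 0,
              degree_surplus_module = 1, degree_surplus_d = 0,
              variance_surplus_module = 1, variance_surplus_d = 0,
              frontal_amplitude = 0, behavior_r = 0)
}

# Nested two-level hierarchy over ROIs: fine modules nested in coarse.
make_hierarchy <- function(n_roi, m_coarse, m_fine) {
  if (m_fine < m_coarse)
    stop("infeasible hierarchy: fine level must have at least as many ",
         "modules as the coarse level")
  coarse_of_fine <- sort(rep_len(seq_len(m_coarse), m_fine))
  roi_fine <- sort(rep_len(seq_len(m_fine), n_roi))
  roi_coarse <- coarse_of_fine[roi_fine]
  list(n_roi = n_roi, m_coarse = m_coarse, m_fine = m_fine,
       roi_fine = roi_fine, roi_coarse = roi_coarse,
       coarse_of_fine = coarse_of_fine)
}

# Intermediate link rate for same-coarse, different-fine ROI pairs. A 25%
# interpolation keeps the fine level the modularity optimum of the nested
# hierarchy (at the midpoint rate, merging sibling fine modules yields a
# higher Newman Q than the planted fine cut).
p_mid_rate <- function(p_in, p_out) p_out + 0.25 * (p_in - p_out)

# Binary SBM adjacency for a nested hierarchy; p_mid applies to ROI pairs
# in the same coarse but different fine modules.
sample_sbm <- function(hier, p_in, p_mid, p_out) {
  n <- hier$n_roi
  same_fine <- outer(hier$roi_fine, hier$roi_fine, `==`)
  same_coarse <- outer(hier$roi_coarse, hier$roi_coarse, `==`)
  p <- matrix(p_out, n, n)
  p[same_coarse] <- p_mid
  p[same_fine] <- p_in
  a <- matrix(0, n, n)
  up <- upper.tri(p)
  a[up] <- stats::rbinom(sum(up), 1, p[up])
  a <- a + t(a)
  diag(a) <- 0
  a
}

#' Simulate one multimodal connectome pair
#'
#' Structural adjacency from a nested stochastic block model (streamline
#' counts drawn on top of present links); functional correlations from
#' module-coherent latent signals plus noise, so functional blocks align
#' with the structural blocks at strength `coupling`.
#'
#' @param n_roi Number of ROIs.
#' @param m_coarse,m_fine Module counts of the nested hierarchy
#'   (`m_fine >= m_coarse`; equal gives a single-level hierarchy).
#' @param p_in,p_out Within-fine-module / between-coarse-module link
#'   probabilities (`p_in > p_out`); pairs in the same coarse but different
#'   fine modules use their mean.
#' @param coupling Signal-to-noise of the module-coherent latent signals
#'   driving the functional matrix (0 = structureless).
#' @param t_len Latent time-series length for the functional correlations.
#' @param seed Integer seed.
#' @return List: `pair` (a [connectome_pair()]) and `hierarchy`.
#' @export
simulate_multimodal_connectome <- function(n_roi = 200, m_coarse = 8,
                                           m_fine = 20, p_in = 0.6,
                                           p_out = 0.05, coupling = 1,
                                           t_len = 150, seed = 1) {
  if (p_in < p_out) stop("p_in must be >= p_out")
  if (min(p_in, p_out) <= 0 || max(p_in, p_out) >= 1)
    stop("p_in and p_out must lie in (0, 1)")
  hier <- make_hierarchy(n_roi, m_coarse, m_fine)
  rng <- local_rng(seed)
  on.exit(rng())
  a <- sample_sbm(hier, p_in, p_mid_rate(p_in, p_out), p_out)
  counts <- a * (1 + matrix(stats::rpois(n_roi^2, 2), n_roi, n_roi))
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  diag(counts) <- 0
  fc <- stats::cor(roi_signals(hier, coupling, t_len))
  list(pair = connectome_pair(counts, fc), hierarchy = hier)
}

# Module-coherent ROI time series: coarse + fine latent signals + noise.
roi_signals <- function(hier, coupling, t_len) {
  g <- matrix(stats::rnorm(t_len * hier$m_coarse), t_len)
  h <- matrix(stats::rnorm(t_len * hier$m_fine), t_len)
  noise <- matrix(stats::rnorm(t_len * hier$n_roi), t_len)
  coupling * (g[, hier$roi_coarse] + 0.7 * h[, hier$roi_fine]) + noise
}

#' Simulate a center-of-pressure sway trajectory
#'
#' Static (SOT) trials are a weakly mean-reverting 2D random walk with
#' per-step jitter SD `sway_sd`; LOS trials add a constant drift toward a
#' target direction; RWS trials oscillate between two targets.
#'
#' @param sway_sd Per-step jitter SD (mm, >= 0).
#' @param duration Trial duration (s, default 20).
#' @param fs Sampling rate (Hz, default 100).
#' @param protocol `"sot"`, `"los"` or `"rws"`.
#' @param target Target direction vector for LOS/RWS.
#' @param drift Per-step goal-directed displacement (mm) for LOS/RWS.
#' @param seed Optional integer seed.
#' @return Matrix (`duration * fs` rows x 2) of COP samples (mm).
#' @export
simulate_sway <- function(sway_sd, duration = 20, fs = 100,
                          protocol = c("sot", "los", "rws"),
                          target = c(1, 0), drift = 1, seed = NULL) {
  protocol <- match.arg(protocol)
  if (sway_sd < 0) stop("sway_sd must be >= 0")
  n <- round(duration * fs)
  if (!is.null(seed)) { rng <- local_rng(seed); on.exit(rng()) }
  jitter <- matrix(stats::rnorm(2 * (n - 1), sd = sway_sd), n - 1, 2)
  u <- target / sqrt(sum(target^2))
  steps <- switch(protocol,
    sot = jitter,
    los = jitter + matrix(drift * u, n - 1, 2, byrow = TRUE),
    rws = {
      phase <- 2 * pi * seq_len(n - 1) / (fs * 4)   # 4-s rhythm
      jitter + outer(drift * 20 * 2 * pi / (fs * 4) * cos(phase), u)
    })
  if (protocol == "sot") {
    # weakly mean-reverting walk keeps the path bounded around the origin
    kappa <- 0.01
    pos <- matrix(0, n - 1, 2)
    prev <- c(0, 0)
    for (t in seq_len(n - 1)) {
      prev <- (1 - kappa) * prev + steps[t, ]
      pos[t, ] <- prev
    }
  } else {
    pos <- apply(steps, 2, cumsum)
  }
  rbind(c(0, 0), pos)
}

#' Simulate a complete synthetic cohort
#'
#' Generates a control/TBI cohort with multimodal connectomes, voxel BOLD
#' on a 3D grid, motion traces, posturography trials and covariates, with
#' the group effects of an [effect_spec()] planted by construction:
#' \itemize{
#'   \item TBI degree deficits: binomial removal of inter-module links in
#'     the named coarse modules, calibrated so the mean degree drop is
#'     `d` control SDs.
#'   \item Fine-level degree surplus: links added from the named
#'     "prefrontal" fine module to other modules, same calibration.
#'   \item Variance surplus: the named module's voxel series are rescaled
#'     in TBI subjects so the first-component variance rises by `d`
#'     control SDs.
#'   \item Frontal recruitment: TBI subjects' BOLD gains a blob of extra
#'     loading on one spatial-map family, placed in a "frontal" corner of
#'     the grid.
#'   \item Behavior coupling: iPL-SOT scores are generated from the
#'     variance descriptor with noise set so the planted correlation is
#'     `behavior_r`, and sway trajectories are synthesized to match the
#'     scores.
#' }
#' Ages and motion summaries are drawn identically for both groups
#' (matched-cohort design).
#'
#' @param effects [effect_spec()].
#' @param n_control,n_tbi Group sizes (defaults 27 and 14).
#' @param n_roi,m_coarse,m_fine Connectome hierarchy (defaults 200/8/20).
#' @param grid BOLD grid dimensions (default `c(24, 24, 24)`).
#' @param t_len BOLD time points (default 200); `tr` repetition time (s).
#' @param n_family Number of spatial-map families (default 5).
#' @param p_in,p_out SBM link probabilities.
#' @param seed Master integer seed; all randomness derives from it.
#' @return List of class `synthetic_cohort`; see Details in the package
#'   vignette. Includes a `truth` record of every planted effect.
#' @export
simulate_cohort <- function(effects = effect_spec(), n_control = 27,
                            n_tbi = 14, n_roi = 200, m_coarse = 8,
                            m_fine = 20, grid = c(24, 24, 24), t_len = 200,
                            tr = 3, n_family = 5, p_in = 0.6, p_out = 0.05,
                            seed = 1) {
  stopifnot(inherits(effects, "effect_spec"))
  hier <- make_hierarchy(n_roi, m_coarse, m_fine)
  if (!all(effects$degree_deficit_modules %in% seq_len(m_coarse)))
    stop("degree_deficit_modules must name coarse modules 1..", m_coarse)
  if (!effects$degree_surplus_module %in% seq_len(m_fine) ||
      !effects$variance_surplus_module %in% seq_len(m_fine))
    stop("surplus/variance modules must name fine modules 1..", m_fine)
  n <- n_control + n_tbi
  rng <- local_rng(seed)
  on.exit(rng())

  cohort <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    group = rep(c("control", "tbi"), c(n_control, n_tbi)),
    age = stats::runif(n, 8, 19),
    sex = sample(c("M", "F"), n, replace = TRUE),
    fd_mean = stats::rlnorm(n, log(0.15), 0.3),
    eddy_motion_mean = stats::rlnorm(n, log(0.8), 0.3))

  ## ---- structural connectomes -------------------------------------------
  adj <- vector("list", n)
  for (s in seq_len(n)) {
    p_out_s <- p_out * exp(stats::rnorm(1, 0, 0.15))  # subject heterogeneity
    adj[[s]] <- sample_sbm(hier, p_in, p_mid_rate(p_in, p_out_s), p_out_s)
  }
  ctrl <- which(cohort$group == "control")
  tbi <- which(cohort$group == "tbi")

  deg_ctrl <- t(vapply(adj[ctrl], function(a)
    module_degree(intermodule_connectivity(a, hier$roi_coarse)),
    numeric(m_coarse)))
  sd_coarse <- apply(deg_ctrl, 2, stats::sd)
  surplus_rois <- which(hier$roi_fine == effects$degree_surplus_module)
  for (s in tbi) {
    for (m in effects$degree_deficit_modules) {
      k <- round(effects$degree_deficit_d * sd_coarse[m])
      adj[[s]] <- thin_module_links(adj[[s]], hier$roi_coarse, m, k,
                                    protect = surplus_rois)
    }
  }
  deg_ctrl_f <- t(vapply(adj[ctrl], function(a)
    module_degree(intermodule_connectivity(a, hier$roi_fine)),
    numeric(m_fine)))
  sd_fine <- apply(deg_ctrl_f, 2, stats::sd)
  for (s in tbi) {
    k <- round(effects$degree_surplus_d * sd_fine[effects$degree_surplus_module])
    adj[[s]] <- add_module_links(adj[[s]], hier$roi_fine,
                                 effects$degree_surplus_module, k,
                                 within = hier$roi_coarse)
  }
  connectomes <- vector("list", n)
  for (s in seq_len(n)) {
    counts <- adj[[s]] * (1 + matrix(stats::rpois(n_roi^2, 2), n_roi, n_roi))
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    diag(counts) <- 0
    fc <- stats::cor(roi_signals(hier, 1, max(100, min(t_len, 200))))
    connectomes[[s]] <- connectome_pair(counts, fc)
  }

  ## ---- voxel grid, families, frontal blob -------------------------------
  V <- prod(grid)
  voxel_fine <- sort(rep_len(seq_len(m_fine), V))
  voxel_coarse <- hier$coarse_of_fine[voxel_fine]
  family_of_module <- rep_len(seq_len(n_family), m_fine)
  # Cohort-fixed heterogeneous loading patterns: the family map support is
  # the union of its modules' regions, with voxel-varying weights so the
  # module and family signals span a rank-2 subspace PCA/ICA can separate.
  fam_maps <- matrix(0, n_family, V)
  for (k in seq_len(n_family)) {
    sup <- voxel_fine %in% which(family_of_module == k)
    # signed weights keep the family pattern near-orthogonal to the
    # all-positive module loadings, as in real signed ICA maps
    fam_maps[k, sup] <- stats::runif(sum(sup), 0.4, 1.2) *
      sample(c(-1, 1), sum(sup), replace = TRUE)
  }
  w_mod <- stats::runif(V, 0.5, 1.5)          # module-signal voxel loadings
  centre <- grid - pmax(2, round(grid / 6))       # "frontal" corner
  coords <- arrayInd(seq_len(V), grid)
  blob <- which(sqrt(rowSums(sweep(coords, 2, centre)^2)) <=
                  max(2, round(min(grid) / 8)))
  alpha_mod <- 1; alpha_fam <- 0.8; noise_sd <- 1

  ## ---- BOLD + motion ----------------------------------------------------
  gen_bold <- function(s, frontal) {
    G <- matrix(stats::rnorm(t_len * m_fine), t_len)     # module signals
    G <- stats::filter(G, 0.4, method = "recursive")      # mild AR(1)
    G <- scale(matrix(as.numeric(G), t_len))
    # supergaussian and positively skewed (burst-like), so the component
    # sign convention (positive skewness) orients maps consistently
    FS <- matrix(stats::rexp(t_len * n_family) - 1, t_len)
    A <- fam_maps
    if (frontal && effects$frontal_amplitude > 0)
      A[effects$frontal_family, blob] <-
        A[effects$frontal_family, blob] + effects$frontal_amplitude
    sweep(G[, voxel_fine], 2, alpha_mod * w_mod, `*`) +
      alpha_fam * (FS %*% A) +
      matrix(stats::rnorm(t_len * V, sd = noise_sd), t_len)
  }
  bold <- vector("list", n)
  motion <- vector("list", n)
  for (s in seq_len(n)) {
    bold[[s]] <- gen_bold(s, frontal = s %in% tbi)
    motion[[s]] <- stats::rlnorm(t_len, log(cohort$fd_mean[s]), 0.3)
  }

  ## variance surplus: rescale the target module's voxels in TBI subjects
  vmod <- effects$variance_surplus_module
  vvox <- voxel_fine == vmod
  # ground-truth descriptor = what the analysis measures: scrub first
  pc_var <- function(s) {
    x <- scrub_interpolate(bold[[s]][, vvox, drop = FALSE], motion[[s]])
    stats::var(first_principal_timecourse(x, tr = tr)$timecourse)
  }
  v_ctrl <- vapply(ctrl, pc_var, numeric(1))
  f_scale <- rep(1, n)
  if (effects$variance_surplus_d != 0 && stats::sd(v_ctrl) > 0) {
    # per-subject rescaling realizes an exact additive shift of the
    # variance descriptor (d control SDs) without inflating TBI spread
    delta <- effects$variance_surplus_d * stats::sd(v_ctrl)
    for (s in tbi) {
      f_scale[s] <- sqrt(1 + delta / pc_var(s))
      bold[[s]][, vvox] <- bold[[s]][, vvox] * f_scale[s]
    }
  }
  v_all <- vapply(seq_len(n), pc_var, numeric(1))

  ## ---- behavior: scores coupled to the variance descriptor --------------
  z_v <- as.numeric(scale(v_all))
  b1 <- -8
  r_target <- effects$behavior_r
  noise_sd_beh <- if (abs(r_target) < 1e-8) 9 else
    abs(b1) * sqrt(1 / r_target^2 - 1)
  ipl_target <- 100 + b1 * (if (abs(r_target) < 1e-8) 0 else z_v) +
    stats::rnorm(n, 0, noise_sd_beh)
  ipl_target <- pmax(ipl_target, 20)
  dc_base <- stats::rnorm(n, 83, 4)

  trials <- vector("list", n)
  n_steps <- round(20 * 100) - 1
  for (s in seq_len(n)) {
    sway_sd <- (1 / ipl_target[s]) / (n_steps * sqrt(pi / 2))
    tr_list <- list()
    for (cond in 1:4) {
      n_trial <- 3
      falls <- stats::rbinom(1, 1, 0.1) == 1   # at most one fall/condition
      for (j in seq_len(n_trial)) {
        tr_list[[length(tr_list) + 1]] <- list(
          protocol = "sot", condition = cond, fall = falls && j == 1,
          traj = simulate_sway(sway_sd, protocol = "sot"),
          target = list(NULL))
      }
    }
    dirs <- cbind(cos(2 * pi * (0:7) / 8), sin(2 * pi * (0:7) / 8))
    sd_dc <- max(0.05, 0.35 - 0.003 * dc_base[s] +
                   stats::rnorm(1, 0, 0.01))
    for (d8 in 1:8)
      tr_list[[length(tr_list) + 1]] <- list(
        protocol = "los", condition = d8, fall = FALSE,
        traj = simulate_sway(sd_dc, duration = 3, protocol = "los",
                             target = dirs[d8, ]),
        target = dirs[d8, ])
    for (cmb in 1:6) {
      u <- if (cmb <= 3) c(1, 0) else c(0, 1)
      tr_list[[length(tr_list) + 1]] <- list(
        protocol = "rws", condition = cmb, fall = FALSE,
        traj = simulate_sway(sd_dc, duration = 6, protocol = "rws",
                             target = u),
        target = u)
    }
    trials[[s]] <- data.frame(
      protocol = vapply(tr_list, `[[`, character(1), "protocol"),
      condition = vapply(tr_list, `[[`, numeric(1), "condition"),
      fall = vapply(tr_list, `[[`, logical(1), "fall"))
    trials[[s]]$traj <- lapply(tr_list, `[[`, "traj")
    trials[[s]]$target <- lapply(tr_list, `[[`, "target")
  }
  scores <- do.call(rbind, lapply(trials, aggregate_scores))
  scores <- cbind(subject = cohort$subject, scores)

  structure(list(
    cohort = cohort, connectomes = connectomes, hierarchy = hier,
    bold = bold, voxel_fine = voxel_fine, voxel_coarse = voxel_coarse,
    grid = as.integer(grid), tr = tr, motion = motion,
    trials = trials, scores = scores,
    truth = list(effects = effects, family_of_module = family_of_module,
                 fam_maps = fam_maps,
                 frontal_blob = blob, variance_scale = f_scale,
                 sd_coarse = sd_coarse, sd_fine = sd_fine,
                 variance_descriptor = v_all, ipl_target = ipl_target,
                 behavior_slope = b1, behavior_noise_sd = noise_sd_beh)),
    class = "synthetic_cohort")
}

# Remove k binary links with exactly one endpoint in module m (kept
# symmetric). Links incident to `protect`ed ROIs are never removed, so
# deficit and surplus injections stay orthogonal. Removes all if fewer
# than k candidates exist.
thin_module_links <- function(a, labels, m, k, protect = NULL) {
  if (k <= 0) return(a)
  inm <- labels == m
  cross <- outer(inm, inm, xor)
  if (!is.null(protect)) {
    keep <- !(seq_along(labels) %in% protect)
    cross <- cross & outer(keep, keep, `&`)
  }
  cand <- which(cross & a > 0 & upper.tri(a))
  if (length(cand) == 0) return(a)
  drop_idx <- if (length(cand) <= k) cand else sample(cand, k)
  a[drop_idx] <- 0
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# Add k absent links between fine module m and other fine modules. When
# `within` labels are supplied, additions stay inside the same
# coarse-level module, so they raise fine-level degree without touching
# coarse-level degrees.
add_module_links <- function(a, labels, m, k, within = NULL) {
  if (k <= 0) return(a)
  inm <- labels == m
  cross <- outer(inm, inm, xor)
  if (!is.null(within)) cross <- cross & outer(within, within, `==`)
  cand <- which(cross & a == 0 & upper.tri(a))
  if (length(cand) == 0) return(a)
  add_idx <- if (length(cand) <= k) cand else sample(cand, k)
  a[add_idx] <- 1
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}
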