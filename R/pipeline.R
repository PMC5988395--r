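# Pipeline orchestration: a structured config, per-stage seeds derived
# from one master seed, staged execution and a plain-text report.

#' Default analysis configuration
#'
#' Central container for every tunable constant of the pipeline. Values
#' round-trip unchanged through YAML serialization.
#'
#' @param ... Overrides of the defaults (unknown names are an error).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    n_control = 27, n_tbi = 14,
    n_roi = 200, m_coarse = 8, m_fine = 20,
    grid = c(24, 24, 24), t_len = 200, tr = 3,
    n_perm = 1000, n_iter = 10000, alpha = 0.05,
    voxel_p = 0.005, k_mrc = 5, n_components = 20,
    fd_threshold = 0.5, ppa_z = 1, fwhm = 2, connect = 6,
    m_range = 2:12, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$voxel_p > 0, cfg$voxel_p < 1,
            cfg$n_perm >= 1, cfg$n_iter >= 1, cfg$k_mrc >= 2,
            cfg$fd_threshold > 0)
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname analysis_config
#' @param config An `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Deterministic per-stage seeds from the master seed (kept below 2^31).
stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000003L
  stats::setNames(as.list((base * 131L + seq_len(6) * 7919L) %% 2147483647L),
                  c("simulate", "atlas", "structural", "dynamics",
                    "funcnet", "behavior"))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate, atlas, structural, dynamics, funcnet and behavior
#' stages on a synthetic cohort and collects the per-stage result tables.
#'
#' @param config [analysis_config()].
#' @param effects [effect_spec()] for the simulated cohort; by default the
#'   standard planted effects, with module ids clamped into the config's
#'   hierarchy.
#' @param stages Character vector of stages to run (default all).
#' @param cohort Optionally, a pre-built `synthetic_cohort` to analyse
#'   (skips the simulate stage).
#' @param verbose Print stage progress.
#' @return List of class `pipeline_result` with one element per stage plus
#'   `config`.
#' @export
run_pipeline <- function(config = analysis_config(),
                         effects = default_effects(config),
                         stages = c("atlas", "structural", "dynamics",
                                    "funcnet", "behavior"),
                         cohort = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list(config = config)

  if (is.null(cohort)) {
    say("[simulate] cohort n=%d+%d, %d ROIs, grid %s",
        config$n_control, config$n_tbi, config$n_roi,
        paste(config$grid, collapse = "x"))
    cohort <- simulate_cohort(effects, n_control = config$n_control,
                              n_tbi = config$n_tbi, n_roi = config$n_roi,
                              m_coarse = config$m_coarse,
                              m_fine = config$m_fine, grid = config$grid,
                              t_len = config$t_len, tr = config$tr,
                              seed = seeds$simulate)
  }
  res$cohort <- cohort
  design <- make_design(cohort$cohort, c("age", "eddy_motion_mean"))
  design_fd <- make_design(cohort$cohort, c("age", "fd_mean"))

  if ("atlas" %in% stages) {
    say("[atlas] selecting hierarchy level by cross-modularity")
    pool <- cohort_average_pair(cohort)
    res$atlas <- select_optimal_level(pool, config$m_range)
    say("[atlas] optimal M = %d", res$atlas$m_star)
  }

  if ("structural" %in% stages) {
    say("[structural] module-degree group comparison (n_perm=%d)",
        config$n_perm)
    deg_coarse <- cohort_module_degrees(cohort$connectomes,
                                        cohort$hierarchy$roi_coarse)
    deg_fine <- cohort_module_degrees(cohort$connectomes,
                                      cohort$hierarchy$roi_fine)
    res$structural <- list(
      coarse = structural_group_comparison(deg_coarse, design,
                                           n_perm = config$n_perm,
                                           seed = seeds$structural,
                                           alpha = config$alpha),
      fine = structural_group_comparison(deg_fine, design,
                                         n_perm = config$n_perm,
                                         seed = seeds$structural + 1L,
                                         alpha = config$alpha))
  }

  if ("dynamics" %in% stages) {
    say("[dynamics] first-PC descriptors and group comparison")
    desc <- cohort_dynamics(cohort$bold, cohort$voxel_fine,
                            motion = cohort$motion,
                            fd_threshold = config$fd_threshold,
                            tr = config$tr)
    res$dynamics <- list(
      descriptors = desc,
      variance = dynamics_group_comparison(desc, design_fd, "variance",
                                           n_perm = config$n_perm,
                                           seed = seeds$dynamics,
                                           alpha = config$alpha))
  }

  if ("funcnet" %in% stages) {
    say("[funcnet] PCA+ICA spatial maps, MRC clustering, cluster FWE")
    res$funcnet <- funcnet_stage(cohort, design, config,
                                 seed = seeds$funcnet)
  }

  if ("behavior" %in% stages) {
    say("[behavior] balance scores and brain-behavior association")
    vmat <- if (!is.null(res$dynamics))
      descriptor_matrix(res$dynamics$descriptors, "variance") else
        descriptor_matrix(cohort_dynamics(cohort$bold, cohort$voxel_fine),
                          "variance")
    vmod <- cohort$truth$effects$variance_surplus_module
    res$behavior <- list(
      scores = cohort$scores,
      association = behavior_brain_association(
        vmat[, vmod], cohort$scores$ipl_sot,
        covariates = cohort$cohort[, c("age", "fd_mean")]))
  }
  structure(res, class = "pipeline_result")
}

# Standard planted effects with module ids clamped into the config's
# hierarchy, so demo runs work at any scale.
default_effects <- function(config) {
  eff <- effect_spec()
  eff$degree_deficit_modules <-
    unique(pmin(eff$degree_deficit_modules, config$m_coarse))
  eff$degree_surplus_module <- min(eff$degree_surplus_module, config$m_fine)
  eff$variance_surplus_module <- min(eff$variance_surplus_module,
                                     config$m_fine)
  eff
}

# Cohort-average connectome pair for the atlas stage.
cohort_average_pair <- function(cohort) {
  scs <- Reduce(`+`, lapply(cohort$connectomes, `[[`, "sc"))
  fcs <- Reduce(`+`, lapply(cohort$connectomes, `[[`, "fc"))
  n <- length(cohort$connectomes)
  connectome_pair(round(scs / n), fcs / n)
}

# Per-module funcnet stage: ICA components, spatial maps, pooled k-means,
# MRC-wise group contrasts with cluster-extent correction.
funcnet_stage <- function(cohort, design, config, seed = 1,
                          modules = NULL) {
  n_sub <- nrow(cohort$cohort)
  labels <- cohort$voxel_fine
  modules <- modules %||% sort(unique(labels))
  n_comp <- config$n_components
  maps <- list(); prov <- list()
  for (m in modules) {
    vox <- labels == m
    for (s in seq_len(n_sub)) {
      cs <- module_ica_components(cohort$bold[[s]][, vox, drop = FALSE],
                                  n_pca = n_comp, seed = seed + 1000L * m + s)
      sm <- component_spatial_map(cohort$bold[[s]], cs)
      maps[[length(maps) + 1]] <- sm
      prov[[length(prov) + 1]] <- data.frame(
        module = m, subject = s, component = seq_len(nrow(sm)))
    }
  }
  maps <- do.call(rbind, maps)
  prov <- do.call(rbind, prov)
  mrc <- cluster_spatial_maps(maps, k = config$k_mrc, seed = seed,
                              provenance = prov)
  null <- cluster_extent_threshold(cohort$grid, fwhm = config$fwhm,
                                   voxel_p = config$voxel_p,
                                   alpha = config$alpha,
                                   n_iter = config$n_iter,
                                   connect = config$connect, seed = seed)
  contrasts <- list()
  for (m in modules) {
    for (cl in seq_len(config$k_mrc)) {
      keep <- prov$module == m & mrc$labels == cl
      if (!any(keep)) next
      sub <- unique(prov$subject[keep])
      if (!all(c("control", "tbi") %in% as.character(design$groups[sub])))
        next
      if (length(sub) < ncol(design$X) + 2) next  # too few for the GLM
      if (qr(design$X[sub, , drop = FALSE])$rank < ncol(design$X)) next
      tm <- mrc_group_contrast(maps, prov, keep, design)
      surv <- lapply(tm[c("control_minus_tbi", "tbi_minus_control")],
                     function(v) apply_cluster_correction(
                       array(v, dim = cohort$grid), tm$df, null))
      contrasts[[paste0("module", m, "_mrc", cl)]] <-
        list(module = m, mrc = cl, tmaps = tm, surviving = surv)
    }
  }
  list(assignment = mrc, null = null, contrasts = contrasts,
       provenance = prov)
}

#' Plain-text summary report of a pipeline result
#'
#' @param result `pipeline_result` from [run_pipeline()].
#' @param path Optional file to write; otherwise returns the lines.
#' @return Character vector of report lines, invisibly when written.
#' @export
write_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  if (length(result) <= 1) stop("empty result bundle")
  ln <- c("Cross-modularity connectome pipeline report",
          sprintf("master seed: %d", result$config$seed), "")
  if (!is.null(result$atlas))
    ln <- c(ln, sprintf("[atlas] optimal level M* = %d (X = %.3f)",
                        result$atlas$m_star,
                        max(result$atlas$cross_modularity)), "")
  fmt_tab <- function(tab, label) {
    sig <- tab[!tab$discarded, , drop = FALSE]
    c(sprintf("[%s] flagged modules (permutation p < alpha):", label),
      if (nrow(sig) == 0) "  none" else
        sprintf("  %s: t = %.3f, p_perm = %.4f, g = %.3f [%.3f, %.3f]",
                sig$feature, sig$t, sig$p_perm, sig$g, sig$ci_low,
                sig$ci_high),
      "")
  }
  if (!is.null(result$structural))
    ln <- c(ln, fmt_tab(result$structural$coarse, "structural coarse"),
            fmt_tab(result$structural$fine, "structural fine"))
  if (!is.null(result$dynamics))
    ln <- c(ln, fmt_tab(result$dynamics$variance, "dynamics variance"))
  if (!is.null(result$funcnet)) {
    surv <- unlist(lapply(result$funcnet$contrasts, function(cc)
      vapply(cc$surviving, nrow, integer(1))))
    ln <- c(ln, sprintf("[funcnet] MRC contrasts with surviving clusters: %d",
                        sum(surv > 0)),
            sprintf("  cluster-extent minimum size: %d voxels",
                    result$funcnet$null$min_size), "")
  }
  if (!is.null(result$behavior)) {
    a <- result$behavior$association
    ln <- c(ln, sprintf(
      "[behavior] corrected variance vs iPL-SOT: r = %.3f (p = %.2g), s = %.3f (p = %.2g)",
      a$pearson_r, a$pearson_p, a$spearman_s, a$spearman_p), "")
  }
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}
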