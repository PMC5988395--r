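# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no binary fixtures.

# Two-block similarity matrix with planted labels.
two_block_similarity <- function(n_per_block = 4, s_in = 0.9, s_out = 0.1) {
  n <- 2 * n_per_block
  labels <- rep(1:2, each = n_per_block)
  s <- matrix(s_out, n, n)
  s[outer(labels, labels, `==`)] <- s_in
  diag(s) <- 1
  list(similarity = s, labels = labels)
}

# Perfect K-block connectome pair: complete within blocks, empty between.
perfect_block_pair <- function(k = 4, n_per_block = 5) {
  n <- k * n_per_block
  labels <- rep(seq_len(k), each = n_per_block)
  block <- outer(labels, labels, `==`) * 1
  sc <- block * 3
  diag(sc) <- 0
  fc <- block
  diag(fc) <- 1
  list(pair = connectome_pair(sc, fc), labels = labels)
}

# Independent brute-force connected-components oracle: breadth-first
# search over the 6-neighborhood, no package machinery.
bf_max_cluster <- function(mask) {
  dims <- dim(mask)
  seen <- array(FALSE, dims)
  best <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1L
      co <- arrayInd(v, dims)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- co
        nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1 || nb[ax] > dims[ax]) next
        lin <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (mask[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    best <- max(best, size)
  }
  best
}

# Brute-force cluster-extent threshold for independent voxels (fwhm = 0):
# direct Bernoulli masks, no smoothing machinery.
bf_extent_threshold <- function(grid, voxel_p, alpha, n_iter, seed) {
  set.seed(seed)
  mx <- integer(n_iter)
  for (b in seq_len(n_iter)) {
    pos <- array(runif(prod(grid)) < voxel_p / 2, dim = grid)
    neg <- array(runif(prod(grid)) < voxel_p / 2, dim = grid)
    mx[b] <- max(bf_max_cluster(pos), bf_max_cluster(neg))
  }
  s <- 1L
  while (mean(mx >= s) > alpha) s <- s + 1L
  s
}

# Five planted spatial-map families: distinct blob supports plus noise.
planted_map_families <- function(n_per_family = 40, v = 200, seed = 1,
                                 noise_sd = 0.3) {
  set.seed(seed)
  supports <- split(seq_len(v), rep_len(1:5, v))
  maps <- list(); labels <- integer()
  for (k in 1:5) {
    base <- numeric(v)
    base[supports[[k]]] <- runif(length(supports[[k]]), 1, 2)
    for (j in seq_len(n_per_family)) {
      maps[[length(maps) + 1]] <- base + rnorm(v, sd = noise_sd)
      labels <- c(labels, k)
    }
  }
  list(maps = do.call(rbind, maps), labels = labels)
}

# Reduced-scale paper-mimicking cohort, cached per seed for reuse.
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed, effects = effect_spec(), grid = c(12, 12, 12),
                         t_len = 120) {
  key <- paste0(seed, "_", paste(grid, collapse = "x"), "_",
                signif(effects$variance_surplus_d, 3), "_",
                signif(effects$frontal_amplitude, 3))
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(
      effects, n_control = 27, n_tbi = 14, n_roi = 120, m_coarse = 8,
      m_fine = 20, grid = grid, t_len = t_len, seed = seed)
  .cohort_cache[[key]]
}
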