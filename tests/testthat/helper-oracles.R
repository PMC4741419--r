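# Independent oracles and small data builders used across the suite.

# Forward model: voxel intensities from concentrations and true intensities.
mix_y <- function(mu_gm, mu_wm, c_gm, noise_sd = 0) {
  y <- mu_gm * c_gm + mu_wm * (1 - c_gm)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  y
}

# Brute-force profiled-RSS grid search over (mu_gm, mu_wm) on a 1-ms grid.
# For each pair the concentrations are profiled per voxel (clamped
# least squares) and the minimum RSS over the grid is returned.
grid_search_rss <- function(y, mu_range = c(600, 1800), step = 1) {
  mus <- seq(mu_range[1], mu_range[2], by = step)
  k <- length(mus)
  # all pairs b < a as vectors
  ia <- rep.int(seq_len(k), times = seq_len(k) - 1L)   # index of a (larger)
  ib <- unlist(lapply(seq_len(k), function(i) seq_len(i - 1L)))
  a <- mus[ia]; b <- mus[ib]
  d <- a - b
  rss <- numeric(length(a))
  for (yi in y) {
    t1 <- yi - b
    cl <- t1 / d
    cl[cl < 0] <- 0; cl[cl > 1] <- 1
    resid <- t1 - d * cl
    rss <- rss + resid * resid
  }
  j <- which.min(rss)
  list(rss = rss[j], mu_gm = a[j], mu_wm = b[j])
}

# Exact permutation two-sample |t| p-value by full enumeration over all
# group-1 index sets (independent of the package's implementation).
enumerate_perm_p <- function(x, group) {
  g <- factor(group)
  n1 <- sum(g == levels(g)[1])
  n <- length(x)
  tstat <- function(idx) {
    x1 <- x[idx]; x2 <- x[-idx]
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n - 2)
    if (sp2 <= 0) return(0)
    abs((mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / (n - n1))))
  }
  t_obs <- tstat(which(g == levels(g)[1]))
  sets <- utils::combn(n, n1)
  ts <- apply(sets, 2, tstat)
  mean(ts >= t_obs - 1e-12)
}

# A tiny single-region label volume: `n` voxels labelled as thalamus
# inside a small grid, with given values.
tiny_region <- function(values, dim = c(6, 6, 6)) {
  stopifnot(length(values) <= prod(dim))
  vals <- array(0, dim = dim)
  labs <- array(0L, dim = dim)
  idx <- seq_along(values)
  vals[idx] <- values
  labs[idx] <- 1L
  list(t1 = t1_volume(vals), labels = label_volume(labs))
}

# Feature-table builder for group_stats tests: per-region iid normal
# features for n subjects (null by default).
null_feature_table <- function(n, regions = c("thalamus", "caudate"),
                               shift = list()) {
  df <- data.frame(subject_id = sprintf("s%02d", seq_len(n)))
  for (r in regions) {
    df[[paste0(r, "_mu_gm")]] <- rnorm(n, 1400, 45)
    df[[paste0(r, "_mu_wm")]] <- rnorm(n, 910, 16)
    df[[paste0(r, "_ratio")]] <- rnorm(n, 0.9, 0.05)
    df[[paste0(r, "_mean_t1")]] <- rnorm(n, 1100, 30)
    df[[paste0(r, "_n_voxels")]] <- 500
    if (r %in% names(shift)) {
      s <- shift[[r]]
      for (cn in names(s)) df[[paste0(r, "_", cn)]] <-
          df[[paste0(r, "_", cn)]] + s[[cn]]
    }
  }
  df
}

null_cohort <- function(n, n_hc = floor(n / 2)) {
  data.frame(subject_id = sprintf("s%02d", seq_len(n)),
             group = rep(c("HC", "PATIENT"), c(n_hc, n - n_hc)),
             age = rnorm(n, 34, 9), sex = sample(c("F", "M"), n, TRUE))
}
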