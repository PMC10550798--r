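# Shared fixture builders. Everything is generated in code; no files.

# One logistic curve as a curves tibble, defaulting to a clean noise-free
# amplification.
make_curve <- function(amplitude = 1, midpoint = 25, steepness = 1.5,
                       noise_sd = 0, intercept = 0.05, slope = 0.001,
                       n_cycles = 40, seed = 1, sample_id = "s1",
                       well = "w001", target_id = "t1", card = "A") {
  simulate_curve(
    curve_params(baseline_intercept = intercept, baseline_slope = slope,
                 amplitude = amplitude, midpoint_cycle = midpoint,
                 steepness = steepness, noise_sd = noise_sd,
                 n_cycles = n_cycles),
    seed = seed, sample_id = sample_id, well = well,
    target_id = target_id, card = card
  )
}

# Long Cq tibble from a targets x samples matrix (rows = targets).
cq_from_matrix <- function(mat, groups = NULL, card = "A",
                           targets = NULL, samples = NULL) {
  if (is.null(targets)) targets <- sprintf("t%02d", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(mat)))
  if (is.null(groups)) groups <- rep("g", ncol(mat))
  tibble::tibble(
    target_id = rep(targets, times = ncol(mat)),
    card = card,
    sample_id = rep(samples, each = nrow(mat)),
    group = rep(groups, each = nrow(mat)),
    cq = as.vector(mat),
    control = NA_character_
  )
}

# Independent brute-force oracles for the pairwise stability statistics:
# plain double loops over candidate pairs, no shared code with the package.
oracle_pairwise_stats <- function(mat) {
  k <- nrow(mat)
  m <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (l in seq_len(k)) {
      if (l == j) next
      diffs <- mat[j, ] - mat[l, ]
      mu <- sum(diffs) / length(diffs)
      acc <- acc + sqrt(sum((diffs - mu)^2) / (length(diffs) - 1))
    }
    m[j] <- acc / (k - 1)
  }
  m
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n1+n2, n1) group assignments (distinct values assumed).
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  ws <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(ws <= w_obs)
  p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}
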