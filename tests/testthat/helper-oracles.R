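# Independent oracles used across test files.

# pairwise-count definition of the Brunner-Munzel relative effect
# P(X < Y) + 0.5 P(X = Y), enumerated pair by pair
pairwise_relative_effect <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y) {
    s <- s + (xi < yi) + 0.5 * (xi == yi)
  }
  s / (length(x) * length(y))
}

# exhaustive permutation p-value of the studentized Brunner-Munzel
# statistic: all choose(N, n1) group assignments of the pooled values
bm_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- abs(vmti::brunner_munzel(x, y)$statistic)
  idx <- utils::combn(length(pooled), n1)
  stats <- apply(idx, 2, function(i) {
    abs(vmti::brunner_munzel(pooled[i], pooled[-i])$statistic)
  })
  mean(stats >= obs - 1e-9)
}

# brute-force voxelwise overlap count by explicit looping
loop_overlap <- function(masks) {
  out <- array(0L, dim(masks[[1]]))
  for (m in masks) {
    for (i in seq_along(out)) out[i] <- out[i] + m[i]
  }
  out
}

# small lesion configuration for fast VLSM simulations
small_lesion_config <- function(...) {
  vmti::lesion_config(
    grid_shape = c(14L, 14L, 14L), voxel_size = c(4, 4, 4),
    critical_center = c(5, 7, 7), critical_radii = c(3, 3, 3),
    blob_count_mean = 3, blob_radius_range = c(3, 5), ...)
}

# simulate one patient x condition detection curve by binomial sampling
simulate_curve <- function(steepness, ddt, trials_per_level,
                           delays = c(33, 100, 200, 300, 400, 500, 600)) {
  p <- 1 / (1 + exp(-steepness * (delays - ddt)))
  data.frame(delay_ms = delays,
             prob = rbinom(length(delays), trials_per_level, p) /
               trials_per_level)
}

table1_groups <- function() {
  tab <- vmti::table1_fixture()
  tab$group
}
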