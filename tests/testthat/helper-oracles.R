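# Independent oracles and small fixture builders used across the suite.

# Iteratively-refined grid search minimizing the total-squared-error
# objective E(slope, intercept) = 1/2 * sum((slope*x + intercept - y)^2).
# Deliberately independent of the closed-form estimator it checks: it
# only ever evaluates the objective. For each candidate slope the
# intercept is profiled out by the 1-D optimality condition
# dE/db = 0  =>  b = mean(y - s*x); the slope grid is then refined on
# the (convex) profiled objective, which is robust even when the
# (slope, intercept) valley is extremely elongated, as it is for
# abundance-scale x.
grid_search_ols <- function(x, y, span = 100, grid_pts = 41L, iters = 40L) {
  profile_obj <- function(s) {
    b <- vapply(s, function(si) mean(y - si * x), numeric(1))
    e <- vapply(seq_along(s),
                function(i) 0.5 * sum((s[i] * x + b[i] - y)^2),
                numeric(1))
    list(b = b, e = e)
  }
  s_lo <- -span; s_hi <- span
  best_s <- 0; best_b <- 0
  for (it in seq_len(iters)) {
    ss <- seq(s_lo, s_hi, length.out = grid_pts)
    pr <- profile_obj(ss)
    k <- which.min(pr$e)
    best_s <- ss[k]; best_b <- pr$b[k]
    step <- ss[2L] - ss[1L]
    s_lo <- best_s - 2 * step; s_hi <- best_s + 2 * step
    if (step < 1e-12) break
  }
  list(slope = best_s, intercept = best_b)
}

# The objective the estimator minimizes, for optimality perturbation checks.
sse_objective <- function(x, y, slope, intercept) {
  0.5 * sum((slope * x + intercept - y)^2)
}

# Tiny profile matrix builder.
profile_mat <- function(values, sample_ids, function_ids) {
  matrix(values, nrow = length(sample_ids), byrow = TRUE,
         dimnames = list(sample_ids, function_ids))
}

# Wrap two aligned matrices as the paired container.
as_pairs <- function(wgs, amplicon) {
  structure(list(wgs = wgs, amplicon = amplicon,
                 sample_ids = rownames(wgs)),
            class = "paired_profiles")
}

# Disease-status study conditions used by classification scenarios:
# two subtly different groups (same habitat), tight clusters, strong
# per-function distortion.
disease_config <- function(seed) {
  generator_config(n_functions = 300,
                   groups = list(healthy = 9, gingivitis = 9),
                   concentration = 2e4, group_mean_concentration = 1e5,
                   slope_range = c(0.2, 5), noise_sd = 2e-4, seed = seed)
}
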