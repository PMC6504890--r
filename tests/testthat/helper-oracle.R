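# Independent oracles used across tests. These never call the package's
# simulation path.

# Closed-form P(nonresolved at each grid point) for the r2-free question
# (the nonresolved occupancy does not depend on tau2 or r2): integrate the
# exponential licensing-1 density over the grid intervals. Conditional on
# licensing falling in (t_{j-1}, t_j], transition draws happen at steps
# j, j+1, ..., so the cell is still nonresolved at step k with probability
# (1 - p1)^max(0, k - j) (effect-at-next-step convention).
analytic_nonresolved <- function(tau1, r1, grid) {
  p1 <- 1 - exp(-r1 * grid$dt)
  k0 <- which(grid$times == 0)
  w <- c(exp(grid$times[1] / tau1), diff(exp(grid$times[1:k0] / tau1)))
  vapply(seq_len(grid$n),
         function(k) sum(w * (1 - p1)^pmax(0, k - seq_len(k0))),
         numeric(1))
}

# Full three-state semi-analytic proportions by numerical integration over
# the joint licensing density (quantile midpoints) combined with the exact
# per-step probability recursion conditional on the licensing times.
analytic_proportions <- function(params, grid, n_quad = 150) {
  p1 <- 1 - exp(-params$r1 * grid$dt)
  p2 <- 1 - exp(-params$r2 * grid$dt)
  q <- (seq_len(n_quad) - 0.5) / n_quad
  x1 <- qexp(q, 1 / params$tau1)
  x2 <- qexp(q, 1 / params$tau2)
  gg <- expand.grid(t1 = -x1, d2 = x2)
  t1 <- gg$t1
  t2 <- gg$t1 + gg$d2
  nn <- rep(1, nrow(gg))  # P(nonresolved), per licensing combination
  rr <- numeric(nrow(gg))
  cc <- numeric(nrow(gg))
  out <- matrix(0, grid$n, 3)
  for (k in seq_len(grid$n)) {
    out[k, ] <- c(mean(nn), mean(rr), mean(cc))
    e1 <- grid$times[k] >= t1
    e2 <- grid$times[k] >= t2
    res_gain <- nn * p1 * e1
    comp_gain <- rr * p2 * e2
    nn <- nn - res_gain
    rr <- rr + res_gain - comp_gain
    cc <- cc + comp_gain
  }
  data.frame(time_min = grid$times, p_nonresolved = out[, 1],
             p_resolved = out[, 2], p_compacted = out[, 3])
}

# Pearson chi-square statistic from the definition, sum over cells of
# (observed - expected)^2 / expected
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_tab)^2 / exp_tab)
}

# default WT-like generating parameters used in pipeline tests
wt_params <- function() model_params(18.0, 9.3, 0.065, 0.12)

# run generator -> classifier -> model-state proportions
synth_observed <- function(params = wt_params(), seed = 1, ...) {
  cfg <- synth_config(params = params, ...)
  tr <- generate_truth(cfg, seed)
  coords <- render_coordinates(tr, seed + 1)
  states <- classify_cells(coords, tr$meta, cfg$classifier)
  to_model_proportions(proportions_over_time(states))
}
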