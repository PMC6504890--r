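#' Draw licensing times for one cell
#'
#' Licensing times are drawn from exponential distributions by inverse-CDF on
#' a uniform stream: the first licensing event (permitting the
#' nonresolved -> resolved transition) occurs at `t_lic1 = 0 - X1` with
#' `X1 ~ Exp(mean tau1)`, i.e. at or before NEBD; the second (permitting
#' resolved -> compacted) at `t_lic2 = t_lic1 + X2` with `X2 ~ Exp(mean tau2)`.
#'
#' @param params a [model_params()] object
#' @param u optional length-2 vector of uniforms in (0, 1); when `NULL`, two
#'   values are taken from the current RNG stream. Supplying `u` makes
#'   single-cell runs fully deterministic.
#' @return list with `t_lic1` (<= 0) and `t_lic2` (>= `t_lic1`), minutes.
#' @examples
#' set.seed(1)
#' draw_licensing_times(model_params(18, 9.3, 0.065, 0.12))
#' @export
draw_licensing_times <- function(params, u = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(u)) u <- runif(2)
  stopifnot(length(u) == 2, all(u > 0 & u < 1))
  t1 <- 0 - qexp(u[1], rate = 1 / params$tau1)
  t2 <- t1 + qexp(u[2], rate = 1 / params$tau2)
  list(t_lic1 = t1, t_lic2 = t2)
}

#' Simulate one cell's state sequence
#'
#' Reference (pure R) implementation of the per-cell rules. The cell is
#' nonresolved while `t_k < t_lic1`; from the first grid point at or after
#' `t_lic1`, a uniform draw is compared at every step with
#' `p1 = 1 - exp(-r1 * dt)` and a success moves the cell to the resolved
#' state. Once resolved and at or past `t_lic2`, fresh uniforms are compared
#' with `p2 = 1 - exp(-r2 * dt)`; a success moves the cell to the absorbing
#' compacted state. If licensing 2 precedes the resolution transition,
#' compaction still cannot occur until after resolution. With
#' `effect = "next"` (default) a successful draw at step k takes effect from
#' step k+1; with `effect = "current"` it takes effect at k itself. One
#' uniform is consumed per step regardless of eligibility, so the draw
#' layout does not depend on the parameters.
#'
#' @param params a [model_params()] object
#' @param grid a [time_grid()]
#' @param effect when a successful transition draw takes effect
#' @param licensing optional list with `t_lic1`, `t_lic2` to stub the
#'   licensing times; drawn via [draw_licensing_times()] when `NULL`
#' @param u_steps optional vector of `grid$n` uniforms for the per-step
#'   draws; taken from the RNG when `NULL`
#' @return factor vector of length `grid$n` with levels
#'   `nonresolved`, `resolved`, `compacted`; licensing times attached as
#'   attribute `licensing`.
#' @examples
#' set.seed(1)
#' s <- simulate_cell(model_params(18, 9.3, 0.065, 0.12), time_grid())
#' table(s)
#' @export
simulate_cell <- function(params, grid, effect = c("next", "current"),
                          licensing = NULL, u_steps = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "time_grid"))
  effect <- match.arg(effect)
  if (is.null(licensing)) licensing <- draw_licensing_times(params)
  if (is.null(u_steps)) u_steps <- runif(grid$n)
  stopifnot(length(u_steps) == grid$n)
  p1 <- -expm1(-params$r1 * grid$dt)
  p2 <- -expm1(-params$r2 * grid$dt)
  tt <- grid$times
  states <- integer(grid$n)
  state <- 1L
  for (k in seq_len(grid$n)) {
    nxt <- state
    if (state == 1L && tt[k] >= licensing$t_lic1 && u_steps[k] < p1) {
      nxt <- 2L
    } else if (state == 2L && tt[k] >= licensing$t_lic2 && u_steps[k] < p2) {
      nxt <- 3L
    }
    if (effect == "next") {
      states[k] <- state
      state <- nxt
    } else {
      state <- nxt
      states[k] <- state
    }
  }
  out <- factor(model_state_levels()[states], levels = model_state_levels())
  attr(out, "licensing") <- licensing
  out
}

model_state_levels <- function() c("nonresolved", "resolved", "compacted")

#' Pre-generate the uniform draws for a population simulation
#'
#' One root seed produces all randomness in a fixed layout: two licensing
#' uniforms per cell plus an n-by-m matrix of per-step uniforms. Reusing the
#' same draws across objective evaluations (common random numbers) makes the
#' fitting surface deterministic.
#'
#' @param m number of cells
#' @param n number of grid points
#' @param seed integer seed
#' @return list with `u_lic1`, `u_lic2` (length m) and `U` (n x m matrix)
#' @export
sim_draws <- function(m, n, seed) {
  stopifnot(m >= 1, n >= 1)
  set.seed(seed)
  list(
    u_lic1 = runif(m),
    u_lic2 = runif(m),
    U = matrix(runif(as.double(n) * m), nrow = n, ncol = m),
    seed = seed
  )
}

# Population state proportions given pre-generated draws (CRN path used by
# the fitter). Returns data.frame time_min, p_nonresolved, p_resolved,
# p_compacted.
sim_proportions <- function(params, grid, draws, effect = c("next", "current")) {
  effect <- match.arg(effect)
  m <- length(draws$u_lic1)
  t1 <- 0 - qexp(draws$u_lic1, rate = 1 / params$tau1)
  t2 <- t1 + qexp(draws$u_lic2, rate = 1 / params$tau2)
  p1 <- -expm1(-params$r1 * grid$dt)
  p2 <- -expm1(-params$r2 * grid$dt)
  counts <- cpp_state_counts(grid$times, t1, t2, draws$U, p1, p2,
                             effect == "next")
  data.frame(
    time_min = grid$times,
    p_nonresolved = counts[, 1] / m,
    p_resolved = counts[, 2] / m,
    p_compacted = counts[, 3] / m
  )
}

#' Simulate population state proportions
#'
#' Simulates `m` independent cells under the licensing/transition model and
#' returns the proportion of cells in each state at every grid time point.
#'
#' @inheritParams simulate_cell
#' @param m number of cells (default 10,000)
#' @param seed integer root seed; identical seed and parameters give
#'   bit-identical output
#' @return data.frame of class `population_proportions` with columns
#'   `time_min`, `p_nonresolved`, `p_resolved`, `p_compacted`, plus
#'   attributes `m`, `seed`, `params`.
#' @examples
#' pp <- simulate_population(model_params(18, 9.3, 0.065, 0.12),
#'                           time_grid(), m = 1000, seed = 1)
#' head(pp)
#' @export
simulate_population <- function(params, grid = time_grid(), m = 10000,
                                seed = 1, effect = c("next", "current")) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "time_grid"))
  if (m < 1) stop("m must be >= 1")
  effect <- match.arg(effect)
  draws <- sim_draws(m, grid$n, seed)
  out <- sim_proportions(params, grid, draws, effect)
  attr(out, "m") <- m
  attr(out, "seed") <- seed
  attr(out, "params") <- params
  class(out) <- c("population_proportions", class(out))
  out
}
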