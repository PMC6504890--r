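#' Time grid relative to NEBD
#'
#' Discrete time grid on which cell-state sequences are simulated. Times are
#' in minutes relative to nuclear envelope breakdown (NEBD), which defines
#' t = 0. The default grid runs from -140 to 90 min at 1-min steps (231
#' points), matching the span of NEBD-aligned live-imaging time courses.
#'
#' @param t_start first grid time (min, relative to NEBD; must be < 0)
#' @param t_end last grid time (min; must be > 0)
#' @param dt time step (min; > 0)
#' @return An object of class `time_grid`: list with `t_start`, `t_end`,
#'   `dt`, `times` (the grid points) and `n` (number of points).
#' @examples
#' g <- time_grid()
#' g$n  # 231
#' @export
time_grid <- function(t_start = -140, t_end = 90, dt = 1) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(dt),
            length(t_start) == 1, length(t_end) == 1, length(dt) == 1)
  if (dt <= 0) stop("dt must be positive")
  if (!(t_start < 0 && t_end > 0)) {
    stop("grid must straddle NEBD: t_start < 0 < t_end")
  }
  times <- seq(t_start, t_end, by = dt)
  structure(
    list(t_start = t_start, t_end = t_end, dt = dt,
         times = times, n = length(times)),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid: %g to %g min (dt = %g), n = %d points; t = 0 is NEBD\n",
              x$t_start, x$t_end, x$dt, x$n))
  invisible(x)
}

#' Model parameters
#'
#' The four parameters of the licensing/transition model: `tau1` and `tau2`
#' (minutes) are the exponential time scales of the two licensing events
#' (licensing for resolution, placed before NEBD, and licensing for
#' compaction, delayed after the first), and `r1`, `r2` (per minute) are the
#' constant rates at which the nonresolved -> resolved and
#' resolved -> compacted transitions occur once licensed.
#'
#' @param tau1,tau2 licensing time scales in minutes (> 0)
#' @param r1,r2 transition rates in min^-1 (>= 0)
#' @return Object of class `model_params`.
#' @examples
#' model_params(tau1 = 18.0, tau2 = 9.3, r1 = 0.065, r2 = 0.12)
#' @export
model_params <- function(tau1, tau2, r1, r2) {
  vals <- c(tau1 = tau1, tau2 = tau2, r1 = r1, r2 = r2)
  if (any(!is.finite(vals))) stop("model parameters must be finite")
  if (tau1 <= 0 || tau2 <= 0) stop("tau1 and tau2 must be strictly positive")
  if (r1 < 0 || r2 < 0) stop("r1 and r2 must be non-negative")
  structure(as.list(vals), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model parameters: tau1 = %g min, tau2 = %g min, r1 = %g /min, r2 = %g /min\n",
              x$tau1, x$tau2, x$r1, x$r2))
  invisible(x)
}

#' Derived quantities from model parameters
#'
#' Converts the model parameters to the quantities reported alongside fits:
#' `ST = tau1 * ln 2` (median licensing-for-resolution time before NEBD),
#' `TD = tau2 * ln 2` (median delay of licensing-for-compaction after the
#' first licensing), per-rate decay half-lives `ln 2 / r`, and per-step
#' transition probabilities `1 - exp(-r * dt)`.
#'
#' @param params a [model_params()] object
#' @param dt time step in minutes used for the per-step probabilities
#' @return list with `ST`, `TD` (min), `r1_half_life`, `r2_half_life` (min,
#'   `Inf` when the rate is 0) and `p1_step`, `p2_step` (dimensionless).
#' @examples
#' dq <- derived_quantities(model_params(18.0, 9.3, 0.065, 0.12))
#' round(dq$ST, 1)            # 12.5
#' round(dq$r1_half_life, 1)  # 10.7
#' round(dq$p1_step, 3)       # 0.063
#' @export
derived_quantities <- function(params, dt = 1) {
  stopifnot(inherits(params, "model_params"), dt > 0)
  half_life <- function(r) if (r > 0) log(2) / r else Inf
  list(
    ST = params$tau1 * log(2),
    TD = params$tau2 * log(2),
    r1_half_life = half_life(params$r1),
    r2_half_life = half_life(params$r2),
    p1_step = -expm1(-params$r1 * dt),
    p2_step = -expm1(-params$r2 * dt)
  )
}
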