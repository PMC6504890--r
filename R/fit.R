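#' Fit configuration
#'
#' Controls the least-squares fit of the licensing/transition model to an
#' observed state-proportion time course. The objective is evaluated on the
#' fitting window (default -50 to +30 min relative to NEBD) by simulating
#' `m_sim` cells with a fixed set of random draws (common random numbers,
#' `sim_seed`), which makes the stochastic objective a deterministic
#' function of the parameters. Parameters are optimised on the log scale,
#' which enforces positivity without constraints. `ndeps` is the
#' finite-difference step (log scale) handed to [stats::optim()]; it is
#' deliberately coarse because with finitely many simulated cells the
#' objective is piecewise constant on very small scales.
#'
#' @param window length-2 numeric, fitting window in minutes (default
#'   `c(-50, 30)`)
#' @param m_sim cells per objective evaluation (default 10,000)
#' @param optimizer method passed to [stats::optim()] (default `"BFGS"`)
#' @param init starting [model_params()]
#' @param sim_seed seed of the common-random-numbers draws
#' @param maxit maximum optimiser iterations
#' @param ndeps finite-difference step on the log-parameter scale
#' @param grid the model [time_grid()]
#' @param effect transition effect timing, see [simulate_cell()]
#' @param weight_by_cells weight each time point by its cell count
#'   (default `FALSE`: equal weights)
#' @param penalty large finite objective value returned for parameter
#'   values whose simulation fails to produce finite proportions
#' @return list of class `fit_config`
#' @export
fit_config <- function(window = c(-50, 30), m_sim = 10000,
                       optimizer = "BFGS",
                       init = model_params(10, 10, 0.1, 0.1),
                       sim_seed = 1234, maxit = 100, ndeps = 0.05,
                       grid = time_grid(), effect = "next",
                       weight_by_cells = FALSE, penalty = 1e6) {
  stopifnot(length(window) == 2, window[1] < window[2], m_sim >= 1,
            inherits(init, "model_params"), inherits(grid, "time_grid"))
  structure(list(window = window, m_sim = m_sim, optimizer = optimizer,
                 init = init, sim_seed = sim_seed, maxit = maxit,
                 ndeps = ndeps, grid = grid, effect = effect,
                 weight_by_cells = weight_by_cells, penalty = penalty),
            class = "fit_config")
}

in_window <- function(observed, config) {
  observed[observed$time_min >= config$window[1] &
             observed$time_min <= config$window[2], , drop = FALSE]
}

#' Sum-of-squares objective
#'
#' Simulates the model population (with the configuration's common random
#' numbers) and returns the sum, over observed in-window time points and
#' over the three model states, of squared differences between model and
#' observed proportions. Duplicated observed rows (as produced by bootstrap
#' resampling) contribute with their multiplicity; row order is irrelevant.
#' The observed table must already be on the model's three states (see
#' [to_model_proportions()]) and unsmoothed.
#'
#' @param params a [model_params()] object
#' @param observed data.frame with `time_min`, `p_nonresolved`,
#'   `p_resolved`, `p_compacted` (optionally `n_cells` for weighting)
#' @param config a [fit_config()]
#' @param draws pre-generated [sim_draws()]; generated from the config when
#'   `NULL`
#' @return non-negative scalar
#' @export
objective_ss <- function(params, observed, config = fit_config(),
                         draws = NULL) {
  obs <- in_window(observed, config)
  if (nrow(obs) == 0) stop("no observed time points inside the fit window")
  if (is.null(draws)) {
    draws <- sim_draws(config$m_sim, config$grid$n, config$sim_seed)
  }
  model <- sim_proportions(params, config$grid, draws, config$effect)
  idx <- match(obs$time_min, model$time_min)
  if (anyNA(idx)) stop("observed time points must lie on the model grid")
  dd <- (model$p_nonresolved[idx] - obs$p_nonresolved)^2 +
    (model$p_resolved[idx] - obs$p_resolved)^2 +
    (model$p_compacted[idx] - obs$p_compacted)^2
  if (config$weight_by_cells && !is.null(obs$n_cells)) {
    dd <- dd * obs$n_cells / mean(obs$n_cells)
  }
  ss <- sum(dd)
  if (!is.finite(ss)) return(config$penalty)
  ss
}

#' Fit the model to observed proportions
#'
#' Minimises [objective_ss()] over log-transformed `(tau1, tau2, r1, r2)`
#' with a quasi-Newton optimiser (BFGS by default). The common-random-numbers
#' seed makes the result deterministic given the configuration.
#'
#' @inheritParams objective_ss
#' @return list of class `fit_result`: `params` (best-fit
#'   [model_params()]), `objective`, `convergence` (0 = converged),
#'   `evaluations`, `derived` ([derived_quantities()] at the optimum) and
#'   the raw `optim` result.
#' @export
fit_model <- function(observed, config = fit_config(), draws = NULL) {
  obs <- in_window(observed, config)
  if (nrow(obs) == 0) stop("no observed time points inside the fit window")
  if (is.null(draws)) {
    draws <- sim_draws(config$m_sim, config$grid$n, config$sim_seed)
  }
  fn <- function(lp) {
    p <- exp(lp)
    if (any(!is.finite(p)) || any(p > 1e6)) return(config$penalty)
    objective_ss(model_params(p[1], p[2], p[3], p[4]), obs, config, draws)
  }
  lp0 <- log(unlist(config$init, use.names = FALSE))
  opt <- optim(lp0, fn, method = config$optimizer,
               control = list(maxit = config$maxit,
                              ndeps = rep(config$ndeps, 4)))
  p <- exp(opt$par)
  params <- model_params(p[1], p[2], p[3], p[4])
  structure(list(params = params, objective = opt$value,
                 convergence = opt$convergence,
                 evaluations = opt$counts[["function"]],
                 derived = derived_quantities(params, config$grid$dt),
                 optim = opt),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("model fit (sum of squares =", format(x$objective, digits = 4), ")\n")
  print(x$params)
  cat(sprintf("  ST = %.1f min, TD = %.1f min; convergence flag %d\n",
              x$derived$ST, x$derived$TD, x$convergence))
  invisible(x)
}

#' Bootstrap uncertainty of the fitted parameters
#'
#' Resamples the in-window observed time points with replacement (keeping
#' the original count; duplicates contribute with multiplicity), refits the
#' model to each resample, and summarises the `B` best-fit values per
#' parameter by their median (the central estimate) and box statistics.
#' Degenerate resamples in which every drawn row is the same time point are
#' skipped and counted. The same common-random-numbers draws are reused for
#' every refit.
#'
#' @inheritParams objective_ss
#' @param B number of bootstrap repetitions (default 300)
#' @param seed seed for the resampling
#' @param warm_start when `TRUE` (default), the model is first fitted to the
#'   full dataset and every resample fit starts from that optimum, which
#'   stabilises and speeds up the resample fits
#' @return list of class `bootstrap_result`: `samples` (B x 4 data.frame),
#'   `median` (named vector), `box` (per-parameter [box_stats()]),
#'   `full_fit` (when warm-started), `B`, `seed`, `n_skipped`.
#' @export
bootstrap_fit <- function(observed, config = fit_config(), B = 300,
                          seed = 1, warm_start = TRUE) {
  stopifnot(B >= 1)
  obs <- in_window(observed, config)
  if (nrow(obs) == 0) stop("no observed time points inside the fit window")
  draws <- sim_draws(config$m_sim, config$grid$n, config$sim_seed)
  full_fit <- NULL
  if (warm_start) {
    full_fit <- fit_model(obs, config, draws)
    config$init <- full_fit$params
  }
  set.seed(seed)
  resamples <- replicate(B, sample.int(nrow(obs), replace = TRUE),
                         simplify = FALSE)
  samples <- matrix(NA_real_, B, 4,
                    dimnames = list(NULL, c("tau1", "tau2", "r1", "r2")))
  n_skipped <- 0L
  for (b in seq_len(B)) {
    idx <- resamples[[b]]
    if (length(unique(obs$time_min[idx])) < 2) {
      n_skipped <- n_skipped + 1L
      message("bootstrap repetition ", b, " degenerate (one time point); skipped")
      next
    }
    ft <- fit_model(obs[idx, , drop = FALSE], config, draws)
    samples[b, ] <- unlist(ft$params, use.names = FALSE)
  }
  samples <- as.data.frame(samples)
  ok <- stats::complete.cases(samples)
  med <- vapply(samples[ok, , drop = FALSE], median, numeric(1))
  box <- lapply(samples[ok, , drop = FALSE], box_stats)
  structure(list(samples = samples, median = med, box = box,
                 full_fit = full_fit, B = B, seed = seed,
                 n_skipped = n_skipped),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap over %d repetitions (%d skipped)\n", x$B,
              x$n_skipped))
  cat("medians:\n")
  print(round(x$median, 4))
  invisible(x)
}

#' Box-plot statistics with 1.5 IQR whiskers
#'
#' Quartiles (type-7 linear interpolation), whiskers at the most extreme
#' data values within 1.5 interquartile ranges of the box, and the values
#' beyond the whiskers as outliers.
#'
#' @param values numeric vector (NAs dropped; at least one value required)
#' @return list: `q1`, `median`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`
#' @examples
#' box_stats(c(1, 2, 3, 4, 100))
#' @export
box_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("box_stats needs at least one value")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values[values >= lo & values <= hi]
  list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo | values > hi]),
       n = length(values))
}
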