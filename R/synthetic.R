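#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic microscopy-data generator. Each cell follows
#' the three-state licensing/transition model; while the model state is
#' still nonresolved and within `brown_window` minutes of NEBD, a two-state
#' telegraph process overlays transient brown ("partially resolved")
#' episodes, whose separated channel is tetO with probability `tetO_bias`.
#' Coordinates are rendered so that noiseless classification recovers the
#' generated states exactly: all generated distances keep explicit margins
#' from the classifier thresholds. Defaults emulate a wild-type cohort:
#' licensing scales 18.0 and 9.3 min, rates 0.065 and 0.12 per min (the
#' compaction rate is a chosen value, see the vignette), ~40 cells, brown
#' episodes of mean 2 min starting at 0.125 per min (stationary occupancy
#' 0.125*2/(1+0.125*2) = 20%) up to 120 min before NEBD, and 80% tetO bias.
#'
#' @param params generating [model_params()]
#' @param n_cells cohort size
#' @param grid observation/simulation [time_grid()]
#' @param classifier [classifier_config()] whose thresholds the geometry
#'   must respect
#' @param nebd_base,nebd_jitter absolute NEBD time is `nebd_base` plus a
#'   uniform integer jitter in `[-nebd_jitter, nebd_jitter]` minutes
#' @param g2_range length-2: uniform range of G2 duration (min), setting
#'   the end of S phase at `nebd - G2 length`
#' @param episode_rate telegraph brown-episode start rate (per min)
#' @param episode_mean_duration mean brown-episode duration (min)
#' @param brown_window telegraph active window before NEBD (min)
#' @param tetO_bias probability a brown episode separates tetO
#' @param sep_dist lognormal (meanlog, sdlog) of sister-separation
#'   distances, truncated to at least `sep_threshold + sep_margin`
#' @param sep_margin margin above the separation threshold (um)
#' @param coloc_dist lognormal (meanlog, sdlog) of colocalized tetO-lacO
#'   pair distances, truncated to at most `coloc_max` um
#' @param coloc_max upper bound of colocalized pair distances (um; must sit
#'   below `coloc_radius` with room for noise)
#' @param resolved_dist lognormal (meanlog, sdlog) of tetO-lacO distances
#'   on a resolved chromatid, truncated to at least `resolved_min`
#' @param resolved_min lower bound of resolved tetO-lacO distances (um)
#' @param d_blue tetO-lacO distance in the nonresolved state (um)
#' @param noise_sd isotropic Gaussian centroid noise per axis (um)
#' @param undetermined_rate fraction of time points dropped to undetermined
#' @return list of class `synth_config`
#' @export
synth_config <- function(params = model_params(18.0, 9.3, 0.065, 0.12),
                         n_cells = 40,
                         grid = time_grid(),
                         classifier = classifier_config(),
                         nebd_base = 600, nebd_jitter = 10,
                         g2_range = c(300, 420),
                         episode_rate = 0.125,
                         episode_mean_duration = 2,
                         brown_window = 120,
                         tetO_bias = 0.8,
                         sep_dist = c(meanlog = log(1.4), sdlog = 0.25),
                         sep_margin = 0.2,
                         coloc_dist = c(meanlog = log(0.1), sdlog = 0.4),
                         coloc_max = 0.15,
                         resolved_dist = c(meanlog = log(1.0), sdlog = 0.2),
                         resolved_min = 0.6,
                         d_blue = 0.25,
                         noise_sd = 0.05,
                         undetermined_rate = 0.1) {
  stopifnot(inherits(params, "model_params"), n_cells >= 1,
            inherits(grid, "time_grid"),
            inherits(classifier, "classifier_config"),
            episode_rate >= 0, episode_mean_duration > 0,
            brown_window >= 0,
            tetO_bias >= 0, tetO_bias <= 1,
            undetermined_rate >= 0, undetermined_rate <= 1,
            noise_sd >= 0)
  if (coloc_max >= classifier$coloc_radius) {
    stop("coloc_max must lie below the colocalization radius")
  }
  if (resolved_min <= classifier$coloc_radius) {
    stop("resolved_min must exceed the colocalization radius")
  }
  if (sep_margin <= 0) stop("sep_margin must be positive")
  structure(list(
    params = params, n_cells = n_cells, grid = grid,
    classifier = classifier, nebd_base = nebd_base,
    nebd_jitter = nebd_jitter, g2_range = g2_range,
    episode_rate = episode_rate,
    episode_mean_duration = episode_mean_duration,
    brown_window = brown_window, tetO_bias = tetO_bias,
    sep_dist = sep_dist, sep_margin = sep_margin,
    coloc_dist = coloc_dist, coloc_max = coloc_max,
    resolved_dist = resolved_dist, resolved_min = resolved_min,
    d_blue = d_blue, noise_sd = noise_sd,
    undetermined_rate = undetermined_rate
  ), class = "synth_config")
}

# truncated lognormal by inverse-CDF
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

# one cell's telegraph overlay evaluated at grid times: list(on, episode)
# continuous-time alternating process, stationary-initialised at window
# entry so per-time-point occupancy equals rate*dur/(1 + rate*dur)
telegraph_overlay <- function(times, t_on_from, rate, mean_dur) {
  n <- length(times)
  on <- logical(n)
  episode <- rep(NA_integer_, n)
  if (rate <= 0) return(list(on = on, episode = episode))
  occ <- rate * mean_dur / (1 + rate * mean_dur)
  t_end <- times[n]
  cur <- t_on_from
  state_on <- runif(1) < occ
  ep <- 0L
  while (cur <= t_end) {
    dur <- if (state_on) rexp(1, 1 / mean_dur) else rexp(1, rate)
    if (state_on) {
      ep <- ep + 1L
      idx <- which(times >= cur & times < cur + dur & times >= t_on_from)
      on[idx] <- TRUE
      episode[idx] <- ep
    }
    cur <- cur + dur
    state_on <- !state_on
  }
  list(on = on, episode = episode)
}

#' Generate ground-truth state sequences
#'
#' Simulates the three-state model for each cell, overlays telegraph brown
#' episodes (only while the model state is nonresolved and within the
#' configured pre-NEBD window), and assigns per-cell NEBD and end-of-S
#' times.
#'
#' @param config a [synth_config()]
#' @param seed integer seed
#' @return list of class `synthetic_truth` with `truth` (data.frame:
#'   `cell_id`, `t_rel_nebd_min`, `model_state`, `observable_state`,
#'   `separated_channel`) and `meta` (data.frame: `cell_id`, `nebd_min`,
#'   `end_of_s_min`, `t_lic1`, `t_lic2`), plus the `config` and `seed`.
#' @export
generate_truth <- function(config = synth_config(), seed = 1) {
  set.seed(seed)
  grid <- config$grid
  obs_map <- c(nonresolved = "blue", resolved = "pink", compacted = "red")
  cells <- vector("list", config$n_cells)
  meta <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    id <- sprintf("cell_%03d", i)
    st <- simulate_cell(config$params, grid)
    lic <- attr(st, "licensing")
    tg <- telegraph_overlay(grid$times, -config$brown_window,
                            config$episode_rate,
                            config$episode_mean_duration)
    observable <- unname(obs_map[as.character(st)])
    sep_ch <- rep(NA_character_, grid$n)
    brown <- tg$on & st == "nonresolved" & grid$times < 0
    if (any(brown)) {
      eps <- unique(tg$episode[brown])
      lab <- ifelse(runif(length(eps)) < config$tetO_bias, "tetO", "lacO")
      names(lab) <- as.character(eps)
      observable[brown] <- "brown"
      sep_ch[brown] <- lab[as.character(tg$episode[brown])]
    }
    nebd <- config$nebd_base +
      sample.int(2 * config$nebd_jitter + 1, 1) - config$nebd_jitter - 1
    g2 <- round(runif(1, config$g2_range[1], config$g2_range[2]))
    cells[[i]] <- data.frame(
      cell_id = id, t_rel_nebd_min = grid$times,
      model_state = as.character(st), observable_state = observable,
      separated_channel = sep_ch, stringsAsFactors = FALSE
    )
    meta[[i]] <- data.frame(
      cell_id = id, nebd_min = nebd, end_of_s_min = nebd - g2,
      t_lic1 = lic$t_lic1, t_lic2 = lic$t_lic2, stringsAsFactors = FALSE
    )
  }
  structure(list(truth = do.call(rbind, cells), meta = do.call(rbind, meta),
                 config = config, seed = seed),
            class = "synthetic_truth")
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# render the 1-4 dots of one time point given the observable state;
# returns data.frame(channel, dot_index, x, y, z)
render_timepoint <- function(state, sep_ch, config) {
  cl <- config$classifier
  centre <- runif(3, 0, 10)
  sep <- function() rlnorm_trunc(1, config$sep_dist["meanlog"],
                                 config$sep_dist["sdlog"],
                                 lower = cl$sep_threshold + config$sep_margin)
  dots <- switch(state,
    blue = {
      u <- rand_unit()
      rbind(c(1, centre), c(2, centre + u * config$d_blue))
    },
    brown = {
      u <- rand_unit(); v <- rand_unit()
      s <- sep()
      dbl <- rbind(centre - u * s / 2, centre + u * s / 2)
      sng <- centre + v * config$d_blue
      if (sep_ch == "tetO") {
        rbind(c(1, dbl[1, ]), c(1, dbl[2, ]), c(2, sng))
      } else {
        rbind(c(2, dbl[1, ]), c(2, dbl[2, ]), c(1, sng))
      }
    },
    pink = {
      u <- rand_unit(); w <- rand_unit()
      s <- sep()
      d <- rlnorm_trunc(1, config$resolved_dist["meanlog"],
                        config$resolved_dist["sdlog"],
                        lower = config$resolved_min)
      c1 <- centre; c2 <- centre + u * s
      rbind(c(1, c1), c(1, c2), c(2, c1 + w * d), c(2, c2 + w * d))
    },
    red = {
      u <- rand_unit(); w <- rand_unit()
      s <- sep()
      d <- rlnorm_trunc(2, config$coloc_dist["meanlog"],
                        config$coloc_dist["sdlog"],
                        upper = config$coloc_max)
      c1 <- centre; c2 <- centre + u * s
      rbind(c(1, c1), c(1, c2),
            c(2, c1 + w * d[1]), c(2, c2 + w * d[2]))
    },
    stop("unknown observable state: ", state)
  )
  ch <- c("tetO", "lacO")[dots[, 1]]
  data.frame(channel = ch,
             dot_index = stats::ave(seq_along(ch), ch, FUN = seq_along),
             x_um = dots[, 2], y_um = dots[, 3], z_um = dots[, 4],
             stringsAsFactors = FALSE)
}

#' Render noisy dot coordinates from ground truth
#'
#' Emits per-time-point centroids consistent with each cell's observable
#' state, adds isotropic Gaussian centroid noise, and removes one channel at
#' randomly chosen time points at the configured undetermined rate.
#' Coordinates are in um with the axial correction already applied (the
#' written `z_um` is the corrected coordinate).
#'
#' @param truth a [generate_truth()] result
#' @param seed integer seed
#' @return data.frame: `cell_id`, `t_min` (absolute minutes), `channel`,
#'   `dot_index`, `x_um`, `y_um`, `z_um`
#' @export
render_coordinates <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  config <- truth$config
  set.seed(seed)
  rows <- vector("list", nrow(truth$truth))
  nebd <- truth$meta$nebd_min[match(truth$truth$cell_id,
                                    truth$meta$cell_id)]
  for (j in seq_len(nrow(truth$truth))) {
    row <- truth$truth[j, ]
    if (runif(1) < config$undetermined_rate) {
      # drop one channel entirely at this time point
      keep_ch <- sample(c("tetO", "lacO"), 1)
      tp <- render_timepoint(row$observable_state, row$separated_channel,
                             config)
      tp <- tp[tp$channel == keep_ch, , drop = FALSE]
    } else {
      tp <- render_timepoint(row$observable_state, row$separated_channel,
                             config)
    }
    if (nrow(tp) == 0) next
    if (config$noise_sd > 0) {
      tp$x_um <- tp$x_um + stats::rnorm(nrow(tp), 0, config$noise_sd)
      tp$y_um <- tp$y_um + stats::rnorm(nrow(tp), 0, config$noise_sd)
      tp$z_um <- tp$z_um + stats::rnorm(nrow(tp), 0, config$noise_sd)
    }
    rows[[j]] <- cbind(cell_id = row$cell_id,
                       t_min = row$t_rel_nebd_min + nebd[j], tp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [generate_truth()] and [render_coordinates()] and writes
#' `coordinates.csv`, `cell_metadata.csv`, `truth.csv` and a
#' `provenance.json` recording the seed and generating parameters.
#'
#' @param config a [synth_config()]
#' @param dir output directory (created if needed)
#' @param seed integer root seed (truth uses `seed`, rendering `seed + 1`)
#' @return invisibly, a list with the three tables and the file paths
#' @export
generate_dataset <- function(config = synth_config(), dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(config, seed)
  coords <- render_coordinates(truth, seed + 1)
  paths <- file.path(dir, c("coordinates.csv", "cell_metadata.csv",
                            "truth.csv", "provenance.json"))
  write.csv(coords, paths[1], row.names = FALSE)
  write.csv(truth$meta, paths[2], row.names = FALSE)
  write.csv(truth$truth, paths[3], row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         params = unclass(config$params),
         n_cells = config$n_cells,
         tetO_bias = config$tetO_bias,
         episode_rate = config$episode_rate,
         episode_mean_duration = config$episode_mean_duration,
         brown_window = config$brown_window,
         noise_sd = config$noise_sd,
         undetermined_rate = config$undetermined_rate,
         package_version = as.character(utils::packageVersion("chromkin"))),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(list(coordinates = coords, meta = truth$meta,
                 truth = truth$truth, paths = paths))
}
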