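#' Classifier configuration
#'
#' Tunable parameters of the dot-configuration classifier. All distances are
#' in micrometres. `sep_threshold` is the sister-separation threshold (a
#' doublet with centre separation above it counts as separated);
#' `coloc_radius` is the centroid-distance proxy for ">50% colocalization"
#' of a tetO/lacO pair; `z_step` and `z_scale` define the effective axial
#' spacing (nominal z-section spacing times the refractive-index scaling
#' applied before any 3D distance is computed); `black_min_run` is the
#' minimum number of consecutive post-NEBD all-colocalized time points
#' required to call the black (nonresolved-and-compacted) state;
#' `smooth_window` is the default rolling-mean window in minutes.
#'
#' @param sep_threshold sister-separation threshold, um (default 0.85)
#' @param coloc_radius colocalization radius, um (default 0.4)
#' @param z_step nominal z-section spacing, um (default 0.75)
#' @param z_scale refractive-index scaling factor for z (default 0.85)
#' @param black_min_run minimum run length for the black state (default 5)
#' @param smooth_window rolling-mean window, min; must be odd (default 9)
#' @return list of class `classifier_config`
#' @export
classifier_config <- function(sep_threshold = 0.85, coloc_radius = 0.4,
                              z_step = 0.75, z_scale = 0.85,
                              black_min_run = 5, smooth_window = 9) {
  stopifnot(sep_threshold > 0, coloc_radius > 0, z_step > 0, z_scale > 0,
            black_min_run >= 1, smooth_window >= 1)
  if (smooth_window %% 2 != 1) stop("smooth_window must be odd")
  structure(list(sep_threshold = sep_threshold, coloc_radius = coloc_radius,
                 z_step = z_step, z_scale = z_scale,
                 black_min_run = black_min_run,
                 smooth_window = smooth_window),
            class = "classifier_config")
}

state_levels <- function() {
  c("blue", "brown", "pink", "red", "black", "undetermined")
}

#' Correct axial (z) coordinates for refractive-index mismatch
#'
#' Imaging through an oil objective into aqueous medium compresses apparent
#' axial distances; the effective spacing per z step is the nominal section
#' spacing multiplied by a scaling factor (defaults 0.75 um x 0.85 ~= 0.64
#' um). Applied before any 3D distance computation.
#'
#' @param z z-section indices (`units = "steps"`) or uncorrected axial
#'   distances in um (`units = "um"`)
#' @param config a [classifier_config()]
#' @param units how `z` is expressed
#' @return corrected axial position/distance in um
#' @examples
#' correct_z(1, classifier_config())        # 0.6375
#' correct_z(0.75, classifier_config(), "um")
#' @export
correct_z <- function(z, config = classifier_config(),
                      units = c("steps", "um")) {
  units <- match.arg(units)
  switch(units,
         steps = z * config$z_step * config$z_scale,
         um = z * config$z_scale)
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# channel summary: list(n, sep = doublet separation or NA)
channel_info <- function(xyz) {
  n <- nrow(xyz)
  sep <- if (n == 2) dist3(xyz[1, ], xyz[2, ]) else NA_real_
  list(n = n, sep = sep)
}

# a channel acts as a single object if it has one dot, or a doublet whose
# separation does not exceed the threshold (boundary value inclusive)
effectively_single <- function(info, thr) {
  info$n == 1 || (info$n == 2 && info$sep <= thr)
}

#' Classify the dot configuration at one time point
#'
#' Applies the rule set that converts the tetO and lacO centroids observed at
#' a single time point into a configuration state:
#' \itemize{
#'   \item either channel absent: `undetermined`;
#'   \item at least one channel effectively single (one object, or a doublet
#'     separated by at most `sep_threshold`): `blue`, unless the other
#'     channel is a doublet separated by more than the threshold, in which
#'     case `brown` labelled with the separated channel;
#'   \item both channels separated doublets: the tetO and lacO dots are
#'     paired by minimal total distance; `red` if both matched pairs lie
#'     within `coloc_radius` of each other, otherwise `pink`.
#' }
#' Coordinates must already be in um with the axial correction applied (see
#' [correct_z()]).
#'
#' @param tet,lac numeric matrices with 0-2 rows and columns x, y, z (um)
#' @param config a [classifier_config()]
#' @return list with `state` (character), `separated_channel`
#'   (`"tetO"`/`"lacO"` for brown, otherwise `NA`) and `black_eligible`
#'   (logical: both channels are doublets and all four dots are mutually
#'   within `coloc_radius`).
#' @examples
#' cfg <- classifier_config()
#' tet <- matrix(c(0, 0, 0), 1)
#' lac <- matrix(c(0.2, 0, 0, 1.4, 0, 0), 2, byrow = TRUE)
#' classify_timepoint(tet, lac, cfg)$state  # "brown"
#' @export
classify_timepoint <- function(tet, lac, config = classifier_config()) {
  tet <- as_xyz(tet); lac <- as_xyz(lac)
  if (nrow(tet) > 2 || nrow(lac) > 2) {
    stop("more than two centroids in one channel")
  }
  if (nrow(tet) == 0 || nrow(lac) == 0) {
    return(list(state = "undetermined", separated_channel = NA_character_,
                black_eligible = FALSE))
  }
  thr <- config$sep_threshold
  it <- channel_info(tet); il <- channel_info(lac)
  st <- effectively_single(it, thr); sl <- effectively_single(il, thr)
  black_eligible <- FALSE
  if (it$n == 2 && il$n == 2) {
    d <- outer(seq_len(2), seq_len(2),
               Vectorize(function(i, j) dist3(tet[i, ], lac[j, ])))
    black_eligible <- all(c(it$sep, il$sep, d) <= config$coloc_radius)
  }
  if (st && sl) {
    return(list(state = "blue", separated_channel = NA_character_,
                black_eligible = black_eligible))
  }
  if (st || sl) {
    ch <- if (!st) "tetO" else "lacO"
    return(list(state = "brown", separated_channel = ch,
                black_eligible = FALSE))
  }
  # both channels separated doublets: pair by minimal total distance
  d11 <- dist3(tet[1, ], lac[1, ]); d22 <- dist3(tet[2, ], lac[2, ])
  d12 <- dist3(tet[1, ], lac[2, ]); d21 <- dist3(tet[2, ], lac[1, ])
  pair <- if (d11 + d22 <= d12 + d21) c(d11, d22) else c(d12, d21)
  state <- if (all(pair <= config$coloc_radius)) "red" else "pink"
  list(state = state, separated_channel = NA_character_,
       black_eligible = black_eligible)
}

as_xyz <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), 0, 3))
  x <- as.matrix(x)
  if (length(x) == 0) return(matrix(numeric(0), 0, 3))
  if (ncol(x) != 3) stop("centroids must have columns x, y, z")
  if (any(!is.finite(x))) stop("centroid coordinates must be finite")
  x
}

#' Classify a single cell's dot time course
#'
#' Classifies every observed time point of one cell, re-indexes times
#' relative to NEBD, and applies the black-state rule: runs of at least
#' `black_min_run` consecutive post-NEBD time points in which both channels
#' are doublets and all four dots are mutually within the colocalization
#' radius are relabelled `black` (shorter runs keep their per-time-point
#' call). Time points at which either channel shows no centroid are
#' `undetermined`.
#'
#' @param coords data.frame for one cell: columns `t_min`, `channel`
#'   (`"tetO"`/`"lacO"`), `x_um`, `y_um`, `z_um` (z already corrected)
#' @param nebd_min NEBD time in the same absolute minutes as `t_min`
#' @param config a [classifier_config()]
#' @return data.frame: `t_rel_nebd_min`, `state`, `separated_channel`
#' @export
classify_series <- function(coords, nebd_min, config = classifier_config()) {
  if (is.null(nebd_min) || is.na(nebd_min)) stop("NEBD time is required")
  times <- sort(unique(coords$t_min))
  calls <- lapply(times, function(tm) {
    sub <- coords[coords$t_min == tm, , drop = FALSE]
    tet <- as.matrix(sub[sub$channel == "tetO", c("x_um", "y_um", "z_um")])
    lac <- as.matrix(sub[sub$channel == "lacO", c("x_um", "y_um", "z_um")])
    classify_timepoint(tet, lac, config)
  })
  out <- data.frame(
    t_rel_nebd_min = times - nebd_min,
    state = vapply(calls, `[[`, character(1), "state"),
    separated_channel = vapply(calls, `[[`, character(1),
                               "separated_channel"),
    stringsAsFactors = FALSE
  )
  eligible <- vapply(calls, `[[`, logical(1), "black_eligible")
  # black relabelling: consecutive (unit-spaced) eligible runs after NEBD
  post <- out$t_rel_nebd_min > 0
  consec <- c(TRUE, diff(out$t_rel_nebd_min) == 1)
  run_id <- cumsum(!(eligible & post) | !consec)
  for (id in unique(run_id[eligible & post])) {
    idx <- which(run_id == id & eligible & post)
    if (length(idx) >= config$black_min_run) {
      out$state[idx] <- "black"
      out$separated_channel[idx] <- NA_character_
    }
  }
  out
}

#' Classify a cohort of cells
#'
#' Applies [classify_series()] to every cell in a tidy coordinate table.
#'
#' @param coords data.frame: `cell_id`, `t_min`, `channel`, `x_um`, `y_um`,
#'   `z_um`
#' @param meta data.frame: `cell_id`, `nebd_min` (and optionally
#'   `end_of_s_min`, carried through untouched by this function)
#' @param config a [classifier_config()]
#' @return data.frame: `cell_id`, `t_rel_nebd_min`, `state`,
#'   `separated_channel`
#' @export
classify_cells <- function(coords, meta, config = classifier_config()) {
  stopifnot(all(c("cell_id", "t_min", "channel", "x_um", "y_um", "z_um")
                %in% names(coords)),
            all(c("cell_id", "nebd_min") %in% names(meta)))
  res <- lapply(unique(coords$cell_id), function(id) {
    nebd <- meta$nebd_min[match(id, meta$cell_id)]
    if (is.na(nebd)) stop("no NEBD time for cell ", id)
    sub <- coords[coords$cell_id == id, , drop = FALSE]
    cbind(cell_id = id, classify_series(sub, nebd, config))
  })
  do.call(rbind, res)
}
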