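#' Per-time-point state counts and proportions
#'
#' Tallies classified states across cells at every time point relative to
#' NEBD. `undetermined` time points never enter the denominator: proportions
#' are over classified cells only. The per-time-point classified count is
#' reported so callers can apply a display mask (the convention is to grey
#' out time points with fewer than 10 cells, never to drop them).
#'
#' @param states data.frame as returned by [classify_cells()]
#' @return data.frame with `time_min`, one `n_<state>` count column per
#'   state (blue, brown, pink, red, black, undetermined), `n_classified`,
#'   and proportions `p_blue` ... `p_black` over classified cells.
#' @export
proportions_over_time <- function(states) {
  if (nrow(states) == 0) stop("no state calls supplied")
  lv <- state_levels()
  tt <- sort(unique(states$t_rel_nebd_min))
  counts <- t(vapply(tt, function(tm) {
    s <- states$state[states$t_rel_nebd_min == tm]
    vapply(lv, function(l) sum(s == l), integer(1))
  }, integer(length(lv))))
  colnames(counts) <- paste0("n_", lv)
  classified <- rowSums(counts[, paste0("n_", setdiff(lv, "undetermined")),
                               drop = FALSE])
  props <- counts[, paste0("n_", setdiff(lv, "undetermined")), drop = FALSE] /
    ifelse(classified > 0, classified, NA_real_)
  colnames(props) <- paste0("p_", setdiff(lv, "undetermined"))
  out <- data.frame(time_min = tt, counts, n_classified = classified, props)
  rownames(out) <- NULL
  out
}

#' Centered rolling-mean smoothing
#'
#' Smooths a numeric vector, or every proportion column (`p_*`) of a
#' proportion table, with a centered rolling mean over an odd window. Edges
#' use the available points (shrinking window). For a table the raw columns
#' are retained and `<col>_smooth` columns are added.
#'
#' @param x numeric vector or data.frame with `p_*` columns
#' @param window window width in time points (odd, >= 1)
#' @return smoothed vector, or the data.frame with added smoothed columns
#' @examples
#' rolling_mean_smooth(c(0, 0, 1, 0, 0), 3)
#' @export
rolling_mean_smooth <- function(x, window = 9) {
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  if (is.data.frame(x)) {
    pcols <- grep("^p_", names(x), value = TRUE)
    pcols <- pcols[!grepl("_smooth$", pcols)]
    for (cl in pcols) {
      x[[paste0(cl, "_smooth")]] <- rolling_mean_smooth(x[[cl]], window)
    }
    return(x)
  }
  if (window == 1) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = window, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Cell-cycle phase of a time point
#'
#' Assigns the standard phase windows used for per-phase summaries, all in
#' minutes: prophase is the 20-min window before NEBD; late G2 the 120 min
#' before that; early G2 the first 90 min after the end of S phase; late S
#' the last 30 min of S phase. Windows are half-open `[start, end)`;
#' when short G2 phases make windows overlap, the later-phase label wins
#' (prophase > late G2 > early G2 > late S).
#'
#' @param t time point(s), absolute minutes
#' @param nebd_min NEBD time, absolute minutes
#' @param end_of_s_min end of S phase, absolute minutes (must precede NEBD)
#' @return character vector: `"late_S"`, `"early_G2"`, `"late_G2"`,
#'   `"prophase"` or `"other"`
#' @examples
#' assign_phase(c(-10, -30) + 600, nebd_min = 600, end_of_s_min = 240)
#' @export
assign_phase <- function(t, nebd_min, end_of_s_min) {
  if (end_of_s_min >= nebd_min) stop("end of S phase must precede NEBD")
  out <- rep("other", length(t))
  out[t >= end_of_s_min - 30 & t < end_of_s_min] <- "late_S"
  out[t >= end_of_s_min & t < end_of_s_min + 90] <- "early_G2"
  out[t >= nebd_min - 140 & t < nebd_min - 20] <- "late_G2"
  out[t >= nebd_min - 20 & t < nebd_min] <- "prophase"
  out
}

#' Chi-square comparison of per-phase state counts
#'
#' Pearson chi-square test (no continuity correction) on a contingency table
#' of time-point counts, conditions in rows and states (or state groups) in
#' columns, as used to compare state occupancy between conditions within a
#' cell-cycle phase.
#'
#' @param counts matrix or table of non-negative counts
#' @return `htest` object from [stats::chisq.test()]
#' @export
phase_compare <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin")
  }
  chisq.test(counts, correct = FALSE)
}

#' tetO/lacO separation asymmetry among partially resolved calls
#'
#' Among brown ("partially resolved") time points, the fraction whose
#' separated channel is tetO versus lacO. The two fractions sum to 1;
#' `n_brown` is the number of brown calls used.
#'
#' @param states data.frame with `state` and `separated_channel` columns
#'   (pre-filter to a phase of interest if required)
#' @return list with `frac_tetO`, `frac_lacO`, `n_brown`; fractions are
#'   `NA` when there are no brown calls.
#' @export
separation_asymmetry <- function(states) {
  ch <- states$separated_channel[states$state == "brown"]
  n <- length(ch)
  if (n == 0) {
    return(list(frac_tetO = NA_real_, frac_lacO = NA_real_, n_brown = 0L))
  }
  ft <- mean(ch == "tetO")
  list(frac_tetO = ft, frac_lacO = 1 - ft, n_brown = n)
}

#' Collapse observed proportions onto the three model states
#'
#' The fitted model has three states; observed brown ("partially resolved")
#' calls count as nonresolved, pink as resolved, red as compacted. Black
#' ("nonresolved and compacted") calls have no model counterpart and are by
#' default excluded from the denominator; `black = "nonresolved"` maps them
#' to nonresolved instead. Undetermined calls are always excluded.
#'
#' @param props output of [proportions_over_time()]
#' @param black how to treat black calls
#' @return data.frame: `time_min`, `p_nonresolved`, `p_resolved`,
#'   `p_compacted`, `n_cells` (the per-time-point denominator)
#' @export
to_model_proportions <- function(props, black = c("drop", "nonresolved")) {
  black <- match.arg(black)
  n_black <- props$n_black
  denom <- props$n_blue + props$n_brown + props$n_pink + props$n_red +
    if (black == "nonresolved") n_black else 0
  nonres <- props$n_blue + props$n_brown +
    if (black == "nonresolved") n_black else 0
  keep <- denom > 0
  data.frame(
    time_min = props$time_min[keep],
    p_nonresolved = nonres[keep] / denom[keep],
    p_resolved = props$n_pink[keep] / denom[keep],
    p_compacted = props$n_red[keep] / denom[keep],
    n_cells = denom[keep]
  )
}
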