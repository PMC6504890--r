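cfg <- classifier_config()

pt <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)

test_that("z correction multiplies the nominal step by the scaling factor", {
  expect_equal(correct_z(1, cfg), 0.6375)
  expect_equal(round(correct_z(1, cfg), 2), 0.64)
  expect_equal(correct_z(2, cfg), 1.275)
  expect_equal(correct_z(1.3, classifier_config(z_scale = 1)), 0.975)
  expect_equal(correct_z(0.9, cfg, units = "um"), 0.9 * 0.85)
})

test_that("time-point rules map dot configurations to states", {
  # one dot per channel: nonresolved
  r <- classify_timepoint(pt(0, 0, 0), pt(0.2, 0, 0), cfg)
  expect_equal(r$state, "blue")
  expect_true(is.na(r$separated_channel))

  # single tetO, lacO doublet separated beyond threshold: partially resolved
  r <- classify_timepoint(pt(0, 0, 0), pt(0, 0, 0, 1.2, 0, 0), cfg)
  expect_equal(r$state, "brown")
  expect_equal(r$separated_channel, "lacO")
  r <- classify_timepoint(pt(0, 0, 0, 0, 1.0, 0), pt(0.2, 0, 0), cfg)
  expect_equal(r$state, "brown")
  expect_equal(r$separated_channel, "tetO")

  # doublet at exactly the threshold counts as not separated
  r <- classify_timepoint(pt(0, 0, 0), pt(0, 0, 0, 0.85, 0, 0), cfg)
  expect_equal(r$state, "blue")

  # sub-threshold doublet in one channel behaves as a single object
  r <- classify_timepoint(pt(0, 0, 0, 0.3, 0, 0), pt(0, 0, 0, 1.2, 0, 0),
                          cfg)
  expect_equal(r$state, "brown")
  expect_equal(r$separated_channel, "lacO")

  # both channels separated: resolved vs compacted by pair colocalization
  tet <- pt(0, 0, 0, 2.0, 0, 0)
  lac_close <- pt(0.1, 0, 0, 2.1, 0, 0)     # both pairs within 0.4
  lac_far <- pt(1.0, 0, 0, 3.0, 0, 0)       # pairs at 1.0
  expect_equal(classify_timepoint(tet, lac_close, cfg)$state, "red")
  expect_equal(classify_timepoint(tet, lac_far, cfg)$state, "pink")
  # one pair colocalized, the other not: still resolved
  lac_mixed <- pt(0.1, 0, 0, 3.0, 0, 0)
  expect_equal(classify_timepoint(tet, lac_mixed, cfg)$state, "pink")

  # missing channel: undetermined; >2 dots: error
  expect_equal(classify_timepoint(pt(0, 0, 0), NULL, cfg)$state,
               "undetermined")
  expect_error(classify_timepoint(pt(0, 0, 0, 1, 0, 0, 2, 0, 0),
                                  pt(0, 0, 0), cfg),
               "more than two")
})

test_that("classification is invariant to dot order and rigid translation", {
  set.seed(11)
  for (i in 1:30) {
    tet <- matrix(runif(6, 0, 3), 2, 3)
    lac <- matrix(runif(6, 0, 3), 2, 3)
    base <- classify_timepoint(tet, lac, cfg)
    swapped <- classify_timepoint(tet[2:1, ], lac[2:1, ], cfg)
    expect_equal(swapped$state, base$state)
    expect_equal(swapped$separated_channel, base$separated_channel)
    shift <- matrix(rep(runif(3, -50, 50), each = 2), 2, 3)
    moved <- classify_timepoint(tet + shift, lac + shift, cfg)
    expect_equal(moved$state, base$state)
  }
})

# build a coordinate table for one cell from a list of per-time-point
# (tet, lac) matrices
coords_from <- function(frames, t0 = 0) {
  rows <- list()
  for (i in seq_along(frames)) {
    for (ch in c("tetO", "lacO")) {
      m <- frames[[i]][[ch]]
      if (is.null(m) || nrow(m) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        t_min = t0 + i - 1, channel = ch,
        dot_index = seq_len(nrow(m)),
        x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
    }
  }
  do.call(rbind, rows)
}

all_coloc <- list(tetO = pt(0, 0, 0, 0.1, 0, 0),
                  lacO = pt(0, 0.1, 0, 0.1, 0.1, 0))
blue_fr <- list(tetO = pt(0, 0, 0), lacO = pt(0.2, 0, 0))

test_that("black state needs >= 5 consecutive all-colocalized points after NEBD", {
  # NEBD at t = 100; frames from t = 98
  frames5 <- c(rep(list(blue_fr), 3), rep(list(all_coloc), 5),
               list(blue_fr))
  co <- coords_from(frames5, t0 = 98)
  st <- classify_series(co, nebd_min = 100, cfg)
  expect_equal(st$state[st$t_rel_nebd_min %in% 1:5], rep("black", 5))
  expect_equal(st$state[st$t_rel_nebd_min == 0], "blue")

  # only 4 consecutive: keep the raw per-time-point call
  frames4 <- c(rep(list(blue_fr), 3), rep(list(all_coloc), 4),
               rep(list(blue_fr), 2))
  st4 <- classify_series(coords_from(frames4, t0 = 98), 100, cfg)
  expect_false(any(st4$state == "black"))

  # run straddling NEBD: only the post-NEBD part is eligible
  frames_straddle <- c(rep(list(all_coloc), 7), rep(list(blue_fr), 2))
  st_s <- classify_series(coords_from(frames_straddle, t0 = 97), 100, cfg)
  # post-NEBD portion is 3 points (t_rel 1..3): too short for black
  expect_false(any(st_s$state == "black"))

  # an all-blue series is returned unchanged
  st_b <- classify_series(coords_from(rep(list(blue_fr), 6), t0 = 98),
                          100, cfg)
  expect_true(all(st_b$state == "blue"))

  expect_error(classify_series(co, NA), "NEBD")
})

test_that("proportions exclude undetermined calls from the denominator", {
  states <- data.frame(
    cell_id = rep(c("a", "b", "c", "d"), each = 2),
    t_rel_nebd_min = rep(c(0, 1), 4),
    state = c("blue", "blue", "blue", "pink",
              "blue", "pink", "undetermined", "red"),
    separated_channel = NA_character_)
  pr <- proportions_over_time(states)
  expect_equal(pr$n_classified, c(3, 4))
  expect_equal(pr$p_blue, c(1, 1 / 4))
  expect_equal(pr$p_pink, c(0, 2 / 4))
  expect_equal(pr$p_red, c(0, 1 / 4))
  # proportions over classified states always sum to 1
  expect_equal(pr$p_blue + pr$p_brown + pr$p_pink + pr$p_red + pr$p_black,
               c(1, 1))
})

test_that("rolling mean smoothing shrinks at edges and preserves totals", {
  expect_equal(rolling_mean_smooth(c(0, 0, 1, 0, 0), 3),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  expect_equal(rolling_mean_smooth(rep(0.4, 8), 5), rep(0.4, 8))
  x <- runif(10)
  expect_equal(rolling_mean_smooth(x, 1), x)
  expect_error(rolling_mean_smooth(x, 4), "odd")
  # smoothing a proportion table preserves the per-time-point sum of 1
  df <- data.frame(time_min = 1:9,
                   p_a = seq(0, 0.8, 0.1))
  df$p_b <- 1 - df$p_a
  sm <- rolling_mean_smooth(df, 3)
  expect_equal(sm$p_a_smooth + sm$p_b_smooth, rep(1, 9))
  expect_equal(sm$p_a, df$p_a)  # raw retained
})

test_that("phase windows follow the live-imaging definitions", {
  nebd <- 600; end_s <- 240
  expect_equal(assign_phase(nebd - 10, nebd, end_s), "prophase")
  expect_equal(assign_phase(nebd - 20, nebd, end_s), "prophase")
  expect_equal(assign_phase(nebd - 21, nebd, end_s), "late_G2")
  expect_equal(assign_phase(nebd - 30, nebd, end_s), "late_G2")
  expect_equal(assign_phase(nebd - 140, nebd, end_s), "late_G2")
  expect_equal(assign_phase(end_s - 10, nebd, end_s), "late_S")
  expect_equal(assign_phase(end_s + 10, nebd, end_s), "early_G2")
  expect_equal(assign_phase(end_s + 200, nebd, end_s), "other")
  expect_error(assign_phase(0, 100, 100), "precede")
})

test_that("chi-square comparison matches the closed-form Pearson statistic", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- phase_compare(even)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)

  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  r2 <- phase_compare(tab)
  expect_equal(unname(r2$statistic), pearson_chisq(tab))
  expect_equal(unname(r2$parameter), 1)
  expect_error(phase_compare(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("separation asymmetry summarises brown calls per channel", {
  states <- data.frame(
    state = c("brown", "brown", "brown", "blue", "pink"),
    separated_channel = c("tetO", "tetO", "lacO", NA, NA))
  a <- separation_asymmetry(states)
  expect_equal(a$frac_tetO, 2 / 3)
  expect_equal(a$frac_lacO, 1 / 3)
  expect_equal(a$n_brown, 3L)
  empty <- separation_asymmetry(data.frame(state = "blue",
                                           separated_channel = NA))
  expect_equal(empty$n_brown, 0L)
  expect_true(is.na(empty$frac_tetO))
})

test_that("black calls can be dropped or remapped for model fitting", {
  states <- data.frame(
    cell_id = rep("a", 4), t_rel_nebd_min = rep(5, 4),
    state = c("blue", "pink", "red", "black"),
    separated_channel = NA_character_)
  # fake four cells at one time point
  states$cell_id <- letters[1:4]
  pr <- proportions_over_time(states)
  dropped <- to_model_proportions(pr)
  expect_equal(dropped$n_cells, 3)
  expect_equal(dropped$p_nonresolved, 1 / 3)
  mapped <- to_model_proportions(pr, black = "nonresolved")
  expect_equal(mapped$n_cells, 4)
  expect_equal(mapped$p_nonresolved, 2 / 4)
  expect_equal(mapped$p_nonresolved + mapped$p_resolved + mapped$p_compacted,
               1)
})
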