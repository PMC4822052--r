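test_that("track filtering applies the lifetime and overlap rules", {
  mask <- matrix(FALSE, 40, 40)
  mask[20, 5:35] <- TRUE  # horizontal microtubule at y = 19 px
  px <- 100
  on_mt <- function(id, dur) {
    t <- seq(0, dur, length.out = 4)
    Trajectory(id, t, seq(500, 3000, length.out = 4), rep(19 * px, 4))
  }
  short <- on_mt("short", 0.3)
  long <- on_mt("long", 2)
  # one sample 5 px off the microtubule
  off <- Trajectory("off", c(0, 1, 2), c(500, 1500, 2500),
                    c(19 * px, (19 + 5) * px, 19 * px))
  tset <- TrajectorySet(list(short, long, off), 10, px)
  kept <- filter_tracks(tset, BinaryMask(mask), min_lifetime_s = 0.5,
                        overlap_tol_px = 1)
  expect_equal(vapply(kept$trajectories, `[[`, "", "track_id"), "long")
  expect_error(filter_tracks(tset, BinaryMask(matrix(FALSE, 4, 4))), "empty")

  # clean synthetic tracks with adequate lifetime all pass the spatial rule
  g <- gen_trajectories(mt_length_um = 20, duration_min = 2,
                        landing_rate_per_um_min = 1.5, loc_noise_nm = 0,
                        seed = 3)
  ok_life <- Filter(function(tr) lifetime(tr) >= 0.5, g$tset$trajectories)
  kept2 <- filter_tracks(g$tset, g$mt_mask)
  expect_equal(length(kept2), length(ok_life))
})

test_that("event classification follows the run-length and dwell rules", {
  tset <- TrajectorySet(list(
    line_track("motile", 300, 2),
    line_track("immotile", 100, 5),
    line_track("too_long", 100, 15),
    line_track("too_short", 100, 1),
    line_track("at_threshold", 250, 3),
    Trajectory("out_and_back", c(0, 1.5, 3), c(0, 1000, 0), c(0, 0, 0))
  ), movie_duration_s = 20, pixel_size_nm = 100)
  ev <- classify_events(tset)
  got <- setNames(ev$event_class, ev$track_id)
  expect_equal(got[["motile"]], "motile")
  expect_equal(ev$velocity_nm_s[ev$track_id == "motile"], 150)
  expect_equal(got[["immotile"]], "immotile")
  expect_equal(got[["too_long"]], "discarded")
  expect_equal(got[["too_short"]], "discarded")
  expect_equal(got[["at_threshold"]], "discarded")  # strict inequalities
  # start-to-end vector: out-and-back has zero run length, so it is not
  # motile (its 3-s dwell makes it count as immotile)
  expect_equal(ev$run_length_nm[ev$track_id == "out_and_back"], 0)
  expect_equal(got[["out_and_back"]], "immotile")
  # partition: every track maps to exactly one class
  expect_equal(sum(table(ev$event_class)), length(tset))
})

test_that("start-to-end run length is bounded by the path sum", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(3:15, 1)
      t <- cumsum(runif(n, 0.05, 0.3))
      x <- cumsum(rnorm(n, 50, 120))
      y <- cumsum(rnorm(n, 0, 80))
      tr <- Trajectory("t", t, x, y)
      tset <- TrajectorySet(list(tr), max(t) + 1, 100)
      run <- classify_events(tset)$run_length_nm
      path_sum <- sum(sqrt(diff(x)^2 + diff(y)^2))
      expect_lte(run, path_sum + 1e-9)
      # insensitive to intermediate samples
      tr2 <- Trajectory("t", t[c(1, n)], x[c(1, n)], y[c(1, n)])
      run2 <- classify_events(TrajectorySet(list(tr2), max(t) + 1, 100))$run_length_nm
      expect_equal(run, run2)
    }
  })
})

test_that("microtubule length follows the skeleton step convention", {
  horiz <- matrix(FALSE, 20, 120)
  horiz[10, 11:110] <- TRUE  # 100 px bar
  len <- mt_total_length(BinaryMask(horiz), 100)
  expect_gte(len, 9.9); expect_lte(len, 10.0)

  diag45 <- matrix(FALSE, 120, 120)
  diag45[cbind(11:110, 11:110)] <- TRUE
  len2 <- mt_total_length(BinaryMask(diag45), 100)
  expect_equal(len2, 99 * sqrt(2) * 0.1, tolerance = 1e-9)

  # a thick bar thins to a line of nearly the same length
  thick <- matrix(FALSE, 20, 120)
  thick[9:11, 11:110] <- TRUE
  len3 <- mt_total_length(BinaryMask(thick), 100)
  expect_gt(len3, 9.5); expect_lt(len3, 10.1)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_warning(len4 <- mt_total_length(BinaryMask(single), 100), "0")
  expect_equal(len4, 0)
  expect_error(mt_total_length(BinaryMask(matrix(FALSE, 3, 3)), 100), "empty")
})

test_that("event summaries compute exact frequencies and stated estimators", {
  ev <- data.frame(
    track_id = sprintf("t%02d", 1:14),
    event_class = c(rep("motile", 12), "immotile", "discarded"),
    run_length_nm = c(seq(300, 1400, 100), 100, 100),
    duration_s = rep(2, 14),
    velocity_nm_s = c(seq(300, 1400, 100) / 2, NA, NA))
  st <- summarize_events(ev, mt_length_um = 40, duration_min = 1.5, seed = 1)
  expect_equal(st$freq_motile, 0.2)
  expect_equal(st$freq_motile * 40 * 1.5, 12)  # frequency identity, exact
  expect_equal(st$freq_immotile, 1 / 60)

  two <- data.frame(track_id = c("a", "b"), event_class = "motile",
                    run_length_nm = c(1250, 2250), duration_s = c(2, 3),
                    velocity_nm_s = c(625, 750))
  # truncated (shifted-exponential) fit estimates the exponential mean
  st_shift <- summarize_events(two, 10, 1, seed = 1)
  expect_equal(st_shift$mean_run_nm, 1500)
  # plain mean of observed runs: exceeds it by exactly r_min
  st_plain <- summarize_events(two, 10, 1, seed = 1, truncation = "none")
  expect_equal(st_plain$mean_run_nm, 1750)

  # same events and seed reproduce identical bootstrap CIs
  a <- summarize_events(ev, 40, 1.5, seed = 42)
  b <- summarize_events(ev, 40, 1.5, seed = 42)
  expect_identical(a$run_ci95, b$run_ci95)
  expect_identical(a$velocity_ci95, b$velocity_ci95)
  expect_true(a$run_ci95[1] <= a$mean_run_nm && a$mean_run_nm <= a$run_ci95[2])

  none <- ev[ev$event_class == "immotile", ]
  st0 <- summarize_events(none, 40, 1.5, seed = 1)
  expect_true(is.na(st0$mean_run_nm))
  expect_equal(st0$freq_immotile, 1 / 60)
})

test_that("bootstrap CI covers the generative mean run across seeds", {
  cover <- 0
  for (s in 1:10) {
    g <- gen_trajectories(mt_length_um = 40, duration_min = 5,
                          landing_rate_per_um_min = 2.5, seed = s)
    st <- summarize_events(classify_events(g$tset), 40, 5, seed = s + 100)
    cover <- cover + (st$run_ci95[1] <= 1200 && 1200 <= st$run_ci95[2])
  }
  expect_gte(cover, 8)
})

test_that("condition comparison reports ratio, Welch and KS statistics", {
  same <- c(1, 1.2, 0.8)
  cmp <- compare_conditions(same, same, same, same)
  expect_equal(cmp$ratio, 1.0)
  expect_equal(cmp$p_welch, 1.0)
  expect_equal(cmp$ks_D, 0)

  cmp2 <- compare_conditions(c(1, 1.2, 0.8), c(0.1, 0.12, 0.08))
  expect_equal(cmp2$ratio, 0.1)
  expect_equal(cmp2$p_welch,
               welch_p_oracle(c(0.1, 0.12, 0.08), c(1, 1.2, 0.8)),
               tolerance = 1e-12)

  expect_warning(z <- compare_conditions(c(0, 0), c(1, 2)), "ratio undefined")
  expect_true(is.na(z$ratio))
})

test_that("synthetic drug inhibition is recovered as a frequency ratio", {
  ratios <- vapply(1:5, function(s) {
    minus <- gen_trajectories(duration_min = 5, landing_rate_per_um_min = 2.5,
                              seed = s)
    plus <- gen_trajectories(duration_min = 5, landing_rate_per_um_min = 0.5,
                             seed = s + 500)
    sm <- summarize_events(classify_events(minus$tset), 40, 5, seed = 1)
    sp <- summarize_events(classify_events(plus$tset), 40, 5, seed = 1)
    sp$freq_motile / sm$freq_motile
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.2) / 0.2, 0.2)
})
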