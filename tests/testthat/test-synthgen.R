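test_that("Poisson fields obey their generative law and are deterministic", {
  f <- gen_poisson_field(100, c(256L, 256L), seed = 1)
  v <- as.vector(f$data)
  expect_lt(abs(mean(v) - 100) / 100, 0.01)
  expect_lt(abs(var(v) / mean(v) - 1), 0.05)
  f2 <- gen_poisson_field(100, c(256L, 256L), seed = 1)
  expect_identical(f$data, f2$data)
  expect_error(gen_poisson_field(0), "mean_level")
})

test_that("Golgi scenes place signal where the state dictates", {
  for (seed in 1:3) {
    cp <- gen_golgi_scene("compact", seed = seed)
    dp <- gen_golgi_scene("dispersed", seed = seed)
    ctr <- cp$truth$params$centre_rc
    rad <- sqrt(outer((seq_len(160) - ctr[1])^2, rep(1, 160)) +
                outer(rep(1, 160), (seq_len(160) - ctr[2])^2))
    band <- abs(rad - cp$truth$params$nucleus_radius_px) <= 10
    expect_gt(sum(cp$expected[band]) / sum(cp$expected), 0.9)
    expect_lt(sum(dp$expected[band]) / sum(dp$expected), 0.3)
    # equal expected total signal across states by construction
    expect_lt(abs(sum(cp$expected) - sum(dp$expected)) / sum(cp$expected), 0.01)
  }
  expect_error(gen_golgi_scene("compact", nucleus_radius_px = 100,
                               dim_px = c(120L, 120L)), "fit")
})

test_that("peroxisome movies move outward on schedule", {
  pm <- gen_perox_movie(speed_nm_s = 20, t_treat_s = 75, interval_s = 15,
                        n_frames = 12, seed = 3)
  r <- pm$truth$params$mean_radius_um
  post <- which(pm$truth$params$times_s > 75 + 15)
  # 20 nm/s x 15 s = 300 nm per frame until clamping
  expect_equal(diff(r[post]), rep(0.3, length(post) - 1), tolerance = 1e-9)

  still <- gen_perox_movie(speed_nm_s = 0, n_frames = 12, seed = 3)
  expect_equal(diff(still$truth$params$mean_radius_um), rep(0, 11))

  pm2 <- gen_perox_movie(speed_nm_s = 20, t_treat_s = 75, interval_s = 15,
                         n_frames = 12, seed = 3)
  expect_identical(pm$stack$data, pm2$stack$data)
  expect_error(gen_perox_movie(t_treat_s = 1e6), "beyond")
})

test_that("sliding movies realise the scheduled motile fraction", {
  mv0 <- gen_sliding_movie(rate_pct_min = 0, n_frames = 4, seed = 2,
                           dim_px = c(192L, 192L), zone_radius_px = 50,
                           n_segments = 12L)
  expect_equal(mv0$truth$params$true_mf_pct, rep(0, 4))

  mv <- gen_sliding_movie(rate_pct_min = 5, n_frames = 8, interval_s = 60,
                          seed = 2)
  sched <- pmin(5 * mv$truth$params$times_min, 80)
  expect_equal(mv$truth$params$true_mf_pct, sched, tolerance = 0.3)

  # bleaching shows up in the rendered frame means
  mvb <- gen_sliding_movie(rate_pct_min = 0, n_frames = 3, seed = 5,
                           bleach_per_frame = 0.1, dim_px = c(192L, 192L),
                           zone_radius_px = 50, n_segments = 12L)
  means <- apply(mvb$stack$data[, 1, , ], 1, mean)
  expect_equal(means[2] / means[1], 0.9, tolerance = 0.02)

  expect_error(gen_sliding_movie(bleach_per_frame = 1), "bleach")
})

test_that("generated trajectories follow the landing and run-length laws", {
  g <- gen_trajectories(mt_length_um = 40, duration_min = 2,
                        landing_rate_per_um_min = 0.5, seed = 1)
  lambda <- 0.5 * 40 * 2
  expect_lt(abs(g$truth$params$n_landings - lambda), 3 * sqrt(lambda))

  # noiseless motile tracks: start-to-end distance equals the true run exactly
  gn <- gen_trajectories(mt_length_um = 20, duration_min = 2,
                         landing_rate_per_um_min = 1, motile_fraction = 1,
                         loc_noise_nm = 0, seed = 2)
  ev <- classify_events(gn$tset)
  expect_equal(ev$run_length_nm, gn$truth$params$true_run_nm, tolerance = 1e-9)

  # CLT check on the generated run-length law across seeds
  runs <- unlist(lapply(1:3, function(s) {
    gg <- gen_trajectories(mt_length_um = 40, duration_min = 4,
                           landing_rate_per_um_min = 1.2, motile_fraction = 1,
                           mean_run_nm = 1200, seed = s)
    gg$truth$params$true_run_nm
  }))
  expect_gt(length(runs), 400)
  expect_lt(abs(mean(runs) - 1200), 2 * 1200 / sqrt(length(runs)))

  # determinism: same seed and parameters give identical output
  g2 <- gen_trajectories(mt_length_um = 40, duration_min = 2,
                         landing_rate_per_um_min = 0.5, seed = 1)
  expect_identical(lapply(g$tset$trajectories, unclass),
                   lapply(g2$tset$trajectories, unclass))
  expect_identical(unclass(g$mt_mask), unclass(g2$mt_mask))
})

test_that("truth sidecars round-trip through JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  g <- gen_sliding_movie(rate_pct_min = 5, n_frames = 3, seed = 9,
                         dim_px = c(96L, 96L), zone_radius_px = 30,
                         n_segments = 6L)
  write_truth(g$truth, p)
  back <- read_truth(p)
  expect_equal(back$seed, g$truth$seed)
  expect_equal(back$scenario, g$truth$scenario)
  expect_equal(back$params$true_mf_pct, g$truth$params$true_mf_pct)
})
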