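#' Ground-truth record for a synthetic dataset
#'
#' Every generator attaches one of these to its output; together with the seed
#' it is sufficient to regenerate the dataset bit-identically and to recompute
#' its ground-truth summary curves.
#'
#' @param seed RNG seed used.
#' @param scenario generator label.
#' @param params named list of all generative parameters.
#' @export
SyntheticTruth <- function(seed, scenario, params) {
  structure(list(seed = seed, scenario = scenario, params = params),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth '%s' (seed %d): %d parameter(s)\n",
              x$scenario, x$seed, length(x$params)))
  invisible(x)
}

#' Write / read a SyntheticTruth JSON sidecar
#' @param truth a [SyntheticTruth].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  SyntheticTruth(x$seed, x$scenario, x$params)
}

#' Pure shot-noise test field
#'
#' Every pixel is an independent Poisson draw with the given mean — the
#' calibration bed for the Golgi integrity statistic, whose whole point is
#' that SD/sqrt(mean) of pure shot noise is 1 regardless of exposure.
#'
#' @param mean_level expected photons per pixel (> 0).
#' @param shape `c(rows, cols)`.
#' @param seed RNG seed.
#' @param pixel_size_nm calibration attached to the result.
#' @return an [ImageStack] of shape (1, 1, rows, cols).
#' @export
gen_poisson_field <- function(mean_level, shape = c(256L, 256L), seed = 1L,
                              pixel_size_nm = 100) {
  if (mean_level <= 0) stop("mean_level must be > 0", call. = FALSE)
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(prod(shape), mean_level), shape[1], shape[2])
  })
  ImageStack(m, pixel_size_nm, 0, "poisson")
}

#' Synthetic two-channel Golgi scene
#'
#' Renders a nucleus channel (filled disc over background) and a Golgi channel
#' in one of two states: `"compact"` places all Golgi signal in a crescent of
#' Gaussian puncta hugging the nucleus border (within `band_px` of it);
#' `"dispersed"` splits the same expected total signal into many puncta spread
#' uniformly over the cell footprint. Poisson noise is applied last, so the
#' expected total Golgi signal is equal across states by construction.
#'
#' @param state `"compact"` or `"dispersed"`.
#' @param nucleus_radius_px nucleus disc radius, pixels.
#' @param total_signal expected total Golgi photons above background.
#' @param seed RNG seed.
#' @param dim_px frame shape `c(rows, cols)`.
#' @param cell_radius_px cell footprint radius for the dispersed state.
#' @param band_px width of the perinuclear band holding compact spots.
#' @param n_compact,n_dispersed punctum counts per state.
#' @param background,nucleus_level expected background / nuclear photons per
#'   pixel.
#' @param pixel_size_nm calibration attached to the stack.
#' @return list with `stack` (channels `"golgi"`, `"nucleus"`), `truth`
#'   ([SyntheticTruth], including spot centres), and `expected` (noise-free
#'   Golgi channel above background, the oracle for signal-placement checks).
#' @export
gen_golgi_scene <- function(state = c("compact", "dispersed"),
                            nucleus_radius_px = 25, total_signal = 2e5,
                            seed = 1L, dim_px = c(160L, 160L),
                            cell_radius_px = 70, band_px = 10,
                            n_compact = 12L, n_dispersed = 40L,
                            background = 20, nucleus_level = 600,
                            pixel_size_nm = 100) {
  state <- match.arg(state)
  if (total_signal <= 0) stop("total_signal must be > 0", call. = FALSE)
  nr <- dim_px[1]; nc <- dim_px[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  if (nucleus_radius_px + band_px >= min(nr, nc) / 2) {
    stop("nucleus does not fit in the frame", call. = FALSE)
  }
  rr <- outer(seq_len(nr) - ctr[1], rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc) - ctr[2])
  rad <- sqrt(rr^2 + cc^2)

  withr::with_seed(seed, {
    if (state == "compact") {
      n_spots <- n_compact
      theta0 <- stats::runif(1, 0, 2 * pi)
      theta <- theta0 + stats::runif(n_spots, 0, 2 * pi / 3)
      r_spot <- nucleus_radius_px + stats::runif(n_spots, 1, band_px - 2)
    } else {
      n_spots <- n_dispersed
      theta <- stats::runif(n_spots, 0, 2 * pi)
      r_spot <- cell_radius_px * sqrt(stats::runif(n_spots))
    }
    centres <- cbind(ctr[1] + r_spot * sin(theta), ctr[2] + r_spot * cos(theta))
    expected <- render_spots(matrix(0, nr, nc), centres,
                             rep(total_signal / n_spots, n_spots))
    golgi <- matrix(stats::rpois(nr * nc, as.vector(expected + background)), nr, nc)
    nucleus_exp <- background + nucleus_level * (rad <= nucleus_radius_px)
    nucleus <- matrix(stats::rpois(nr * nc, as.vector(nucleus_exp)), nr, nc)
  })

  data <- array(0, c(1L, 2L, nr, nc))
  data[1, 1, , ] <- golgi
  data[1, 2, , ] <- nucleus
  truth <- SyntheticTruth(seed, "golgi_scene", list(
    dispersion_state = state, nucleus_radius_px = nucleus_radius_px,
    total_signal = total_signal, n_spots = n_spots,
    centre_rc = ctr, cell_radius_px = cell_radius_px, band_px = band_px,
    background = background, nucleus_level = nucleus_level,
    spot_r = centres[, 1], spot_c = centres[, 2], poisson_noise = TRUE))
  list(stack = ImageStack(data, pixel_size_nm, 0, c("golgi", "nucleus")),
       truth = truth, expected = expected)
}

#' Synthetic inducible peroxisome-redistribution movie
#'
#' Two-channel time-lapse: `"561"` carries peroxisome puncta that jitter in
#' place before the treatment time and then move radially outward at a set
#' speed until they reach the cell boundary; `"488"` carries a motor
#' recruitment signal that ramps from background to a plateau on the puncta
#' after treatment. Poisson noise is applied last.
#'
#' @param n_spots number of peroxisomes.
#' @param speed_nm_s outward radial speed after treatment.
#' @param t_treat_s treatment-addition time, seconds (must fall inside the
#'   movie).
#' @param n_frames,interval_s number of frames and frame interval (this assay
#'   is typically acquired at 15-s intervals).
#' @param seed RNG seed.
#' @param dim_px frame shape.
#' @param pixel_size_nm pixel size.
#' @param r0_range_um initial radius range, µm.
#' @param cell_radius_um clamping radius (cell boundary), µm.
#' @param jitter_nm per-frame isotropic Brownian jitter SD.
#' @param spot_photons,background expected photons per punctum / per background
#'   pixel (561 channel).
#' @param green_plateau,green_background,ramp_s 488-channel recruitment signal:
#'   per-spot photons rise linearly from 0 to `green_plateau` over `ramp_s`
#'   after treatment.
#' @return list with `stack` (channels `"561"`, `"488"`), `centre_nm` (cell
#'   centre, `c(x, y)` nm), and `truth` whose params include the per-frame
#'   ground-truth mean radius `mean_radius_um`.
#' @export
gen_perox_movie <- function(n_spots = 20L, speed_nm_s = 20, t_treat_s = 75,
                            n_frames = 24L, interval_s = 15, seed = 1L,
                            dim_px = c(256L, 256L), pixel_size_nm = 100,
                            r0_range_um = c(1, 3), cell_radius_um = 11,
                            jitter_nm = 30, spot_photons = 3000,
                            background = 10, green_plateau = 400,
                            green_background = 5, ramp_s = 60) {
  if (n_spots < 1L) stop("n_spots must be >= 1", call. = FALSE)
  if (interval_s <= 0) stop("interval_s must be > 0", call. = FALSE)
  times <- (seq_len(n_frames) - 1L) * interval_s
  if (t_treat_s >= max(times)) {
    stop("t_treat_s lies beyond the end of the movie", call. = FALSE)
  }
  nr <- dim_px[1]; nc <- dim_px[2]
  ctr_rc <- c((nr + 1) / 2, (nc + 1) / 2)
  data <- array(0, c(n_frames, 2L, nr, nc))
  truth_radius <- numeric(n_frames)

  withr::with_seed(seed, {
    theta <- stats::runif(n_spots, 0, 2 * pi)
    r0 <- stats::runif(n_spots, r0_range_um[1], r0_range_um[2]) * 1000  # nm
    for (f in seq_len(n_frames)) {
      t <- times[f]
      r_t <- pmin(r0 + speed_nm_s * max(0, t - t_treat_s), cell_radius_um * 1000)
      truth_radius[f] <- mean(r_t) / 1000
      jit_r <- stats::rnorm(n_spots, 0, jitter_nm)
      jit_t <- stats::rnorm(n_spots, 0, jitter_nm)
      rows <- ctr_rc[1] + (r_t * sin(theta) + jit_r) / pixel_size_nm
      cols <- ctr_rc[2] + (r_t * cos(theta) + jit_t) / pixel_size_nm
      red_exp <- render_spots(matrix(0, nr, nc), cbind(rows, cols),
                              rep(spot_photons, n_spots)) + background
      green_amp <- green_plateau * min(1, max(0, (t - t_treat_s) / ramp_s))
      green_exp <- render_spots(matrix(0, nr, nc), cbind(rows, cols),
                                rep(green_amp, n_spots)) + green_background
      data[f, 1, , ] <- stats::rpois(nr * nc, as.vector(red_exp))
      data[f, 2, , ] <- stats::rpois(nr * nc, as.vector(green_exp))
    }
  })

  centre_nm <- c((ctr_rc[2] - 1) * pixel_size_nm, (ctr_rc[1] - 1) * pixel_size_nm)
  truth <- SyntheticTruth(seed, "perox_movie", list(
    n_spots = n_spots, perox_speed_nm_s = speed_nm_s, t_treat_s = t_treat_s,
    interval_s = interval_s, pixel_size_nm = pixel_size_nm,
    cell_radius_um = cell_radius_um, jitter_nm = jitter_nm,
    background_level = background, poisson_noise = TRUE,
    times_s = times, mean_radius_um = truth_radius))
  list(stack = ImageStack(data, pixel_size_nm, interval_s, c("561", "488")),
       centre_nm = centre_nm, truth = truth)
}

# One curvilinear microtubule segment: a bounded-curvature random walk of
# n_steps steps of step_px pixels, centred on the origin.
random_segment <- function(n_steps = 10L, step_px = 3, turn_sd_deg = 15) {
  ang <- stats::runif(1, 0, 2 * pi) +
    cumsum(c(0, stats::rnorm(n_steps - 1L, 0, turn_sd_deg * pi / 180)))
  verts <- cbind(cumsum(c(0, step_px * sin(ang))), cumsum(c(0, step_px * cos(ang))))
  sweep(verts, 2, colMeans(verts))
}

#' Synthetic photoconverted microtubule-sliding movie
#'
#' Curvilinear microtubule segments start inside a compact photoconverted
#' zone; per frame a scheduled subset is translocated fully outside the zone
#' so the ground-truth motile fraction follows `min(rate_pct_min * t,
#' plateau_pct)` (granular at `100 / n_segments` %). Global intensity decays
#' by `(1 - bleach_per_frame)` per frame before Poisson noise.
#'
#' @param rate_pct_min ground-truth sliding rate, percent motile fraction per
#'   minute.
#' @param n_frames,interval_s movie length and frame interval (60 s in the
#'   original acquisition).
#' @param bleach_per_frame fractional intensity loss per frame, in [0, 1).
#' @param seed RNG seed.
#' @param dim_px frame shape.
#' @param zone_radius_px radius of the photoconverted zone (disc at frame
#'   centre).
#' @param n_segments number of microtubule segments.
#' @param plateau_pct motile-fraction plateau.
#' @param amplitude,background photons on microtubule pixels / background.
#' @param pixel_size_nm calibration.
#' @return list with `stack` and `truth`; truth params include the per-frame
#'   realised motile fraction `true_mf_pct`.
#' @export
gen_sliding_movie <- function(rate_pct_min = 5, n_frames = 8L, interval_s = 60,
                              bleach_per_frame = 0.05, seed = 1L,
                              dim_px = c(384L, 384L), zone_radius_px = 100,
                              n_segments = 50L, plateau_pct = 80,
                              amplitude = 600, background = 20,
                              pixel_size_nm = 100) {
  if (bleach_per_frame < 0 || bleach_per_frame >= 1) {
    stop("bleach_per_frame must be in [0, 1)", call. = FALSE)
  }
  if (rate_pct_min < 0) stop("rate_pct_min must be >= 0", call. = FALSE)
  nr <- dim_px[1]; nc <- dim_px[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  times_min <- (seq_len(n_frames) - 1L) * interval_s / 60

  withr::with_seed(seed, {
    # place each segment twice without pixel overlap (rejection sampling):
    # once inside the zone, once at its out-of-zone destination, so every
    # segment contributes the same pixel count whether moved or not and the
    # pixel motile fraction tracks the scheduled segment fraction
    segs <- vector("list", n_segments)
    segs_out <- vector("list", n_segments)
    occ_in <- matrix(FALSE, nr, nc)
    occ_out <- matrix(FALSE, nr, nc)
    r_max <- min(nr, nc) / 2 - 2
    place <- function(v, ext, occ, inside_zone) {
      for (try in 1:40) {
        a <- stats::runif(1, 0, 2 * pi)
        if (inside_zone) {
          r <- max(0, zone_radius_px - ext - 2) * sqrt(stats::runif(1))
        } else {
          lo <- zone_radius_px + ext + 6
          hi <- max(r_max - ext, lo + 1)
          r <- sqrt(stats::runif(1, lo^2, hi^2))
        }
        cand <- sweep(v, 2, c(ctr[1] + r * sin(a), ctr[2] + r * cos(a)), "+")
        px <- rasterize_polyline(matrix(FALSE, nr, nc), cand, radius_px = 2)
        if (!any(px & occ) || try == 40L) return(list(v = cand, px = px))
      }
    }
    for (i in seq_len(n_segments)) {
      v <- random_segment()
      ext <- max(sqrt(rowSums(v^2)))
      p_in <- place(v, ext, occ_in, TRUE)
      segs[[i]] <- p_in$v
      occ_in <- occ_in | p_in$px
      p_out <- place(v, ext, occ_out, FALSE)
      segs_out[[i]] <- p_out$v
      occ_out <- occ_out | p_out$px
    }
    move_order <- sample.int(n_segments)
    true_mf <- numeric(n_frames)
    data <- array(0, c(n_frames, 1L, nr, nc))
    for (f in seq_len(n_frames)) {
      frac <- min(rate_pct_min * times_min[f], plateau_pct) / 100
      m <- round(frac * n_segments)
      true_mf[f] <- 100 * m / n_segments
      lines <- matrix(FALSE, nr, nc)
      moved <- move_order[seq_len(m)]
      for (i in seq_len(n_segments)) {
        v <- if (i %in% moved) segs_out[[i]] else segs[[i]]
        lines <- rasterize_polyline(lines, v, radius_px = 1)
      }
      expected <- (background + amplitude * lines) * (1 - bleach_per_frame)^(f - 1L)
      data[f, 1, , ] <- stats::rpois(nr * nc, as.vector(expected))
    }
  })

  truth <- SyntheticTruth(seed, "sliding_movie", list(
    sliding_rate_pct_min = rate_pct_min, interval_s = interval_s,
    bleach_per_frame = bleach_per_frame, zone_radius_px = zone_radius_px,
    n_segments = n_segments, plateau_pct = plateau_pct,
    background_level = background, poisson_noise = TRUE,
    times_min = times_min, true_mf_pct = true_mf))
  list(stack = ImageStack(data, pixel_size_nm, interval_s, "photoconverted"),
       truth = truth)
}

# Piecewise-linear microtubule path of a given arc length (nm), plus helpers
# for arc-length interpolation.
random_mt_path <- function(length_nm, step_nm = 1000, turn_sd_deg = 8) {
  n <- ceiling(length_nm / step_nm)
  ang <- stats::runif(1, 0, 2 * pi) +
    cumsum(c(0, stats::rnorm(n - 1L, 0, turn_sd_deg * pi / 180)))
  steps <- rep(step_nm, n)
  steps[n] <- length_nm - (n - 1L) * step_nm
  verts <- cbind(cumsum(c(0, steps * cos(ang))), cumsum(c(0, steps * sin(ang))))
  list(verts = verts, arc = c(0, cumsum(steps)))
}

path_point <- function(path, s) {
  s <- pmin(pmax(s, 0), path$arc[length(path$arc)])
  i <- findInterval(s, path$arc, rightmost.closed = TRUE)
  i <- pmin(i, nrow(path$verts) - 1L)
  f <- (s - path$arc[i]) / (path$arc[i + 1L] - path$arc[i])
  cbind(path$verts[i, 1] + f * (path$verts[i + 1L, 1] - path$verts[i, 1]),
        path$verts[i, 2] + f * (path$verts[i + 1L, 2] - path$verts[i, 2]))
}

#' Synthetic single-molecule motor trajectories on a microtubule
#'
#' Landings follow a Poisson process with expectation `landing_rate * length *
#' duration`. Each landing is motile with probability `motile_fraction`:
#' its run length is Exponential with the given mean (clamped at the
#' microtubule ends), its speed Normal truncated to positive values, and it
#' is sampled every `sample_interval_s` along the microtubule path. Immotile
#' landings dwell in place for a Uniform time. Isotropic Gaussian
#' localization noise is added to every sample. The truth records each
#' track's class and true (noise-free) run length.
#'
#' @param mt_length_um microtubule length.
#' @param duration_min movie duration, minutes.
#' @param landing_rate_per_um_min landing rate per µm of microtubule per
#'   minute.
#' @param motile_fraction probability a landing is motile, in [0, 1].
#' @param mean_run_nm mean of the exponential run-length law.
#' @param mean_velocity_nm_s,velocity_sd Normal velocity law (truncated > 0).
#' @param immotile_dwell_range_s dwell-time range for immotile landings; the
#'   default sits inside the 2.5–10 s counting window so generated immotile
#'   events are countable; widen it to exercise the discard rules.
#' @param loc_noise_nm localization noise SD per axis.
#' @param sample_interval_s camera sampling interval.
#' @param seed RNG seed.
#' @param pixel_size_nm calibration used to rasterize the microtubule mask.
#' @param mask_halfwidth_px half-width of the rasterized microtubule mask.
#' @return list with `tset` ([TrajectorySet]), `mt_mask` ([BinaryMask]), and
#'   `truth` (per-track `class`, `true_run_nm`, `velocity_nm_s`).
#' @export
gen_trajectories <- function(mt_length_um = 40, duration_min = 2,
                             landing_rate_per_um_min = 0.5,
                             motile_fraction = 0.7, mean_run_nm = 1200,
                             mean_velocity_nm_s = 800, velocity_sd = 150,
                             immotile_dwell_range_s = c(2.5, 10),
                             loc_noise_nm = 20, sample_interval_s = 0.1,
                             seed = 1L, pixel_size_nm = 107,
                             mask_halfwidth_px = 1) {
  stopifnot(mt_length_um > 0, duration_min > 0, landing_rate_per_um_min >= 0,
            motile_fraction >= 0, motile_fraction <= 1, mean_run_nm > 0,
            mean_velocity_nm_s > 0, sample_interval_s > 0)
  T_s <- duration_min * 60
  L_nm <- mt_length_um * 1000

  withr::with_seed(seed, {
    path <- random_mt_path(L_nm)
    n_land <- stats::rpois(1, landing_rate_per_um_min * mt_length_um * duration_min)
    trajs <- vector("list", n_land)
    cls <- character(n_land)
    true_run <- numeric(n_land)
    vel_true <- numeric(n_land)
    for (k in seq_len(n_land)) {
      motile <- stats::runif(1) < motile_fraction
      if (motile) {
        v <- -1
        while (v <= 0) v <- stats::rnorm(1, mean_velocity_nm_s, velocity_sd)
        # draw the run first, then a landing position where it completes on
        # the path, so realized runs follow the exponential law exactly
        run <- Inf
        while (run >= L_nm) run <- stats::rexp(1, 1 / mean_run_nm)
        dir <- sample(c(-1, 1), 1)
        s0u <- stats::runif(1, 0, L_nm - run)
        s0 <- if (dir > 0) s0u else L_nm - s0u
        dur <- run / v
        cls[k] <- "motile"; vel_true[k] <- v
      } else {
        dur <- stats::runif(1, immotile_dwell_range_s[1], immotile_dwell_range_s[2])
        s0 <- stats::runif(1, 0, L_nm)
        dir <- 0
        v <- 0
        cls[k] <- "immotile"; true_run[k] <- 0; vel_true[k] <- NA_real_
      }
      t0 <- stats::runif(1, 0, max(T_s - dur, 0))
      offs <- unique(c(seq(0, dur, by = sample_interval_s), dur))
      if (length(offs) < 2L) offs <- c(0, dur)
      s_t <- s0 + dir * v * offs
      pts <- path_point(path, s_t)
      if (cls[k] == "motile") {
        # the analysable truth is the start-to-end chord: on a curved path it
        # sits slightly below the arc-length run drawn from the exponential
        n_p <- nrow(pts)
        true_run[k] <- sqrt((pts[n_p, 1] - pts[1, 1])^2 +
                            (pts[n_p, 2] - pts[1, 2])^2)
      }
      trajs[[k]] <- Trajectory(
        sprintf("trk%04d", k), t0 + offs,
        pts[, 1] + stats::rnorm(length(offs), 0, loc_noise_nm),
        pts[, 2] + stats::rnorm(length(offs), 0, loc_noise_nm))
    }
  })

  # rasterize the microtubule path onto a pixel grid with a margin wide
  # enough that localization noise cannot push samples off the canvas
  margin_px <- 8
  mins <- apply(path$verts, 2, min)
  maxs <- apply(path$verts, 2, max)
  off_nm <- mins - margin_px * pixel_size_nm
  nrow_px <- ceiling((maxs[2] - off_nm[2]) / pixel_size_nm) + margin_px + 1
  ncol_px <- ceiling((maxs[1] - off_nm[1]) / pixel_size_nm) + margin_px + 1
  verts_rc <- cbind((path$verts[, 2] - off_nm[2]) / pixel_size_nm + 1,
                    (path$verts[, 1] - off_nm[1]) / pixel_size_nm + 1)
  mask <- rasterize_polyline(matrix(FALSE, nrow_px, ncol_px), verts_rc,
                             radius_px = mask_halfwidth_px, step = 0.3)
  # shift trajectories into the same pixel frame
  trajs <- lapply(trajs, function(tr) {
    Trajectory(tr$track_id, tr$t_s, tr$x_nm - off_nm[1], tr$y_nm - off_nm[2])
  })

  truth <- SyntheticTruth(seed, "trajectories", list(
    mt_length_um = mt_length_um, duration_min = duration_min,
    landing_rate_per_um_min = landing_rate_per_um_min,
    motile_fraction = motile_fraction, mean_run_nm = mean_run_nm,
    mean_velocity_nm_s = mean_velocity_nm_s, velocity_sd = velocity_sd,
    immotile_dwell_range_s = immotile_dwell_range_s,
    loc_noise_nm = loc_noise_nm, sample_interval_s = sample_interval_s,
    pixel_size_nm = pixel_size_nm, n_landings = n_land,
    track_class = cls, true_run_nm = true_run, true_velocity_nm_s = vel_true))
  list(tset = TrajectorySet(trajs, T_s, pixel_size_nm, "synthetic"),
       mt_mask = BinaryMask(mask, "microtubule"), truth = truth)
}
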