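#' Filter trajectories by lifetime and microtubule overlap
#'
#' Keeps tracks whose lifetime is at least `min_lifetime_s` and whose every
#' sample falls on the microtubule mask dilated by `overlap_tol_px` pixels
#' (the spatial "fully overlaps the microtubule image" rule with a small
#' tolerance for localization noise).
#'
#' @param tset a [TrajectorySet]; its `pixel_size_nm` maps nm positions onto
#'   mask pixels.
#' @param mt_mask [BinaryMask] of the microtubule channel (non-empty).
#' @param min_lifetime_s minimum track lifetime, seconds.
#' @param overlap_tol_px dilation tolerance, pixels.
#' @return the filtered [TrajectorySet].
#' @export
filter_tracks <- function(tset, mt_mask, min_lifetime_s = 0.5,
                          overlap_tol_px = 1L) {
  stopifnot(inherits(tset, "TrajectorySet"))
  m <- mask_values(mt_mask)
  if (!any(m)) stop("microtubule mask is empty", call. = FALSE)
  if (overlap_tol_px > 0) m <- disc_dilate(m, overlap_tol_px)
  px <- tset$pixel_size_nm
  nr <- nrow(m); nc <- ncol(m)
  keep <- vapply(tset$trajectories, function(tr) {
    if (lifetime(tr) < min_lifetime_s) return(FALSE)
    cols <- round(tr$x_nm / px) + 1L
    rows <- round(tr$y_nm / px) + 1L
    if (any(rows < 1L | rows > nr | cols < 1L | cols > nc)) return(FALSE)
    all(m[cbind(rows, cols)])
  }, logical(1))
  TrajectorySet(tset$trajectories[keep], tset$movie_duration_s,
                tset$pixel_size_nm, tset$field_id)
}

#' Classify landing events as motile, immotile or discarded
#'
#' The run length of a track is the Euclidean distance between its first and
#' last sample (a start-to-end-point vector, insensitive to positional noise,
#' rather than a sum of instantaneous displacements). A track is motile when
#' its run length exceeds `r_min_nm`; it is immotile when the run length is
#' below `r_min_nm` and its duration lies within the immotile counting window
#' (2.5–10 s by default; shorter landings are indistinguishable from
#' transient collisions and longer ones from nonspecific adsorption, so both
#' are discarded). A run length exactly at the threshold is discarded, the
#' strict-inequality convention of both rules.
#'
#' @param tset a filtered [TrajectorySet].
#' @param r_min_nm motile run-length threshold, nm.
#' @param immotile_window_s `c(min, max)` duration window for immotile events.
#' @return data.frame of `MotilityEvent` rows: `track_id`, `event_class`,
#'   `run_length_nm`, `duration_s`, `velocity_nm_s` (run length over duration;
#'   NA for non-motile events).
#' @export
classify_events <- function(tset, r_min_nm = 250,
                            immotile_window_s = c(2.5, 10)) {
  stopifnot(inherits(tset, "TrajectorySet"))
  n <- length(tset$trajectories)
  out <- data.frame(
    track_id = character(n), event_class = character(n),
    run_length_nm = numeric(n), duration_s = numeric(n),
    velocity_nm_s = rep(NA_real_, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- tset$trajectories[[i]]
    k <- length(tr$t_s)
    run <- sqrt((tr$x_nm[k] - tr$x_nm[1])^2 + (tr$y_nm[k] - tr$y_nm[1])^2)
    dur <- lifetime(tr)
    cls <- if (run > r_min_nm) {
      "motile"
    } else if (run < r_min_nm && dur >= immotile_window_s[1] &&
               dur <= immotile_window_s[2]) {
      "immotile"
    } else {
      "discarded"
    }
    out$track_id[i] <- tr$track_id
    out$event_class[i] <- cls
    out$run_length_nm[i] <- run
    out$duration_s[i] <- dur
    if (cls == "motile") out$velocity_nm_s[i] <- run / dur
  }
  class(out) <- c("MotilityEvents", "data.frame")
  out
}

#' Summary statistics for a set of motility events
#'
#' Event frequencies are counts normalised per micrometre of microtubule per
#' minute: `freq = n / (mt_length_um * duration_min)`, exactly. The mean run
#' length is extracted from an exponential fit to the motile run lengths
#' that treats the `r_min_nm` detection threshold as a left truncation: for
#' an exponential law the excess over the threshold is again exponential
#' with the same mean, so the maximum-likelihood mean run is the sample mean
#' of `run - r_min_nm` (`truncation = "shifted"`, default). With
#' `truncation = "none"` the plain sample mean of the observed runs is
#' reported instead; for truncated data it exceeds the generative mean by
#' `r_min_nm`. The mean velocity is the sample mean of motile velocities
#' (the normal-fit mean). 95% confidence intervals are percentile bootstrap
#' over events, `n_boot` resamples, seeded for reproducibility.
#'
#' @param events `MotilityEvents` data.frame from [classify_events()].
#' @param mt_length_um total microtubule length in the field, µm.
#' @param duration_min movie duration, minutes.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param r_min_nm motile threshold used in classification.
#' @param truncation `"shifted"` or `"none"` (see Details).
#' @return an `EventStats` list: counts, frequencies, `mean_run_nm` and
#'   `mean_velocity_nm_s` with `ci95` bounds, `n_boot`, `seed`.
#' @export
summarize_events <- function(events, mt_length_um, duration_min,
                             n_boot = 2000L, seed = 1L, r_min_nm = 250,
                             truncation = c("shifted", "none")) {
  truncation <- match.arg(truncation)
  stopifnot(mt_length_um > 0, duration_min > 0)
  motile <- events[events$event_class == "motile", , drop = FALSE]
  n_mot <- nrow(motile)
  n_imm <- sum(events$event_class == "immotile")
  est_run <- function(runs) {
    if (truncation == "shifted") mean(runs - r_min_nm) else mean(runs)
  }
  res <- list(
    n_motile = n_mot, n_immotile = n_imm,
    mt_length_um = mt_length_um, duration_min = duration_min,
    freq_motile = n_mot / (mt_length_um * duration_min),
    freq_immotile = n_imm / (mt_length_um * duration_min),
    mean_run_nm = NA_real_, run_ci95 = c(NA_real_, NA_real_),
    mean_velocity_nm_s = NA_real_, velocity_ci95 = c(NA_real_, NA_real_),
    r_min_nm = r_min_nm, truncation = truncation,
    n_boot = n_boot, seed = seed)
  if (n_mot >= 1L) {
    res$mean_run_nm <- est_run(motile$run_length_nm)
    res$mean_velocity_nm_s <- mean(motile$velocity_nm_s)
    withr::with_seed(seed, {
      idx <- matrix(sample.int(n_mot, n_mot * n_boot, replace = TRUE),
                    nrow = n_boot)
      boot_run <- apply(idx, 1, function(i) est_run(motile$run_length_nm[i]))
      boot_vel <- apply(idx, 1, function(i) mean(motile$velocity_nm_s[i]))
    })
    res$run_ci95 <- unname(stats::quantile(boot_run, c(0.025, 0.975)))
    res$velocity_ci95 <- unname(stats::quantile(boot_vel, c(0.025, 0.975)))
    res$run_boot_se <- stats::sd(boot_run)
  }
  structure(res, class = "EventStats")
}

#' @export
as.data.frame.EventStats <- function(x, ...) {
  data.frame(n_motile = x$n_motile, n_immotile = x$n_immotile,
             mt_length_um = x$mt_length_um, duration_min = x$duration_min,
             freq_motile = x$freq_motile, freq_immotile = x$freq_immotile,
             mean_run_nm = x$mean_run_nm,
             run_ci_lo = x$run_ci95[1], run_ci_hi = x$run_ci95[2],
             mean_velocity_nm_s = x$mean_velocity_nm_s,
             velocity_ci_lo = x$velocity_ci95[1],
             velocity_ci_hi = x$velocity_ci95[2],
             n_boot = x$n_boot, seed = x$seed)
}

#' @export
print.EventStats <- function(x, ...) {
  cat(sprintf("EventStats: %d motile, %d immotile over %.3g um x %.3g min\n",
              x$n_motile, x$n_immotile, x$mt_length_um, x$duration_min))
  cat(sprintf("  freq %.4g (motile) / %.4g (immotile) events/um/min\n",
              x$freq_motile, x$freq_immotile))
  if (is.finite(x$mean_run_nm)) {
    cat(sprintf("  mean run %.0f nm [%.0f, %.0f], mean velocity %.0f nm/s [%.0f, %.0f] (boot n=%d)\n",
                x$mean_run_nm, x$run_ci95[1], x$run_ci95[2],
                x$mean_velocity_nm_s, x$velocity_ci95[1], x$velocity_ci95[2],
                x$n_boot))
  }
  invisible(x)
}

#' Compare event frequencies between conditions
#'
#' `ratio` is mean(+drug) / mean(-drug) of per-movie event frequencies;
#' `p_welch` is a heteroscedastic (Welch) two-tailed t-test on the same
#' values. When per-cell rates are supplied (e.g. sliding rates per cell),
#' a two-sample Kolmogorov–Smirnov test is also reported.
#'
#' @param freqs_minus,freqs_plus per-movie event frequencies without / with
#'   drug (>= 2 values each for the t-test).
#' @param per_cell_minus,per_cell_plus optional per-cell rate distributions
#'   for the KS test.
#' @return a `ConditionComparison` list with `ratio`, `p_welch`, and (when
#'   per-cell rates are given) `p_ks` and `ks_D`.
#' @export
compare_conditions <- function(freqs_minus, freqs_plus,
                               per_cell_minus = NULL, per_cell_plus = NULL) {
  mminus <- mean(freqs_minus)
  ratio <- if (mminus == 0) NA_real_ else mean(freqs_plus) / mminus
  if (is.na(ratio)) {
    warning("mean of the -drug group is 0; ratio undefined", call. = FALSE)
  }
  p_welch <- if (length(freqs_minus) >= 2L && length(freqs_plus) >= 2L) {
    if (stats::var(freqs_minus) == 0 && stats::var(freqs_plus) == 0) {
      if (mean(freqs_minus) == mean(freqs_plus)) 1 else 0
    } else {
      stats::t.test(freqs_plus, freqs_minus, var.equal = FALSE)$p.value
    }
  } else {
    NA_real_
  }
  out <- list(ratio = ratio, p_welch = p_welch,
              p_ks = NA_real_, ks_D = NA_real_)
  if (!is.null(per_cell_minus) && !is.null(per_cell_plus)) {
    ks <- suppressWarnings(stats::ks.test(per_cell_minus, per_cell_plus))
    out$p_ks <- ks$p.value
    out$ks_D <- unname(ks$statistic)
  }
  structure(out, class = "ConditionComparison")
}

#' @export
print.ConditionComparison <- function(x, ...) {
  cat(sprintf("ConditionComparison: ratio %.4g, Welch p %.4g",
              x$ratio, x$p_welch))
  if (is.finite(x$p_ks)) cat(sprintf(", KS D %.3g p %.4g", x$ks_D, x$p_ks))
  cat("\n")
  invisible(x)
}
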