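# Shared fixture builders; everything is generated in code at test time.

disc_mask <- function(dim_rc, centre_rc, radius) {
  rr <- outer(seq_len(dim_rc[1]) - centre_rc[1], rep(1, dim_rc[2]))
  cc <- outer(rep(1, dim_rc[1]), seq_len(dim_rc[2]) - centre_rc[2])
  sqrt(rr^2 + cc^2) <= radius
}

# brute-force Euclidean distance of every pixel to the nearest mask pixel
brute_distance_to_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      out[r, cc] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - cc)^2))
    }
  }
  out
}

# independent Welch two-tailed p-value from the closed form
welch_p_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# a tiny straight-line trajectory with given displacement (nm) and duration
line_track <- function(id, disp_nm, dur_s, n = 5L, t0 = 0) {
  t <- seq(t0, t0 + dur_s, length.out = n)
  Trajectory(id, t, seq(0, disp_nm, length.out = n), rep(0, n))
}
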