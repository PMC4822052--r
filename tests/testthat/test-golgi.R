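test_that("golgi integrity matches hand arithmetic and degenerate cases", {
  all_on <- BinaryMask(matrix(TRUE, 1, 2))
  m <- golgi_integrity(matrix(c(0, 2), 1, 2), all_on)
  expect_equal(m$integrity, 1.0)  # mean 1, population SD 1

  const <- golgi_integrity(matrix(7, 4, 4), BinaryMask(matrix(TRUE, 4, 4)))
  expect_equal(const$integrity, 0)

  expect_error(golgi_integrity(matrix(0, 2, 2), BinaryMask(matrix(TRUE, 2, 2))),
               "mean")
  # sample-SD variant for the two-pixel case: SD = sqrt(2)
  ms <- golgi_integrity(matrix(c(0, 2), 1, 2), all_on, sd_type = "sample")
  expect_equal(ms$integrity, sqrt(2))
})

test_that("integrity of pure shot noise is 1 independent of exposure", {
  reg <- BinaryMask(matrix(TRUE, 256, 256))
  for (lambda in c(25, 100, 400)) {
    f <- gen_poisson_field(lambda, c(256L, 256L), seed = lambda)
    m <- golgi_integrity(get_plane(f), reg)
    expect_lt(abs(m$integrity - 1), 0.05)
  }
})

test_that("integrity is a histogram statistic: invariant to pixel permutation", {
  withr::with_seed(42, {
    img <- matrix(rgamma(400, 2, 0.1), 20, 20)
    reg <- matrix(runif(400) < 0.6, 20, 20)
    perm <- img
    perm[reg] <- sample(img[reg])
  })
  a <- golgi_integrity(img, BinaryMask(reg))$integrity
  b <- golgi_integrity(perm, BinaryMask(reg))$integrity
  expect_equal(a, b)
})

test_that("nucleus segmentation recovers a bright disc inside the ROI", {
  img <- matrix(100, 80, 80)
  disc <- disc_mask(c(80, 80), c(40, 40), 15)
  img[disc] <- 1000
  roi <- BinaryMask(disc_mask(c(80, 80), c(40, 40), 30))
  nuc <- nucleus_mask(img, roi)
  # recovered mask matches the disc up to a 1-px boundary
  expect_true(all(mask_values(nuc)[disc_mask(c(80, 80), c(40, 40), 14)]))
  expect_false(any(mask_values(nuc)[!disc_mask(c(80, 80), c(40, 40), 16)]))

  expect_error(nucleus_mask(matrix(5, 10, 10), BinaryMask(matrix(TRUE, 10, 10))),
               "degenerate")

  # two discs in the ROI: only the larger survives
  img2 <- matrix(100, 80, 80)
  big <- disc_mask(c(80, 80), c(30, 30), 12)
  small <- disc_mask(c(80, 80), c(60, 60), 5)
  img2[big | small] <- 1000
  nuc2 <- mask_values(nucleus_mask(img2, BinaryMask(matrix(TRUE, 80, 80))))
  expect_true(any(nuc2 & big))
  expect_false(any(nuc2 & small))
})

test_that("extend_mask agrees with a brute-force distance transform", {
  single <- matrix(FALSE, 25, 25); single[13, 13] <- TRUE
  ext <- mask_values(extend_mask(BinaryMask(single), 10))
  expect_identical(ext, brute_distance_to_mask(single) <= 10)

  disc <- disc_mask(c(61, 61), c(31, 31), 20)
  ext2 <- mask_values(extend_mask(BinaryMask(disc), 10))
  expect_identical(ext2, brute_distance_to_mask(disc) <= 10)

  # identity at distance 0 and monotone in the distance
  expect_identical(mask_values(extend_mask(BinaryMask(disc), 0)), disc)
  for (d in c(2, 5, 9)) {
    a <- mask_values(extend_mask(BinaryMask(disc), d))
    b <- mask_values(extend_mask(BinaryMask(disc), d + 1))
    expect_true(all(b[a]))
  }
  expect_error(extend_mask(BinaryMask(matrix(FALSE, 3, 3)), 1), "empty")
})

test_that("compact scenes score higher integrity than dispersed ones", {
  roi <- BinaryMask(disc_mask(c(160, 160), c(80.5, 80.5), 35))
  n_pairs <- 20
  compact <- dispersed <- numeric(n_pairs)
  for (s in seq_len(n_pairs)) {
    mc <- golgi_dispersion(gen_golgi_scene("compact", seed = s)$stack, roi,
                           cell_id = sprintf("c%02d", s))
    md <- golgi_dispersion(gen_golgi_scene("dispersed", seed = s)$stack, roi,
                           cell_id = sprintf("d%02d", s))
    compact[s] <- mc$integrity
    dispersed[s] <- md$integrity
    expect_gt(mc$region_area_px, mc$nucleus_area_px)  # strict dilation
  }
  p <- t.test(compact, dispersed, alternative = "greater",
              var.equal = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("tip accumulation ratio is the background-subtracted ROI quotient", {
  img <- matrix(100, 20, 20)
  distal <- matrix(FALSE, 20, 20); distal[1:5, 1:5] <- TRUE
  proximal <- matrix(FALSE, 20, 20); proximal[15:20, 15:20] <- TRUE
  img[distal] <- 300

  # equal ROI statistics give a ratio of exactly 1
  img_eq <- matrix(100, 20, 20)
  expect_equal(tip_accumulation_ratio(img_eq, BinaryMask(distal),
                                      BinaryMask(proximal))$ratio, 1.0)
  expect_error(tip_accumulation_ratio(img, BinaryMask(proximal),
                                      BinaryMask(proximal)), "disjoint")

  r <- tip_accumulation_ratio(img, BinaryMask(distal), BinaryMask(proximal))
  expect_equal(r$ratio, 3.0)
  r2 <- tip_accumulation_ratio(img, BinaryMask(distal), BinaryMask(proximal),
                               background = 50)
  expect_equal(r2$ratio, 5.0)
  expect_error(tip_accumulation_ratio(img, BinaryMask(distal),
                                      BinaryMask(proximal), background = 100),
               "background")
})
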