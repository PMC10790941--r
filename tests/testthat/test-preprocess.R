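test_that("IAF-relative bands partition [iaf-6, iaf+2] into four exact 2 Hz bands", {
  b <- define_bands(10)$bands
  expect_equal(b$theta, c(4, 6))
  expect_equal(b$alpha_low1, c(6, 8))
  expect_equal(b$alpha_low2, c(8, 10))
  expect_equal(b$alpha_high, c(10, 12))
  expect_equal(define_bands(8)$bands$theta, c(2, 4))

  for (iaf in seq(8, 15, by = 0.5)) {
    bs <- define_bands(iaf)$bands
    edges <- unlist(bs)
    expect_equal(min(edges), iaf - 6)
    expect_equal(max(edges), iaf + 2)
    # contiguous: each band's upper edge is the next band's lower edge
    for (i in 1:3) expect_equal(bs[[i]][2], bs[[i + 1]][1])
    expect_true(all(vapply(bs, diff, numeric(1)) == 2))
  }
  expect_error(define_bands(7.9), "range")
  expect_error(define_bands(15.1), "range")
})

test_that("IAF estimation averages the two eyes-closed spectral peaks", {
  fs <- 256
  t <- (seq_len(40 * fs) - 1) / fs
  noise <- function(seed) {
    withr::with_seed(seed, matrix(rnorm(length(t) * 3, sd = 0.5), ncol = 3,
      dimnames = list(NULL, c("O1", "Oz", "O2"))
    ))
  }
  planted <- function(f, seed) noise(seed) + sin(2 * pi * f * t)

  expect_equal(estimate_iaf(planted(10, 1), planted(10, 2), fs = fs), 10)
  # drifting peak: 9.5 then 10.5 averages to 10
  expect_equal(estimate_iaf(planted(9.5, 1), planted(10.5, 2), fs = fs), 10)
  # flat spectrum: no-peak error
  expect_error(estimate_iaf(noise(1), noise(2), fs = fs), "no alpha peak")
  # too-short baseline rejected
  expect_error(
    estimate_iaf(planted(10, 1)[1:(20 * fs), ], planted(10, 2), fs = fs),
    "30 s"
  )
})

test_that("baseline z-normalization yields exact zero mean / unit sd on the baseline", {
  fs <- 256
  withr::with_seed(8, {
    p <- matrix(rexp(40 * fs * 3, rate = 0.2), ncol = 3)
  })
  idx <- seq_len(32 * fs)
  z <- baseline_z_normalize(p, idx, fs = fs)
  expect_lt(max(abs(colMeans(z[idx, ]))), 1e-9)
  expect_lt(max(abs(apply(z[idx, ], 2, sd) - 1)), 1e-9)
  # affine property: doubling the power after the baseline only shifts the
  # post-baseline z-values, the baseline stays standardized
  p2 <- p
  p2[-idx, ] <- p2[-idx, ] * 2
  z2 <- baseline_z_normalize(p2, idx, fs = fs)
  expect_equal(z2[idx, ], z[idx, ])
  expect_true(all(z2[-idx, ] >= z[-idx, ] - 1e-12))

  expect_error(
    baseline_z_normalize(matrix(1, 40 * fs, 2), idx, fs = fs),
    "degenerate"
  )
  expect_error(baseline_z_normalize(p, seq_len(10 * fs), fs = fs), "30 s")
})

test_that("session preprocessing produces finite normalized band power with remapped segments", {
  ps <- preprocess_session(tiny_session())
  expect_s3_class(ps, "power_session")
  expect_equal(ps$fs, 256)
  expect_named(ps$power, c("theta", "alpha_low1", "alpha_low2", "alpha_high"))
  expect_equal(ncol(ps$power$theta), 41)
  expect_true(all(vapply(ps$power, function(p) all(is.finite(p)), logical(1))))
  # IAF recovered near the generating value
  expect_lt(abs(ps$iaf - tiny_session()$iaf_true), 0.3)

  # segment remapping: floor starts / ceil ends at ratio 256/500, ordered
  s500 <- tiny_session()$segments
  s256 <- ps$segments
  r <- 256 / 500
  expect_equal(s256$start_sample, pmax(1, floor((s500$start_sample - 1) * r) + 1))
  expect_true(all(s256$end_sample >= ceiling(s500$end_sample * r) - 1))
  expect_true(all(diff(s256$start_sample) > 0))

  # the baseline segment of every band is standardized exactly
  eo <- s256[s256$segment_kind == "eyes_open", ][1, ]
  idx <- eo$start_sample:eo$end_sample
  for (band in names(ps$power)) {
    expect_lt(max(abs(colMeans(ps$power[[band]][idx, ]))), 1e-9)
    expect_lt(max(abs(apply(ps$power[[band]][idx, ], 2, sd) - 1)), 1e-9)
  }
})

test_that("fused preprocessing equals the composed standalone operations away from the padded edges", {
  session <- tiny_session()
  ps <- preprocess_session(session)
  r <- bandpass_1_50(resample_256(session))
  mont <- montage_subset()
  eo <- ps$segments[ps$segments$segment_kind == "eyes_open", ][1, ]
  for (band in c("theta", "alpha_high")) {
    praw <- filter_hilbert_power(
      r$signal[, mont$channel], ps$bands$bands[[band]], 256
    )
    pz <- baseline_z_normalize(praw, eo$start_sample:eo$end_sample)
    n <- nrow(pz)
    inner <- seq(10 * 256, n - 10 * 256)
    expect_lt(max(abs(pz[inner, ] - ps$power[[band]][inner, ])), 1e-3)
  }
})

test_that("responders show rising normalized upper-alpha power over occipital channels", {
  ps <- preprocess_session(tiny_session()) # plateau after block 1 of 2
  segs <- ps$segments[ps$segments$segment_kind == "navigation", ]
  blk_mean <- function(block) {
    rows <- unlist(lapply(which(segs$block_index == block), function(i) {
      segs$start_sample[i]:segs$end_sample[i]
    }))
    mean(ps$power$alpha_high[rows, c("O1", "Oz", "O2")])
  }
  expect_gt(blk_mean(2), blk_mean(1))
})

test_that("the artifact-removal hook enters the pipeline", {
  session <- tiny_session()
  seen <- FALSE
  hook <- function(x, fs) {
    seen <<- TRUE
    expect_equal(fs, 256)
    x
  }
  ps_hook <- preprocess_session(session, artifact_hook = hook)
  expect_true(seen)
  ps <- preprocess_session(session)
  # identity hook reproduces the default result (up to padding round trip)
  expect_equal(ps_hook$iaf, ps$iaf)
  n <- nrow(ps$power$alpha_high)
  inner <- seq(10 * 256, n - 10 * 256)
  expect_lt(
    max(abs(ps_hook$power$alpha_high[inner, ] - ps$power$alpha_high[inner, ])),
    1e-3
  )
})
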