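tone_epoch <- function(f, fs = 125, channel = 3, amp = 1) {
  x <- matrix(0, 16, fs)
  x[channel, ] <- amp * sin(2 * pi * f * (seq_len(fs) - 1) / fs)
  x
}

test_that("featurization has the (44, 16) shape with 1 Hz bins", {
  f <- featurize(matrix(stats::rnorm(16 * 125), 16), 125)
  expect_equal(dim(f), c(44, 16))
  expect_identical(attr(f, "bin_freqs"), 1:44)
  expect_true(all(f >= 0) && all(is.finite(f)))
  expect_equal(unname(featurize(matrix(0, 16, 125), 125)[, 1]), rep(0, 44))
  expect_error(featurize(matrix(0, 16, 250), 125), "1 s")
})

test_that("a pure integer-frequency tone peaks exactly at its own bin", {
  for (f0 in c(1, 7, 10, 25, 44)) {
    f <- featurize(tone_epoch(f0), 125)
    expect_equal(which.max(f[, 3]), f0)
    expect_gt(f[f0, 3], 100 * max(f[-f0, 3]))
  }
})

test_that("featurization is homogeneous: scaling the epoch scales the features", {
  e <- matrix(stats::rnorm(16 * 125), 16)
  expect_equal(unclass(featurize(3.5 * e, 125)),
               3.5 * unclass(featurize(e, 125)), tolerance = 1e-12)
})

test_that("band powers respect the half-open band convention and sum to total", {
  ep <- epoch_set(array(tone_epoch(10), c(1, 16, 125)), "rest", 125,
                  default_montage(),
                  data.frame(trial = 1L, session = 1L, phase = "rest",
                             onset_s = 0))
  bp <- band_power(ep)
  ch3 <- bp[bp$channel == "C3", ]
  expect_gt(ch3$power[ch3$band == "alpha"], 0.4)
  expect_lt(max(ch3$power[ch3$band != "alpha"]), 1e-20)
  # shared edges go to the upper band
  for (edge in list(c(4, "theta"), c(13, "beta"), c(30, "gamma"))) {
    epe <- epoch_set(array(tone_epoch(as.numeric(edge[1])), c(1, 16, 125)),
                     "rest", 125, default_montage(),
                     data.frame(trial = 1L, session = 1L, phase = "rest",
                                onset_s = 0))
    bpe <- band_power(epe)
    top <- bpe[bpe$channel == "C3", ]
    expect_equal(top$band[which.max(top$power)], edge[2])
  }
  # five band powers sum to the total 1-45 Hz power
  set.seed(3)
  e <- matrix(stats::rnorm(16 * 125), 16)
  eps <- epoch_set(array(e, c(1, 16, 125)), "rest", 125, default_montage(),
                   data.frame(trial = 1L, session = 1L, phase = "rest",
                              onset_s = 0))
  bpr <- band_power(eps)
  f <- featurize(e, 125)
  expect_equal(sum(bpr$power[bpr$channel == "C3"]), sum(f[, 3]^2),
               tolerance = 1e-9)
})

test_that("white-noise band power is proportional to bandwidth", {
  set.seed(10)
  n <- 200
  wins <- array(stats::rnorm(n * 16 * 125), c(n, 16, 125))
  ep <- epoch_set(wins, rep("rest", n), 125, default_montage(),
                  data.frame(trial = 1L, session = 1L, phase = "rest",
                             onset_s = seq_len(n)))
  bp <- band_power(ep)
  means <- tapply(bp$power, bp$band, mean)
  widths <- c(delta = 3, theta = 4, alpha = 5, beta = 17, gamma = 14)
  dens <- means[names(widths)] / widths
  expect_lt(diff(range(dens)) / mean(dens), 0.2)
})

test_that("rest alpha boost shows up as higher rest-condition alpha power", {
  batch <- generate_epoch_batch(subject_profile(effect_size = 0,
                                                rest_alpha_gain = 1.6,
                                                seed = 12),
                                n_per_class = 60)
  bp <- band_power(batch)
  a <- bp[bp$band == "alpha", ]
  expect_gt(mean(a$power[a$label == "rest"]),
            mean(a$power[a$label == "fist"]))
})

test_that("condition contrasts are antisymmetric and localized as constructed", {
  # a pure alpha contrast: no ERD, but a strong rest-time alpha boost
  batch <- generate_epoch_batch(subject_profile(effect_size = 0,
                                                rest_alpha_gain = 1.8,
                                                seed = 13),
                                n_per_class = 80)
  bp <- band_power(batch)
  eff <- condition_contrast(bp, "fist", "rest")
  rev <- condition_contrast(bp, "rest", "fist")
  expect_equal(eff$effect, -rev$effect, tolerance = 1e-12)
  # the strongest (most negative, fist - rest) effect sits in alpha
  c3 <- eff[eff$channel == "C3", ]
  expect_equal(c3$band[which.min(c3$effect)], "alpha")
  expect_lt(min(c3$effect), -1)
  # identical distributions give near-zero effects (iid windows)
  set.seed(14)
  n <- 800
  wins <- array(stats::rnorm(n * 16 * 125), c(n, 16, 125))
  null <- epoch_set(wins, rep(c("fist", "rest"), n / 2), 125,
                    default_montage(),
                    data.frame(trial = 1L, session = 1L, phase = "rest",
                               onset_s = seq_len(n)))
  eff0 <- condition_contrast(band_power(null), "fist", "rest")
  # 80 channel-band cells, each d ~ N(0, sqrt(4/n)): the largest stays small
  expect_lt(max(abs(eff0$effect)), 0.3)
  expect_error(condition_contrast(bp, "fist", "fist"), "differ")
  expect_error(condition_contrast(bp, "fist", "nap"), "not present")
})
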