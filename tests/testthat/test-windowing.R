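test_that("acceleration magnitude follows the root-sum-of-squares", {
  expect_equal(smv(3, 4, 0), 5)
  expect_equal(smv(0, 0, 0), 0)
  expect_equal(smv(1, 2, 2), 3)
  expect_equal(smv(c(3, 1), c(4, 2), c(0, 2)), c(5, 3)) # vectorised
})

test_that("peak locator matches the exhaustive-scan oracle", {
  acc <- rbind(c(0, 0, 1), c(0, 3, 4), c(0, 0, 1))
  sig <- toy_signal(cbind(acc, matrix(0, 3, 3)))
  expect_equal(peak_index(sig), 2L)

  expect_equal(peak_index(toy_signal(matrix(1, 5, 6))), 1L) # earliest tie

  withr::with_seed(11, {
    for (i in 1:50) {
      m <- matrix(rnorm(200 * 6), 200, 6)
      expect_equal(peak_index(toy_signal(m)), brute_force_peak(m))
    }
  })
  expect_error(peak_index(toy_signal(matrix(0, 0, 6))), "at least one")
})

test_that("peak location is invariant to positive rescaling of the acceleration", {
  withr::with_seed(12, {
    for (a in c(0.01, 3, 1000)) {
      m <- matrix(rnorm(300 * 6), 300, 6)
      m2 <- m
      m2[, 1:3] <- m2[, 1:3] * a
      expect_equal(peak_index(toy_signal(m)), peak_index(toy_signal(m2)))
    }
  })
})

test_that("peak-centred extraction spans [p - L/2, p + L/2) with boundary clamping", {
  cfg <- windowing_config() # L = 600
  mk <- function(T_, p) {
    m <- matrix(0, T_, 6)
    m[, 3] <- 1
    m[p, 1] <- 50
    toy_signal(m)
  }
  w <- extract_peak_window(mk(1200, 601), cfg, "FHF") # peak offset 600 0-based
  expect_equal(c(w$start, w$end), c(301L, 900L))
  expect_equal(nrow(w$samples[[1]]), 600L)

  w2 <- extract_peak_window(mk(1000, 11), cfg, "FHF") # near the left edge
  expect_equal(c(w2$start, w2$end), c(1L, 600L))
  w3 <- extract_peak_window(mk(1000, 995), cfg, "FHF") # near the right edge
  expect_equal(c(w3$start, w3$end), c(401L, 1000L))

  w4 <- extract_peak_window(mk(600, 300), cfg, "FHF") # exactly one window
  expect_equal(c(w4$start, w4$end), c(1L, 600L))
  expect_error(extract_peak_window(mk(599, 300), cfg, "FHF"), "shorter")
})

test_that("the extracted window always contains the peak sample", {
  cfg <- windowing_config(duration_s = 0.1, fs = 100) # L = 10
  withr::with_seed(13, {
    for (i in 1:100) {
      m <- matrix(rnorm(25 * 6), 25, 6)
      sig <- toy_signal(m)
      p <- peak_index(sig)
      w <- extract_peak_window(sig, cfg, "FHF")
      expect_true(w$start <= p && p <= w$end)
      expect_equal(w$end - w$start + 1L, 10L)
    }
  })
})

test_that("sliding windows are disjoint, ordered and drop the remainder", {
  cfg <- windowing_config()
  sig <- toy_signal(matrix(rnorm(1500 * 6), 1500, 6), "D01")
  w <- extract_sliding_windows(sig, cfg, "W")
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(1L, 601L))
  expect_equal(w$end, c(600L, 1200L))
  expect_equal(w$samples[[1]], sig$samples[1:600, ])
  expect_equal(w$samples[[2]], sig$samples[601:1200, ])

  expect_equal(nrow(extract_sliding_windows(
    toy_signal(matrix(0, 599, 6)), cfg, "W")), 0L)
  w3 <- extract_sliding_windows(toy_signal(matrix(0, 1200, 6)), cfg, "W")
  expect_equal(nrow(w3), 2L)
})

test_that("recordings dispatch to the scheme-appropriate windowing", {
  scheme <- label_scheme("ten_class")
  cfg <- windowing_config()
  long <- toy_signal(matrix(rnorm(20000 * 6, 0, 0.1), 20000, 6), "D01")
  w <- window_recording(long, scheme, cfg)
  expect_equal(nrow(w), 33L) # floor(20000 / 600)
  expect_true(all(w$label == "W"))

  fall <- toy_signal(matrix(rnorm(2400 * 6), 2400, 6), "F01")
  wf <- window_recording(fall, scheme, cfg)
  expect_equal(nrow(wf), 1L)
  expect_equal(wf$label, "FHF")

  excl <- toy_signal(matrix(0, 2400, 6), "D17")
  expect_message(we <- window_recording(excl, scheme, cfg), "excluded")
  expect_equal(nrow(we), 0L)
})
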