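test_that("ROI averaging uses retained member channels only", {
  hb <- makeChannelHb(list("31" = 0.2, "32" = 0.4))
  montage <- buildMontage()
  ## only channels 31, 32 retained in left_MC
  mask <- fullMask()
  mask[as.character(33:40)] <- FALSE
  roi <- roiAverage(hb, montage, mask)
  expect_true(all(abs(hbo(roi)["left_MC", ] - 0.3) < 1e-12))
  expect_equal(metadata(roi)$n_channels[["left_MC"]], 2L)
  ## one of the two rejected -> ROI equals the survivor
  mask["32"] <- FALSE
  roi2 <- roiAverage(hb, montage, mask)
  expect_true(all(hbo(roi2)["left_MC", ] == 0.2))
  ## all members rejected -> missing ROI, not an error
  mask[as.character(31:40)] <- FALSE
  roi3 <- roiAverage(hb, montage, mask)
  expect_true(all(is.na(hbo(roi3)["left_MC", ])))
  expect_equal(metadata(roi3)$n_channels[["left_MC"]], 0L)
  ## overlap channels contribute to both PFC ROIs
  hb4 <- makeChannelHb(list("9" = 1, "12" = 1))
  keepBoth <- setNames(rep(FALSE, 40), 1:40)
  keepBoth[c("9", "12")] <- TRUE
  roi4 <- roiAverage(hb4, montage, keepBoth)
  expect_true(all(hbo(roi4)["left_PFC", ] == 1))
  expect_true(all(hbo(roi4)["right_PFC", ] == 1))
})

test_that("baseline mean is the half-open pre-stimulus window average", {
  times <- (0:399) / FS
  y <- rep(0.5, 400)
  expect_equal(baselineMean(y, times, onset = 60), 0.5)
  ## linear ramp over the window samples averages to its midpoint
  idx <- which(times >= 30 & times < 60)
  y2 <- numeric(400)
  y2[idx] <- seq(0, 0.3, length.out = length(idx))
  expect_equal(baselineMean(y2, times, onset = 60), 0.15)
  expect_error(baselineMean(y, times, onset = 10), "precedes")
})

test_that("peak latency uses earliest-maximum ties and boundary flags", {
  times <- (0:399) / FS
  onset <- 60; dur <- 30
  win <- which(times >= onset & times <= onset + dur)
  ## two equal maxima at onset+4 s and onset+8 s -> earliest wins, tie flag
  y <- numeric(400)
  i4 <- which.min(abs(times - (onset + 4)))
  i8 <- which.min(abs(times - (onset + 8)))
  y[c(i4, i8)] <- 1
  pl <- peakLatency(y, times, onset, dur)
  expect_equal(pl$latency, times[i4] - onset)
  expect_true(pl$tie)
  expect_false(pl$boundary)
  ## monotonically rising -> boundary flag, latency = window length
  y2 <- seq_along(times) / 400
  pl2 <- peakLatency(y2, times, onset, dur)
  expect_true(pl2$boundary)
  expect_equal(pl2$latency, times[win[length(win)]] - onset)
  expect_error(peakLatency(y, times, onset = 500, dur), "empty")
})

test_that("delta-HbO and delta-HbO* are window statistics minus baseline", {
  times <- (0:999) / FS
  onset <- 60; dur <- 30; end <- onset + dur
  y <- rep(0.10, 1000)
  ipk <- which.min(abs(times - (onset + 6)))
  y[ipk] <- 0.45
  post <- which(times > end & times <= end + 15)
  y[post] <- 0.44
  base <- baselineMean(y, times, onset)
  expect_equal(base, 0.10)
  expect_equal(deltaHbo(y, times, onset, dur, base), 0.35)
  expect_equal(deltaHboStar(y, times, onset, dur, base), 0.34)
  ## flat series -> both zero
  flat <- rep(0.1, 1000)
  expect_equal(deltaHbo(flat, times, onset, dur, 0.1), 0)
  expect_equal(deltaHboStar(flat, times, onset, dur, 0.1), 0)
  ## instantaneous variant picks the last sample of the window
  y2 <- y; y2[post[length(post)]] <- 0.2
  expect_equal(deltaHboStar(y2, times, onset, dur, 0.1, method = "instant"),
               0.1)
  ## truncated post window errors
  expect_error(deltaHboStar(y, times, onset = 230, dur, 0.1), "truncated")
})

test_that("features are invariant to a constant shift of series + baseline", {
  set.seed(10)
  times <- (0:999) / FS
  y <- 0.2 * exp(-(times - 70)^2 / 40) + rnorm(1000, 0, 0.005)
  onset <- 60; dur <- 30
  base <- baselineMean(y, times, onset)
  for (c0 in c(-0.7, 1.3)) {
    ys <- y + c0
    bs <- baselineMean(ys, times, onset)
    expect_equal(bs, base + c0, tolerance = 1e-12)
    expect_equal(deltaHbo(ys, times, onset, dur, bs),
                 deltaHbo(y, times, onset, dur, base), tolerance = 1e-12)
    expect_equal(deltaHboStar(ys, times, onset, dur, bs),
                 deltaHboStar(y, times, onset, dur, base), tolerance = 1e-12)
    expect_equal(peakLatency(ys, times, onset, dur)$latency,
                 peakLatency(y, times, onset, dur)$latency)
  }
})

test_that("delta-HbO* of an ROI mean equals the mean of channel values", {
  ## linear feature: holds exactly for arbitrary (not just identical) channels
  set.seed(11)
  times <- (0:799) / FS
  m <- matrix(rnorm(2 * 800, 0, 0.02), 2, 800)
  onset <- 60; dur <- 30
  perCh <- apply(m, 1, function(y)
    deltaHboStar(y, times, onset, dur, baselineMean(y, times, onset)))
  avg <- colMeans(m)
  expect_equal(deltaHboStar(avg, times, onset, dur,
                            baselineMean(avg, times, onset)),
               mean(perCh), tolerance = 1e-12)
})

test_that("unimodal decaying responses satisfy delta-HbO >= delta-HbO*", {
  gs <- fixedGroupSpec(lat = 6, A = 0.5, d = 0.3)
  s <- simulateSubjectHbo(gs, seed = 3, kernel = "monotone")
  fe <- extractFeatures(s$hb, s$paradigm)
  expect_true(all(fe$delta_hbo >= fe$delta_hbo_star))
})

test_that("percent change reproduces the printed group summaries", {
  expect_equal(percentChange(0.25, 0.38)$rounded, 52.00)
  expect_equal(percentChange(0.39, 0.57)$rounded, 46.15)
  expect_equal(percentChange(0.44, 0.72)$rounded, 63.64)
  expect_equal(percentChange(0.15, 0.24)$rounded, 60.00)
  expect_equal(percentChange(0.26, 0.35)$rounded, 34.62)
  ## controls left-MC latency: printed as a 1.11% magnitude decrease
  expect_equal(percentChange(8.09, 8.00)$rounded, -1.11)
  expect_equal(percentChange(3, 3)$rounded, 0)
  expect_error(percentChange(0, 1), "zero")
  ## rounding is half away from zero
  expect_equal(roundHalfUp(2.345, 2), 2.35)
  expect_equal(roundHalfUp(-2.345, 2), -2.35)
  expect_equal(roundHalfUp(52.0049, 2), 52.00)
})
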