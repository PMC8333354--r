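test_that("coefficient of variation follows the n-1 convention", {
  rec <- makeRecording(list(rep(5, 10), c(8, 12, 8, 12, 8, 12, 8, 12, 8, 12)))
  cv <- channelCV(rec)
  expect_equal(cv$cv[cv$channel_id == 1], c(0, 0))
  ## series alternating 8/12: mean 10, sd 2.108 (n-1) -> CV 21.08%
  expect_equal(cv$cv[cv$channel_id == 2],
               rep(100 * sd(c(8, 12, 8, 12, 8, 12, 8, 12, 8, 12)) / 10, 2),
               tolerance = 1e-12)
  ## two-point series {8, 12}: sd = 2.828, CV = 28.28%
  rec2 <- makeRecording(list(c(8, 12)))
  expect_equal(channelCV(rec2)$cv, rep(100 * sqrt(8) / 10, 2),
               tolerance = 1e-12)
  expect_equal(round(channelCV(rec2)$cv[1], 2), 28.28)
})

test_that("zero-mean signals get an undefined CV and are rejected", {
  rec <- makeRecording(list(c(-1, 1, -1, 1), c(2, 2, 2, 2)))
  cv <- channelCV(rec)
  expect_true(all(is.na(cv$cv[cv$channel_id == 1])))
  rj <- rejectChannels(cv)
  expect_true(rj$rejected[rj$channel_id == 1])
  expect_match(rj$reason[rj$channel_id == 1], "undefined")
  expect_false(rj$rejected[rj$channel_id == 2])
})

test_that("rejection is strict at the 7.5% threshold on either wavelength", {
  qc <- data.frame(channel_id = rep(1:3, 2),
                   wavelength_nm = rep(c(760, 850), each = 3),
                   cv = c(8.0, 7.5, 2.0,   3.0, 7.5, 2.0))
  rj <- rejectChannels(qc)
  expect_true(rj$rejected[rj$channel_id == 1])    # 8.0 / 3.0 -> rejected
  expect_false(rj$rejected[rj$channel_id == 2])   # exactly 7.5 -> retained
  expect_false(rj$rejected[rj$channel_id == 3])   # 2.0 / 2.0 -> retained
  expect_error(rejectChannels(qc, threshold = 0), "> 0")
})

test_that("raising the CV threshold never rejects more channels", {
  set.seed(14)
  for (rep in 1:20) {
    qc <- data.frame(channel_id = rep(1:12, 2),
                     wavelength_nm = rep(c(760, 850), each = 12),
                     cv = rexp(24, 1 / 6))
    thr <- sort(runif(2, 1, 15))
    lo <- rejectChannels(qc, thr[1])$rejected
    hi <- rejectChannels(qc, thr[2])$rejected
    expect_true(all(which(hi) %in% which(lo)))
  }
})

test_that("optical density conversion handles constants, spikes and errors", {
  rec <- makeRecording(list(rep(2, 8)))
  od <- toOpticalDensity(rec)
  expect_true(all(od[["760"]] == 0))
  ## one sample at mean/10 -> OD = 1 there
  x <- rep(1, 101); x[51] <- mean(x) / 10   # mean barely changes; use reference
  rec2 <- makeRecording(list(x))
  od2 <- toOpticalDensity(rec2, reference = mean(x))
  expect_equal(unname(od2[["760"]][1, 51]), -log10(x[51] / mean(x)),
               tolerance = 1e-12)
  rec3 <- makeRecording(list(c(1, -0.5, 1)))
  expect_error(toOpticalDensity(rec3), "non-positive intensity")
})

test_that("band-pass keeps passband sinusoids and removes stopband and DC", {
  n <- round(300 * FS)
  t <- (seq_len(n) - 1) / FS
  inband <- sin(2 * pi * 0.05 * t)
  stop1 <- sin(2 * pi * 1.0 * t)
  expect_gt(fftAmplitude(bandpassFilter(inband)), 0.9)
  expect_lt(fftAmplitude(bandpassFilter(stop1)), 0.1)
  dc <- rep(3, n)
  expect_lt(abs(mean(bandpassFilter(dc))), 1e-6 * 3)
  expect_error(bandpassFilter(inband, low = 0.1, high = 2.5), "Nyquist")
  expect_error(bandpassFilter(inband, low = 0.3, high = 0.2), "Nyquist|band")
})

test_that("mbll solves the per-sample system and is linear", {
  ## identity system: extinction = I, separation 1, DPF (1,1)
  idE <- diag(2); dimnames(idE) <- list(c("760", "850"), c("HbO", "HbR"))
  od <- list("760" = matrix(0.3, 1, 4, dimnames = list("1", NULL)),
             "850" = matrix(0.1, 1, 4, dimnames = list("1", NULL)))
  hb <- mbll(od, separation = 1, dpf = c("760" = 1, "850" = 1),
             extinction = idE)
  expect_true(all(hbo(hb) == 0.3))
  expect_true(all(hbr(hb) == 0.1))
  ## zero OD -> zero concentrations
  od0 <- lapply(od, function(m) m * 0)
  hb0 <- mbll(od0)
  expect_true(all(hbo(hb0) == 0) && all(hbr(hb0) == 0))
  ## linearity: mbll(a od1 + b od2) = a mbll(od1) + b mbll(od2)
  set.seed(4)
  mk <- function() lapply(od, function(m)
    matrix(rnorm(length(m), 0, 0.01), nrow(m), ncol(m),
           dimnames = dimnames(m)))
  o1 <- mk(); o2 <- mk()
  lhs <- mbll(Map(function(a, b) 2 * a - 0.5 * b, o1, o2))
  rhs <- 2 * hbo(mbll(o1)) - 0.5 * hbo(mbll(o2))
  expect_equal(hbo(lhs), rhs, tolerance = 1e-12)
  ## singular extinction / missing wavelength errors
  bad <- matrix(1, 2, 2, dimnames = dimnames(idE))
  expect_error(mbll(od, extinction = bad), "singular")
  expect_error(mbll(od["760"]), "both wavelengths")
})

test_that("filtering and MBLL commute (both linear)", {
  set.seed(6)
  n <- 600
  od <- list("760" = matrix(rnorm(2 * n, 0, 0.01), 2, n,
                            dimnames = list(1:2, NULL)),
             "850" = matrix(rnorm(2 * n, 0, 0.01), 2, n,
                            dimnames = list(1:2, NULL)))
  filterFirst <- mbll(lapply(od, bandpassFilter))
  mbllFirst <- bandpassFilter(hbo(mbll(od)))
  expect_lt(max(abs(hbo(filterFirst) - mbllFirst)), 1e-8)
})

test_that("preprocessRecording aborts when QC rejects every channel", {
  set.seed(8)
  noiseM <- matrix(rnorm(40 * 200, 0, 0.005), 40, 200)
  hb <- HbSeries(noiseM, -noiseM / 3, level = "channel", rowIds = 1:40)
  rec <- inverseMbllEncode(hb)
  expect_error(preprocessRecording(rec, cvThreshold = 1e-5),
               "rejected all channels")
  ok <- preprocessRecording(rec)
  expect_s4_class(ok$hb, "HbSeries")
  expect_true(all(ok$mask))
})
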