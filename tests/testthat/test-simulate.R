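test_that("noiseless responses reproduce the drawn targets downstream", {
  gs <- defaultGroupSpecs()
  s <- simulateSubjectHbo(gs$fibromyalgia, seed = 42)
  fe <- extractFeatures(s$hb, s$paradigm)
  m <- merge(fe, s$targets, by = c("roi", "temperature"),
             suffixes = c("_meas", "_true"))
  expect_equal(nrow(m), 8)
  ## latency to within one sample period; amplitudes essentially exact
  expect_lt(max(abs(m$peak_latency_meas - m$peak_latency_true)), 1 / 3.91)
  expect_lt(max(abs(m$delta_hbo_meas - m$delta_hbo_true)), 1e-6)
  expect_lt(max(abs(m$delta_hbo_star_meas - m$delta_hbo_star_true)), 1e-6)
})

test_that("identical seeds give identical subjects and cohorts", {
  gs <- defaultGroupSpecs()
  a <- simulateSubjectHbo(gs$control, seed = 7)
  b <- simulateSubjectHbo(gs$control, seed = 7)
  expect_identical(hbo(a$hb), hbo(b$hb))
  expect_identical(a$scores, b$scores)

  small <- lapply(gs, function(g) { g$n <- 2L; g })
  c1 <- generateCohort(small, seed = 11, band = NULL)
  c2 <- generateCohort(small, seed = 11, band = NULL)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(intensity(c1$recordings[[1]], "760"),
                   intensity(c2$recordings[[1]], "760"))
})

test_that("monotone-decay kernel honours targets and flags infeasible ones", {
  spec <- fixedGroupSpec(lat = 6, A = 0.4, d = 0.2)
  s <- simulateSubjectHbo(spec, seed = 1, kernel = "monotone")
  fe <- extractFeatures(s$hb, s$paradigm)
  expect_lt(max(abs(fe$delta_hbo_star - 0.2)), 1e-6)
  expect_lt(max(abs(fe$delta_hbo - 0.4)), 1e-6)

  bad <- fixedGroupSpec(lat = 6, A = 0.3, d = 0.45)
  expect_error(simulateSubjectHbo(bad, seed = 1, kernel = "monotone"),
               "infeasible response shape")
})

test_that("drawn feature targets recover the configured group parameters", {
  gs <- defaultGroupSpecs()
  dr <- drawFeatureTargets(gs$fibromyalgia, n = 200, seed = 3)
  left5 <- dr$targets[dr$targets$roi == "left_PFC" &
                      dr$targets$temperature == 5, ]
  ## sample mean of left-PFC delta-HbO* at 5 degC within 3 SE of 0.34
  se <- sd(left5$delta_hbo_star) / sqrt(nrow(left5))
  expect_lt(abs(mean(left5$delta_hbo_star) - 0.34), 3 * se)

  ## every delta-HbO* cell is unclamped: means match the configuration
  pr <- gs$fibromyalgia$params
  for (k in seq_len(nrow(pr))) {
    cell <- dr$targets[dr$targets$roi == pr$roi[k] &
                       dr$targets$temperature == pr$temperature[k], ]
    se_k <- sd(cell$delta_hbo_star) / sqrt(nrow(cell))
    expect_lt(abs(mean(cell$delta_hbo_star) - pr$dhbostar_mean[k]),
              3.5 * se_k)
  }
})

test_that("clinical scores carry the configured rank correlation", {
  gs <- defaultGroupSpecs()
  dr <- drawFeatureTargets(gs$fibromyalgia, n = 800, seed = 5)
  left5 <- dr$targets[dr$targets$roi == "left_PFC" &
                      dr$targets$temperature == 5, ]
  rho_csi <- cor(left5$delta_hbo_star, dr$scores$csi, method = "spearman")
  rho_dis <- cor(left5$delta_hbo_star, dr$scores$disability,
                 method = "spearman")
  expect_lt(abs(rho_csi - 0.60), 0.08)
  expect_lt(abs(rho_dis - 0.40), 0.10)
  expect_lt(abs(cor(dr$scores$csi, dr$scores$disability,
                    method = "spearman") - 0.64), 0.08)
})

test_that("optical encoding inverts exactly and scales with the DPF", {
  set.seed(9)
  n <- 120
  hboM <- matrix(rnorm(40 * n, 0, 0.1), 40, n, dimnames = list(1:40, NULL))
  hbrM <- matrix(rnorm(40 * n, 0, 0.05), 40, n, dimnames = list(1:40, NULL))
  hb <- HbSeries(hboM, hbrM, level = "channel", rowIds = 1:40)
  rec <- inverseMbllEncode(hb)
  ## zero concentrations give constant intensity
  hb0 <- HbSeries(hboM * 0, hbrM * 0, level = "channel", rowIds = 1:40)
  rec0 <- inverseMbllEncode(hb0)
  expect_true(all(intensity(rec0, "760") == 1))
  ## round trip via a known reference recovers concentrations to < 1e-9
  back <- mbll(toOpticalDensity(rec, reference = 1))
  expect_lt(max(abs(hbo(back) - hboM)), 1e-9)
  expect_lt(max(abs(hbr(back) - hbrM)), 1e-9)
  ## optical density scales linearly with the DPF per wavelength
  recU <- inverseMbllEncode(hb, dpf = c("760" = 1, "850" = 1))
  odU <- toOpticalDensity(recU, reference = 1)
  od <- toOpticalDensity(rec, reference = 1)
  expect_equal(od[["760"]], odU[["760"]] * 7.25, tolerance = 1e-10)
  expect_equal(od[["850"]], odU[["850"]] * 6.38, tolerance = 1e-10)
  ## singular extinction is rejected
  bad <- matrix(1, 2, 2, dimnames = list(c("760", "850"), c("HbO", "HbR")))
  expect_error(inverseMbllEncode(hb, extinction = bad), "singular")
})

test_that("artifact injection is targeted, seeded and inert at rate 0", {
  gs <- defaultGroupSpecs()
  s <- simulateSubjectHbo(gs$control, seed = 21)
  chHb <- makeChannelHb(list(), n = 400)
  set.seed(2); noise <- matrix(rnorm(40 * 400, 0, 0.01), 40, 400)
  hb <- HbSeries(noise, -noise / 3, level = "channel", rowIds = 1:40)
  rec <- inverseMbllEncode(hb)

  none <- injectArtifacts(rec, silentNoiseSpec(), seed = 1)
  expect_identical(intensity(none$recording, "760"), intensity(rec, "760"))
  expect_equal(nrow(none$log), 0)

  art <- injectArtifacts(rec, noiseSpec(), seed = 1, targetCv = 10,
                         channels = 5)
  cv <- channelCV(art$recording)
  cv5 <- cv$cv[cv$channel_id == 5]
  expect_true(all(cv5 > 7.5))
  expect_equal(art$log$channel_id, 5L)
  ## rejected downstream
  rj <- rejectChannels(cv)
  expect_true(rj$rejected[rj$channel_id == 5])

  a1 <- injectArtifacts(rec, noiseSpec(artifact_rate = 0.5), seed = 33)
  a2 <- injectArtifacts(rec, noiseSpec(artifact_rate = 0.5), seed = 33)
  expect_identical(a1$log, a2$log)
  expect_identical(intensity(a1$recording, "850"),
                   intensity(a2$recording, "850"))
})

test_that("default cohort matches the study layout and tiny cohorts run", {
  gs <- defaultGroupSpecs()
  expect_equal(sum(vapply(gs, function(g) g$n, integer(1))), 41L)
  small <- lapply(gs, function(g) { g$n <- 1L; g })
  co <- generateCohort(small, seed = 2, band = NULL)
  expect_equal(nrow(co$metadata), 2)
  expect_error(generateCohort(list(), seed = 1), "at least one group")
  ## end-to-end on the tiny cohort
  cfg <- pipelineConfig(n_fibromyalgia = 1, n_control = 1)
  res <- suppressWarnings(runPipeline(cfg, cohort = co))
  expect_equal(length(unique(res$features$subject)), 2)
})
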