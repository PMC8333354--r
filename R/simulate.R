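## Synthetic cohort generation: seeded draws of per-subject response
## parameters, clinical scores through a Gaussian copula, noiseless response
## synthesis (optionally pre-compensated for the analysis band-pass), channel
## noise, optical encoding and motion artifacts.

.spearmanToPearson <- function(rho) 2 * sin(pi * rho / 6)

## Draw one subject's immersion durations, feature targets and clinical
## scores from the current RNG stream.
.drawSubject <- function(spec) {
  dr <- spec$durationRange
  durations <- runif(2, dr[1], dr[2])
  pr <- spec$params
  nr <- nrow(pr)
  rho <- spec$amplitudeCorr
  z <- matrix(rnorm(3 * nr), nr, 3)
  uA <- z[, 2]
  uD <- rho * z[, 2] + sqrt(1 - rho^2) * z[, 3]
  dur <- ifelse(pr$temperature == 25, durations[1], durations[2])
  tp <- pmin(pmax(pr$latency_mean + pr$latency_sd * z[, 1], 0.5),
             dur - 0.3)
  ## a response needs a measurable positive peak for its latency to be
  ## defined, and the post-offset target must stay comparable to the peak
  ## or the band-pass smears the offset response above the in-stimulus
  ## maximum (positive side) or rings above it (negative side)
  A <- pmax(pr$dhbo_mean + pr$dhbo_sd * uA, 0.05)
  d <- pr$dhbostar_mean + pr$dhbostar_sd * uD
  d <- pmax(pmin(d, 2 * A), -3 * A)
  targets <- data.frame(roi = pr$roi, temperature = pr$temperature,
                        peak_latency = tp, delta_hbo = A, delta_hbo_star = d)
  iLeft <- which(pr$roi == "left_PFC" & pr$temperature == 5)
  scores <- NULL
  if (!is.null(spec$clinical)) {
    cl <- spec$clinical
    rv <- .spearmanToPearson(unname(cl$rho[cl$scores$score]))
    Rss <- matrix(.spearmanToPearson(cl$interRho), 2, 2); diag(Rss) <- 1
    condCov <- Rss - tcrossprod(rv)
    L <- chol(condCov)
    zS <- rv * uD[iLeft] + as.vector(crossprod(L, rnorm(2)))
    raw <- cl$scores$mean + cl$scores$sd * zS
    scores <- setNames(round(pmin(pmax(raw, cl$scores$min), cl$scores$max)),
                       cl$scores$score)
  }
  list(durations = durations, targets = targets, scores = scores,
       latentLeft = uD[iLeft])
}

#' Draw feature targets and clinical scores without waveform synthesis
#'
#' Fast parameter-level sampling from a \code{\link{groupSpec}}: per subject,
#' the immersion durations, the per-ROI x temperature feature targets (peak
#' latency, delta-HbO, delta-HbO*) and the copula-linked clinical scores.
#' Useful for Monte-Carlo studies of the statistical layer that do not need
#' optical waveforms.
#'
#' @param spec a \code{GroupSpec}.
#' @param n number of subjects (default \code{spec$n}).
#' @param seed optional integer seed.
#' @return list with \code{targets} (data.frame with subject column) and
#'   \code{scores} (data.frame subject x score).
#' @export
drawFeatureTargets <- function(spec, n = spec$n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- list(); sc <- list()
  for (i in seq_len(n)) {
    s <- .drawSubject(spec)
    tg[[i]] <- cbind(subject = i, s$targets)
    if (!is.null(s$scores))
      sc[[i]] <- data.frame(subject = i, t(s$scores))
  }
  list(targets = do.call(rbind, tg),
       scores = if (length(sc)) do.call(rbind, sc) else NULL)
}

.realizeParadigm <- function(paradigm, durations) {
  makeParadigm(restDuration = paradigm@restDuration,
               baselineWindow = paradigm@baselineWindow,
               durations = durations,
               interStimulusRest = paradigm@interStimulusRest,
               postWindow = paradigm@postWindow)
}

## Returns the ROI x time response matrix plus the per-ROI x temperature
## response parameters actually realized in the emitted series (these equal
## the drawn targets except for the rare draws the band calibration cannot
## reach exactly).
.roiSeriesMatrix <- function(draw, paradigm, samplingRate, band, kernel,
                             times) {
  ev <- paradigmEvents(paradigm)
  pw <- paradigm@postWindow
  bw <- paradigm@baselineWindow
  onset0 <- primaryOnset(paradigm)
  targets <- draw$targets
  rois <- unique(targets$roi)
  out <- matrix(0, length(rois), length(times),
                dimnames = list(rois, NULL))
  for (r in rois) {
    rows <- vapply(seq_len(nrow(ev)), function(k)
      which(targets$roi == r &
            targets$temperature == ev$temperature_C[k]), integer(1))
    evs <- lapply(seq_len(nrow(ev)), function(k) {
      row <- targets[rows[k], ]
      list(onset = ev$onset[k], duration = ev$duration[k],
           tp = row$peak_latency, A = row$delta_hbo,
           d = row$delta_hbo_star)
    })
    if (is.null(band)) {
      out[r, ] <- .responseSeries(times, evs, samplingRate, pw, kernel)
    } else {
      cal <- .calibrateSeries(times, evs, samplingRate, pw, bw, onset0,
                              band, kernel = kernel)
      out[r, ] <- cal$series
      targets$peak_latency[rows] <- cal$achieved[, "tp"]
      targets$delta_hbo[rows] <- cal$achieved[, "A"]
      targets$delta_hbo_star[rows] <- cal$achieved[, "d"]
    }
  }
  list(series = out, targets = targets)
}

#' Simulate one subject's ROI-level hemoglobin responses
#'
#' Draws response parameters and clinical scores for one subject from a
#' \code{\link{groupSpec}} and synthesises the noiseless ROI-level HbO
#' series (HbR is modelled as -HbO/3).  With all noise amplitudes zero the
#' features extracted from the returned series equal the drawn targets: the
#' peak latency to within one sample period and the two amplitude measures
#' essentially exactly.  When \code{band} is given, the kernel parameters
#' are instead pre-compensated so the targets are met \emph{after} zero-phase
#' band-pass filtering with that band (used by \code{\link{generateCohort}}
#' so the full pipeline recovers the drawn parameters).
#'
#' @param spec a \code{GroupSpec}.
#' @param paradigm a \linkS4class{ParadigmTimeline}; immersion durations are
#'   redrawn from \code{spec$durationRange}.
#' @param noise a \code{NoiseSpec}; its oscillatory/white/drift components
#'   are added to the ROI series (defaults to silence).
#' @param seed optional integer seed.
#' @param band NULL (default) or numeric(2) analysis band in Hz for
#'   filter pre-compensation.
#' @param kernel \code{"offset"} (stimulus transient + post-offset response,
#'   default) or \code{"monotone"} (single transient with exponential
#'   return-to-baseline; errors when the requested delta-HbO* is infeasible).
#' @param samplingRate Hz.
#' @return list: \code{hb} (ROI-level \linkS4class{HbSeries}),
#'   \code{paradigm} (realized timing), \code{targets} (drawn parameters),
#'   \code{scores} (named clinical scores), \code{durations}.
#' @export
simulateSubjectHbo <- function(spec, paradigm = makeParadigm(),
                               noise = silentNoiseSpec(), seed = NULL,
                               band = NULL, kernel = c("offset", "monotone"),
                               samplingRate = 3.91) {
  kernel <- match.arg(kernel)
  if (!is.null(seed)) set.seed(seed)
  draw <- .drawSubject(spec)
  real <- .realizeParadigm(paradigm, draw$durations)
  n <- ceiling((paradigmSpan(real) + 15) * samplingRate)
  times <- (seq_len(n) - 1) / samplingRate
  rs <- .roiSeriesMatrix(draw, real, samplingRate, band, kernel, times)
  m <- rs$series
  for (r in rownames(m)) m[r, ] <- m[r, ] + .channelNoise(times, noise)
  hb <- HbSeries(m, -m / 3, samplingRate = samplingRate, times = times,
                 level = "roi",
                 provenance = list(group = spec$group, kernel = kernel,
                                   calibrated_band_Hz = band))
  list(hb = hb, paradigm = real, targets = rs$targets,
       scores = draw$scores, durations = draw$durations)
}

## additive physiological noise for one channel (concentration units)
.channelNoise <- function(times, noise) {
  y <- numeric(length(times))
  for (cp in list(noise$cardiac, noise$respiratory, noise$mayer)) {
    jit <- 1 + 0.05 * rnorm(1)
    ph <- runif(1, 0, 2 * pi)
    if (cp$amp > 0) y <- y + cp$amp * sin(2 * pi * cp$freq * jit * times + ph)
    else { invisible(ph) }  # keep the draw count fixed across specs
  }
  slope <- rnorm(1, 0, noise$drift_sd)
  y <- y + slope * (times - mean(times))
  if (noise$white_sd > 0) y <- y + rnorm(length(times), 0, noise$white_sd)
  else invisible(rnorm(length(times), 0, 1) * 0)
  y
}

#' Encode hemoglobin series into raw optical intensities
#'
#' The exact inverse of the modified Beer-Lambert conversion, used for
#' synthesis: \eqn{\Delta OD_\lambda = L \cdot DPF_\lambda (\epsilon_{\lambda,HbO}
#' \Delta HbO + \epsilon_{\lambda,HbR} \Delta HbR)} and
#' \eqn{I_\lambda(t) = I_0 10^{-\Delta OD_\lambda(t)}}.  A round trip through
#' \code{\link{mbll}} recovers the concentrations to numerical precision.
#'
#' @param hb channel-level \linkS4class{HbSeries}.
#' @param montage a \linkS4class{Montage} (supplies the separation).
#' @param dpf,extinction see \code{\link{mbll}}; extinction must be
#'   nonsingular.
#' @param i0 reference intensity.
#' @param subjectId subject identifier for the recording.
#' @return a \linkS4class{NirsRecording}.
#' @export
inverseMbllEncode <- function(hb, montage = buildMontage(),
                              dpf = dpfDefaults(),
                              extinction = extinctionDefaults(), i0 = 1,
                              subjectId = "S1") {
  if (abs(det(extinction)) < .Machine$double.eps * 100 * max(abs(extinction))^2)
    stop("extinction matrix is singular")
  L <- montage@separation
  hboM <- hbo(hb); hbrM <- hbr(hb)
  od760 <- L * dpf[["760"]] *
    (extinction["760", "HbO"] * hboM + extinction["760", "HbR"] * hbrM)
  od850 <- L * dpf[["850"]] *
    (extinction["850", "HbO"] * hboM + extinction["850", "HbR"] * hbrM)
  NirsRecording(list("760" = i0 * 10^(-od760), "850" = i0 * 10^(-od850)),
                samplingRate = samplingRate(hb), montage = montage,
                subjectId = subjectId, times = sampleTimes(hb))
}

#' Inject motion artifacts into a recording
#'
#' Each channel is corrupted with probability \code{noise$artifact_rate} by
#' a multiplicative gain ramp applied to both wavelengths, with the ramp
#' amplitude solved so the channel's intensity CV reaches the target
#' (\code{targetCv}, or \code{noise$artifact_cv} jittered by +-10 percent).
#' With rate 0 the recording is returned unchanged.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @param noise a \code{NoiseSpec}.
#' @param seed optional integer seed (otherwise the current RNG stream).
#' @param targetCv optional fixed CV target in percent.
#' @param channels optional explicit channel ids to corrupt (overrides the
#'   random selection).
#' @return list: \code{recording} (corrupted copy), \code{log} (data.frame
#'   channel_id, target_cv).
#' @export
injectArtifacts <- function(rec, noise, seed = NULL, targetCv = NULL,
                            channels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m760 <- intensity(rec, "760"); m850 <- intensity(rec, "850")
  nch <- nrow(m760)
  if (is.null(channels)) {
    hit <- which(runif(nch) < noise$artifact_rate)
  } else {
    hit <- match(as.character(channels), rownames(m760))
    if (anyNA(hit)) stop("unknown channel id in 'channels'")
  }
  logRows <- list()
  if (length(hit)) {
    u <- seq(-0.5, 0.5, length.out = ncol(m760))
    for (i in hit) {
      tcv <- if (is.null(targetCv)) noise$artifact_cv * runif(1, 0.9, 1.1)
             else targetCv
      cvOf <- function(a) {
        v <- m760[i, ] * (1 + a * u)
        100 * sd(v) / mean(v)
      }
      if (cvOf(0) < tcv) {
        a <- uniroot(function(a) cvOf(a) - tcv, c(0, 6), tol = 1e-10)$root
        g <- 1 + a * u
        m760[i, ] <- m760[i, ] * g
        m850[i, ] <- m850[i, ] * g
      }
      logRows[[length(logRows) + 1L]] <-
        data.frame(channel_id = as.integer(rownames(m760)[i]),
                   target_cv = tcv)
    }
  }
  out <- NirsRecording(list("760" = m760, "850" = m850),
                       samplingRate = samplingRate(rec),
                       montage = metadata(rec)$montage,
                       subjectId = subjectId(rec),
                       times = sampleTimes(rec))
  list(recording = out,
       log = if (length(logRows)) do.call(rbind, logRows)
             else data.frame(channel_id = integer(), target_cv = numeric()))
}

## Features of the noiseless ROI-averaged series, measured exactly as the
## feature extractor does (after the analysis band-pass when one is set).
.noiselessRoiTruth <- function(chM, targets, montage, paradigm, fs, band,
                               times) {
  ev <- paradigmEvents(paradigm)
  evs <- lapply(seq_len(nrow(ev)), function(k)
    list(onset = ev$onset[k], duration = ev$duration[k]))
  for (r in unique(targets$roi)) {
    y <- colMeans(chM[as.character(montage@roiMap[[r]]), , drop = FALSE])
    if (!is.null(band)) y <- bandpassFilter(y, band[1], band[2], fs)
    f <- .measureEvents(y, times, evs, primaryOnset(paradigm),
                        paradigm@baselineWindow, paradigm@postWindow)
    for (k in seq_len(nrow(ev))) {
      i <- which(targets$roi == r &
                 targets$temperature == ev$temperature_C[k])
      targets$peak_latency[i] <- f[k, "tp"]
      targets$delta_hbo[i] <- f[k, "A"]
      targets$delta_hbo_star[i] <- f[k, "d"]
    }
  }
  targets
}

## channel-level series from ROI responses: a channel carries the mean of
## the ROIs it belongs to (channels 9 and 12 mix both PFC responses)
.channelMatrixFromRoi <- function(roiM, montage) {
  chans <- montage@channels$channel_id
  out <- matrix(0, length(chans), ncol(roiM),
                dimnames = list(chans, NULL))
  for (ch in chans) {
    rois <- names(montage@roiMap)[vapply(montage@roiMap,
                                         function(x) ch %in% x, logical(1))]
    out[as.character(ch), ] <- colMeans(roiM[rois, , drop = FALSE])
  }
  out
}

## Generate one subject end to end (draws from the current RNG stream).
.generateSubjectRecording <- function(spec, sid, paradigm, noise, band,
                                      montage, kernel, samplingRate = 3.91) {
  draw <- .drawSubject(spec)
  real <- .realizeParadigm(paradigm, draw$durations)
  n <- ceiling((paradigmSpan(real) + 15) * samplingRate)
  times <- (seq_len(n) - 1) / samplingRate
  rs <- .roiSeriesMatrix(draw, real, samplingRate, band, kernel, times)
  chM <- .channelMatrixFromRoi(rs$series, montage)
  ## recorded truth = what the analysis chain extracts from the noiseless
  ## ROI averages (overlap channels 9/12 blend both PFC responses, so the
  ## ROI-average response differs slightly from the pure ROI kernel)
  draw$targets <- .noiselessRoiTruth(chM, rs$targets, montage, real,
                                     samplingRate, band, times)
  hbrM <- -chM / 3
  for (i in seq_len(nrow(chM))) {
    chM[i, ] <- chM[i, ] + .channelNoise(times, noise)
    hbrM[i, ] <- hbrM[i, ] + rnorm(length(times), 0, noise$white_sd / 3)
  }
  hb <- HbSeries(chM, hbrM, samplingRate = samplingRate, times = times,
                 level = "channel", rowIds = rownames(chM))
  rec <- inverseMbllEncode(hb, montage = montage, subjectId = sid)
  art <- injectArtifacts(rec, noise)
  meta <- data.frame(subject = sid, group = spec$group,
                     duration_primary_s = draw$durations[1],
                     duration_secondary_s = draw$durations[2])
  if (!is.null(draw$scores))
    meta <- cbind(meta, as.data.frame(t(draw$scores)))
  truth <- cbind(subject = sid, group = spec$group, draw$targets)
  list(recording = art$recording, paradigm = real, metadata = meta,
       truth = truth, artifact_log = art$log)
}

#' Generate a full synthetic cohort
#'
#' Seeded end-to-end generation of one recording, realized paradigm and
#' metadata row per subject across the given groups.  Responses are
#' pre-compensated for the analysis band-pass (\code{band}) so that the
#' standard preprocessing pipeline recovers the drawn feature targets; pass
#' \code{band = NULL} for uncompensated kernels.
#'
#' @param groups list of \code{GroupSpec}s (default \code{defaultGroupSpecs()},
#'   fibromyalgia n = 22 plus controls n = 19, 41 subjects).
#' @param paradigm a \linkS4class{ParadigmTimeline} template.
#' @param noise a \code{NoiseSpec}.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param band analysis band (Hz) for kernel pre-compensation.
#' @param montage a \linkS4class{Montage}.
#' @param kernel response kernel, see \code{\link{simulateSubjectHbo}}.
#' @return list: \code{recordings} (named list of
#'   \linkS4class{NirsRecording}), \code{paradigms} (realized timelines),
#'   \code{metadata} (one row per subject), \code{truth} (drawn per-subject
#'   feature targets), \code{artifact_log}.
#' @export
generateCohort <- function(groups = defaultGroupSpecs(),
                           paradigm = makeParadigm(), noise = noiseSpec(),
                           seed = 1, band = c(0.01, 0.2),
                           montage = buildMontage(),
                           kernel = c("offset", "monotone")) {
  kernel <- match.arg(kernel)
  if (length(groups) == 0) stop("at least one group spec is required")
  set.seed(seed)
  recs <- list(); pars <- list(); meta <- list(); truth <- list(); logs <- list()
  for (g in groups) {
    for (i in seq_len(g$n)) {
      sid <- sprintf("%s_%02d", substr(g$group, 1, 2), i)
      s <- .generateSubjectRecording(g, sid, paradigm, noise, band, montage,
                                     kernel)
      recs[[sid]] <- s$recording
      pars[[sid]] <- s$paradigm
      meta[[sid]] <- s$metadata
      truth[[sid]] <- s$truth
      if (nrow(s$artifact_log))
        logs[[sid]] <- cbind(subject = sid, s$artifact_log)
    }
  }
  list(recordings = recs, paradigms = pars,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       artifact_log = if (length(logs))
         do.call(rbind, c(logs, list(make.row.names = FALSE)))
       else NULL)
}
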