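## Shared fixtures built in code.

FS <- 3.91

## A recording whose per-channel intensity series are supplied as a list
## (760 nm); the 850 nm series default to the same values.
makeRecording <- function(series760, series850 = series760,
                          samplingRate = FS, montage = buildMontage()) {
  m760 <- do.call(rbind, series760)
  m850 <- do.call(rbind, series850)
  rownames(m760) <- rownames(m850) <- NULL
  NirsRecording(list("760" = m760, "850" = m850),
                samplingRate = samplingRate, montage = montage)
}

## A channel-level HbSeries over all 40 montage channels where selected
## channels carry given constant HbO values and the rest are zero.
makeChannelHb <- function(values, n = 50, samplingRate = FS) {
  m <- matrix(0, 40, n, dimnames = list(1:40, NULL))
  for (ch in names(values)) m[ch, ] <- values[[ch]]
  HbSeries(m, -m / 3, samplingRate = samplingRate, level = "channel",
           rowIds = 1:40)
}

## Full-retention mask for the default montage.
fullMask <- function() setNames(rep(TRUE, 40), 1:40)

## A group spec with zero between-subject SD so that drawn targets equal
## the supplied means exactly (useful for noiseless oracle tests).
fixedGroupSpec <- function(lat = 6.48, A = 0.41, d = 0.34,
                           duration = c(30, 30), group = "fixed") {
  rois <- c("left_PFC", "right_PFC", "left_MC", "right_MC")
  params <- do.call(rbind, lapply(rois, function(r) rbind(
    data.frame(roi = r, temperature = 25, latency_mean = lat,
               latency_se = 0, dhbo_mean = A, dhbo_se = 0,
               dhbostar_mean = d, dhbostar_se = 0),
    data.frame(roi = r, temperature = 5, latency_mean = lat,
               latency_se = 0, dhbo_mean = A, dhbo_se = 0,
               dhbostar_mean = d, dhbostar_se = 0))))
  groupSpec(group, 5, params, durationRange = duration)
}

## FFT amplitude of the dominant spectral component.
fftAmplitude <- function(y) {
  n <- length(y)
  max(Mod(fft(y - mean(y))))  * 2 / n
}

## AUC by exhaustive positive/negative pair counting (ties get half credit).
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
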