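## Window conventions shared by the feature extractor and the synthetic
## generator: baseline = [onset - bw, onset), peak search = [onset, onset +
## duration + ext], post window = (end, end + pw].

.baselineIdx <- function(times, onset, bw) {
  which(times >= onset - bw & times < onset)
}
.peakIdx <- function(times, onset, duration, ext = 0) {
  which(times >= onset & times <= onset + duration + ext)
}
.postIdx <- function(times, end, pw) {
  which(times > end & times <= end + pw)
}

#' Average retained channels into ROI series
#'
#' Unweighted mean of the retained member channels of each ROI.  Channels
#' belonging to two ROIs (9 and 12 in the default montage) contribute to
#' both.  An ROI whose member channels were all rejected is returned as a
#' row of NAs with a contributing count of 0 (missing, not an error).
#'
#' @param hb channel-level \linkS4class{HbSeries}.
#' @param montage a \linkS4class{Montage}.
#' @param mask named logical vector (channel id -> retained); channels
#'   absent from \code{hb} are treated as rejected.
#' @return ROI-level \linkS4class{HbSeries}; \code{metadata()$n_channels}
#'   holds the per-ROI contributing counts.
#' @export
roiAverage <- function(hb, montage, mask = NULL) {
  hboM <- hbo(hb); hbrM <- hbr(hb)
  avail <- rownames(hboM)
  if (is.null(avail)) stop("channel-level HbSeries must carry channel ids")
  rois <- names(montage@roiMap)
  counts <- setNames(integer(length(rois)), rois)
  outO <- matrix(NA_real_, length(rois), ncol(hboM),
                 dimnames = list(rois, NULL))
  outR <- outO
  for (r in rois) {
    members <- as.character(montage@roiMap[[r]])
    keep <- members[members %in% avail]
    if (!is.null(mask))
      keep <- keep[vapply(keep, function(ch)
        isTRUE(mask[[ch]]), logical(1))]
    counts[r] <- length(keep)
    if (length(keep)) {
      outO[r, ] <- colMeans(hboM[keep, , drop = FALSE])
      outR[r, ] <- colMeans(hbrM[keep, , drop = FALSE])
    }
  }
  res <- HbSeries(outO, outR, samplingRate = samplingRate(hb),
                  times = sampleTimes(hb), level = "roi",
                  provenance = metadata(hb)$provenance, rowIds = rois)
  metadata(res)$n_channels <- counts
  res
}

#' Pre-stimulus baseline mean
#'
#' Arithmetic mean of an HbO series over the half-open window
#' \eqn{[onset - w, onset)} preceding the primary stimulus (default
#' w = 30 s).
#'
#' @param y numeric series.
#' @param times sample times (s).
#' @param onset primary stimulus onset (s).
#' @param window baseline window length (s).
#' @return baseline mean (same units as \code{y}).
#' @export
baselineMean <- function(y, times, onset, window = 30) {
  if (onset - window < times[1])
    stop("baseline window [", onset - window, ", ", onset,
         ") precedes the start of the recording")
  mean(y[.baselineIdx(times, onset, window)])
}

#' Peak latency of the HbO response
#'
#' Time from stimulus onset to the maximum HbO sample inside the search
#' window \eqn{[onset, onset + duration + ext]}.  The earliest sample wins
#' ties (\code{tie} flag set); if the maximum is the last sample of the
#' window the \code{boundary} flag is set.
#'
#' @param y numeric HbO series.
#' @param times sample times (s).
#' @param onset,duration event onset and duration (s).
#' @param ext extension of the search window beyond the stimulus end (s);
#'   default 0 confines the peak to the stimulation period.
#' @return list(latency, boundary, tie).
#' @export
peakLatency <- function(y, times, onset, duration, ext = 0) {
  idx <- .peakIdx(times, onset, duration, ext)
  if (!length(idx)) stop("empty peak search window")
  v <- y[idx]
  mx <- max(v)
  hits <- which(v == mx)
  i <- hits[1]
  list(latency = times[idx[i]] - onset,
       boundary = i == length(idx),
       tie = length(hits) > 1L)
}

#' Baseline-to-peak HbO change (delta-HbO)
#'
#' Maximum HbO inside the peak search window minus the pre-stimulus
#' baseline (mM).
#'
#' @inheritParams peakLatency
#' @param baseline baseline mean (see \code{\link{baselineMean}}).
#' @return delta-HbO (mM).
#' @export
deltaHbo <- function(y, times, onset, duration, baseline, ext = 0) {
  idx <- .peakIdx(times, onset, duration, ext)
  if (!length(idx)) stop("empty peak search window")
  max(y[idx]) - baseline
}

#' Post-stimulus HbO change (delta-HbO*)
#'
#' Signed difference between the mean HbO over the 15 s window following the
#' stimulus end and the pre-stimulus baseline.  The default summarises the
#' window by its mean; \code{method = "instant"} uses the single sample
#' closest to end + window instead.
#'
#' @inheritParams deltaHbo
#' @param window post-stimulus window length (s), default 15.
#' @param method \code{"mean"} (default) or \code{"instant"}.
#' @return delta-HbO* (mM), sign retained.
#' @export
deltaHboStar <- function(y, times, onset, duration, baseline, window = 15,
                         method = c("mean", "instant")) {
  method <- match.arg(method)
  end <- onset + duration
  if (end + window > times[length(times)] + 1e-9)
    stop("post-stimulus window [", end, ", ", end + window,
         "] is truncated by the end of the recording")
  idx <- .postIdx(times, end, window)
  if (method == "mean") mean(y[idx]) - baseline
  else y[idx[length(idx)]] - baseline
}

#' Percent change between two values
#'
#' \eqn{100 (post - pre)/pre}, returned both at full precision and rounded
#' half-up (away from zero) to two decimals, matching how group summaries
#' are conventionally printed.
#'
#' @param pre,post numeric values; \code{pre} must be nonzero.
#' @return list(value, rounded).
#' @examples
#' percentChange(0.25, 0.38)$rounded  # 52
#' @export
percentChange <- function(pre, post) {
  if (any(pre == 0)) stop("percent change undefined for a zero pre value")
  v <- 100 * (post - pre) / pre
  list(value = v, rounded = roundHalfUp(v, 2))
}

#' Round half away from zero
#'
#' Decimal rounding where halves round away from zero (2.345 -> 2.35),
#' unlike \code{round()}'s round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Extract the three features for every ROI and stimulus
#'
#' Computes, per ROI and thermal stimulus, the pre-stimulus baseline, the
#' peak latency, delta-HbO and delta-HbO*.  The baseline is the 30 s (by
#' default) before the primary stimulus and is shared by both stimuli.
#'
#' @param roiHb ROI-level \linkS4class{HbSeries} from \code{\link{roiAverage}}.
#' @param paradigm a \linkS4class{ParadigmTimeline} whose event onsets and
#'   durations reflect the realized timing for this subject.
#' @param peakWindowExtension extension of the peak search window beyond the
#'   stimulus end (s); default 0.
#' @param starMethod passed to \code{\link{deltaHboStar}}.
#' @return data.frame: roi, temperature, baseline, peak_latency, delta_hbo,
#'   delta_hbo_star, n_channels, boundary, tie.
#' @export
extractFeatures <- function(roiHb, paradigm, peakWindowExtension = 0,
                            starMethod = "mean") {
  times <- sampleTimes(roiHb)
  ev <- paradigmEvents(paradigm)
  onset0 <- primaryOnset(paradigm)
  bw <- paradigm@baselineWindow
  pw <- paradigm@postWindow
  counts <- metadata(roiHb)$n_channels
  m <- hbo(roiHb)
  rows <- list()
  for (r in rownames(m)) {
    y <- m[r, ]
    missing <- all(is.na(y))
    base <- if (missing) NA_real_ else baselineMean(y, times, onset0, bw)
    for (k in seq_len(nrow(ev))) {
      if (missing) {
        rows[[length(rows) + 1L]] <- data.frame(
          roi = r, temperature = ev$temperature_C[k], baseline = NA_real_,
          peak_latency = NA_real_, delta_hbo = NA_real_,
          delta_hbo_star = NA_real_,
          n_channels = if (is.null(counts)) NA_integer_ else counts[[r]],
          boundary = NA, tie = NA)
        next
      }
      pl <- peakLatency(y, times, ev$onset[k], ev$duration[k],
                        ext = peakWindowExtension)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, temperature = ev$temperature_C[k], baseline = base,
        peak_latency = pl$latency,
        delta_hbo = deltaHbo(y, times, ev$onset[k], ev$duration[k], base,
                             ext = peakWindowExtension),
        delta_hbo_star = deltaHboStar(y, times, ev$onset[k], ev$duration[k],
                                      base, window = pw,
                                      method = starMethod),
        n_channels = if (is.null(counts)) NA_integer_ else counts[[r]],
        boundary = pl$boundary, tie = pl$tie)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
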