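## Noiseless hemodynamic response synthesis.
##
## Each stimulation event contributes (i) a gamma-variate transient peaking
## at the drawn latency with the drawn amplitude, and (ii) a smooth
## post-offset response spanning the 15 s window after immersion ends, whose
## level is solved so that the sampled post-window mean equals the drawn
## delta-HbO* target.  The offset component is compact (~25 s), so its
## spectral content lies inside the 0.01-0.2 Hz analysis band and survives
## the band-pass largely intact; a sustained monotone decay does not, which
## is why the alternative "monotone" kernel cannot reach high
## delta-HbO*/delta-HbO ratios once filtering is applied.

.gammaTransient <- function(times, onset, tp, A, shape = 3) {
  y <- numeric(length(times))
  s <- (times - onset) / tp
  pos <- s > 0
  y[pos] <- A * s[pos]^shape * exp(shape * (1 - s[pos]))
  y
}

## The offset response starts shortly after immersion ends (delay reduces
## how much of it the zero-phase filter smears back into the stimulus
## window) and holds a flat level across the remainder of the post window.
.offsetPlateau <- function(times, end, pw = 15, delay = 1, rise = 3,
                           fall = 6) {
  w <- numeric(length(times))
  t0 <- end + delay
  up <- times > t0 & times <= t0 + rise
  w[up] <- 0.5 * (1 - cos(pi * (times[up] - t0) / rise))
  w[times > t0 + rise & times <= end + pw] <- 1
  dn <- times > end + pw & times <= end + pw + fall
  w[dn] <- 0.5 * (1 + cos(pi * (times[dn] - end - pw) / fall))
  w
}

## events: list of lists with onset, duration, tp, A, d
.responseSeries <- function(times, events, fs, pw = 15,
                            kernel = c("offset", "monotone"), shape = 3) {
  kernel <- match.arg(kernel)
  y <- numeric(length(times))
  for (e in events) {
    tpk <- round((e$onset + e$tp) * fs) / fs        # snap peak to the grid
    end <- e$onset + e$duration
    pid <- .postIdx(times, end, pw)
    if (kernel == "offset") {
      g <- .gammaTransient(times, e$onset, tpk - e$onset, e$A, shape)
      w <- .offsetPlateau(times, end, pw)
      p <- (e$d - mean(g[pid])) / mean(w[pid])
      y <- y + g + p * w
    } else {
      ## single transient with exponential return-to-baseline; the sampled
      ## post-window mean is monotone in tau, so solve tau for d
      build <- function(tau) {
        g <- .gammaTransient(times, e$onset, tpk - e$onset, e$A, shape)
        dec <- times > tpk
        g[dec] <- e$A * exp(-(times[dec] - tpk) / tau)
        tpr <- times > end + pw
        frac <- pmin((times - (end + pw)) / 60, 1)
        g[tpr] <- g[tpr] * 0.5 * (1 + cos(pi * frac[tpr]))
        g[tpr & frac >= 1] <- 0
        g
      }
      obj <- function(tau) mean(build(tau)[pid]) - e$d
      if (obj(1e5) < 0)
        stop("infeasible response shape: requested delta-HbO* (", e$d,
             ") exceeds what a monotone-decay kernel can reach for ",
             "delta-HbO = ", e$A)
      tau <- if (obj(0.05) >= 0) 0.05 else
        uniroot(obj, c(0.05, 1e5), tol = 1e-12)$root
      y <- y + build(tau)
    }
  }
  y
}

## measure the three features of each event exactly as extractFeatures does
.measureEvents <- function(y, times, events, baseOnset, bw, pw, ext = 0) {
  base <- mean(y[.baselineIdx(times, baseOnset, bw)])
  t(vapply(events, function(e) {
    idx <- .peakIdx(times, e$onset, e$duration, ext)
    i <- idx[which.max(y[idx])]
    c(tp = times[i] - e$onset,
      A = max(y[idx]) - base,
      d = mean(y[.postIdx(times, e$onset + e$duration, pw)]) - base)
  }, numeric(3)))
}

## Fixed-point pre-compensation of the analysis band-pass: adjust the raw
## kernel parameters until the features measured AFTER zero-phase filtering
## match the drawn targets.  Latency is grid-quantised, so it is matched to
## within half a sample; amplitudes converge to ~1e-3 or better and the best
## iterate is kept.
.calibrateSeries <- function(times, events, fs, pw, bw, baseOnset, band,
                             ext = 0, kernel = "offset", maxit = 25,
                             tol = 1e-5) {
  target <- t(vapply(events, function(e) c(e$tp, e$A, e$d), numeric(3)))
  par <- events
  best <- NULL; bestErr <- Inf; bestF <- NULL
  dt <- 1 / fs
  for (it in seq_len(maxit)) {
    y <- .responseSeries(times, par, fs, pw, kernel)
    yf <- bandpassFilter(y, band[1], band[2], fs)
    f <- .measureEvents(yf, times, par, baseOnset, bw, pw, ext)
    err <- target - f
    ## quality of an iterate: amplitude error plus any latency error beyond
    ## the grid resolution (so a peak that has jumped windows is never kept)
    e2 <- max(abs(err[, 2:3]))
    eq <- e2 + 0.5 * max(0, max(abs(err[, 1])) - dt)
    if (eq < bestErr) { bestErr <- eq; best <- y; bestF <- f }
    if (e2 < tol && max(abs(err[, 1])) <= dt / 2 + 1e-9) break
    for (i in seq_along(par)) {
      par[[i]]$tp <- min(max(par[[i]]$tp + err[i, 1], 0.5),
                         par[[i]]$duration - 0.2)
      par[[i]]$A <- par[[i]]$A + err[i, 2]
      par[[i]]$d <- par[[i]]$d + err[i, 3]
    }
  }
  ## achieved = the features the analysis pipeline measures on the emitted
  ## noiseless response; equals the targets whenever calibration converged
  list(series = best, achieved = bestF)
}
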