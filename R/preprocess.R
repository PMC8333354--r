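#' Default differential pathlength factors
#'
#' Wavelength-specific multipliers correcting the geometric source-detector
#' distance for photon scattering: 7.25 at 760 nm and 6.38 at 850 nm.
#' @return named numeric(2).
#' @export
dpfDefaults <- function() c("760" = 7.25, "850" = 6.38)

#' Default extinction coefficient matrix
#'
#' Effective extinction coefficients of oxy- and deoxyhemoglobin at 760 and
#' 850 nm, expressed in optical density per cm per concentration unit on the
#' instrument's mM-labelled reporting scale (the molar-scale conversion is
#' folded into the constants; values derive from the standard compiled
#' in-vitro tabulation).  Rows = wavelengths, columns = chromophores.
#' @return 2 x 2 matrix, rows \code{c("760","850")}, cols \code{c("HbO","HbR")}.
#' @export
extinctionDefaults <- function() {
  matrix(c(5.860e-4, 1.54852e-3,
           1.0584e-3, 6.9132e-4),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO", "HbR")))
}

#' Coefficient of variation per channel and wavelength
#'
#' The channel quality-control statistic: 100 * sample SD / sample mean of
#' the raw intensity, computed per channel and wavelength on the unfiltered
#' recording.  A non-positive mean leaves the CV undefined (NA), which
#' downstream rejection treats as a failed channel.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @return data.frame with columns \code{channel_id}, \code{wavelength_nm},
#'   \code{cv} (percent, NA when undefined).
#' @examples
#' ## a constant positive signal has CV 0
#' @export
channelCV <- function(rec) {
  out <- do.call(rbind, lapply(c("760", "850"), function(wl) {
    m <- intensity(rec, wl)
    if (ncol(m) < 2L) stop("channelCV needs at least two samples")
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    cv <- ifelse(mu > 0, 100 * s / mu, NA_real_)
    data.frame(channel_id = as.integer(rownames(m)),
               wavelength_nm = as.integer(wl), cv = cv)
  }))
  rownames(out) <- NULL
  out
}

#' Reject channels whose CV exceeds a threshold
#'
#' A channel is rejected when the CV at either wavelength strictly exceeds
#' the threshold (default 7.5 percent), or when its CV is undefined.  A CV
#' exactly at the threshold is retained.
#'
#' @param qc output of \code{\link{channelCV}}.
#' @param threshold rejection threshold in percent (> 0).
#' @return data.frame with one row per channel: \code{channel_id},
#'   \code{cv_760}, \code{cv_850}, \code{rejected}, \code{reason}.
#' @export
rejectChannels <- function(qc, threshold = 7.5) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  wide <- merge(qc[qc$wavelength_nm == 760, c("channel_id", "cv")],
                qc[qc$wavelength_nm == 850, c("channel_id", "cv")],
                by = "channel_id", suffixes = c("_760", "_850"))
  undef <- is.na(wide$cv_760) | is.na(wide$cv_850)
  high <- (!is.na(wide$cv_760) & wide$cv_760 > threshold) |
          (!is.na(wide$cv_850) & wide$cv_850 > threshold)
  wide$rejected <- undef | high
  wide$reason <- ifelse(undef, "undefined CV",
                 ifelse(high, sprintf("CV > %g%%", threshold), ""))
  wide[order(wide$channel_id), ]
}

#' Convert raw intensities to optical-density changes
#'
#' Attenuation change per channel and wavelength,
#' \eqn{\Delta OD(t) = -log10(I(t)/I_0)}.  By default \eqn{I_0} is the
#' channel's full-recording mean intensity (the common convention; the
#' arbitrary per-channel DC level this leaves in the concentrations is
#' removed downstream by baseline subtraction).  Pass a numeric
#' \code{reference} to use a known source intensity instead, which makes
#' the conversion the exact inverse of \code{\link{inverseMbllEncode}}.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @param reference NULL (per-channel mean) or a positive scalar.
#' @return named list of two matrices (\code{"760"}, \code{"850"}).
#' @export
toOpticalDensity <- function(rec, reference = NULL) {
  lapply(setNames(c("760", "850"), c("760", "850")), function(wl) {
    m <- intensity(rec, wl)
    if (any(m <= 0)) {
      bad <- rownames(m)[apply(m <= 0, 1, any)]
      stop("optical-density conversion failed: non-positive intensity in ",
           "channel(s) ", paste(bad, collapse = ", "), " at ", wl, " nm")
    }
    i0 <- if (is.null(reference)) rowMeans(m) else reference
    -log10(m / i0)
  })
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, order 3 per pass,
#' with the study band 0.01-0.2 Hz as default.  Zero-phase filtering
#' preserves peak timing, which protects latency estimates.
#'
#' @param x numeric vector or matrix (series along rows).
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param samplingRate sampling rate fs in Hz.
#' @param order Butterworth order per pass.
#' @return filtered data, same shape as \code{x}.
#' @export
bandpassFilter <- function(x, low = 0.01, high = 0.2, samplingRate = 3.91,
                           order = 3) {
  nyq <- samplingRate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("filter band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- butter(order, c(low, high) / nyq, type = "pass")
  ## removing the series mean first avoids the step transient a nonzero DC
  ## level would otherwise leave at the record edges (the band-pass removes
  ## DC in any case)
  f1 <- function(v) as.numeric(filtfilt(bf, v - mean(v)))
  if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Solves, per time point and channel, the 2 x 2 system
#' \deqn{\epsilon \cdot (\Delta HbO, \Delta HbR)^T =
#'       (\Delta OD_\lambda / (L \cdot DPF_\lambda))_\lambda}
#' where \eqn{L} is the source-detector separation and DPF the differential
#' pathlength factor.  Output concentrations are on the instrument's
#' mM-labelled scale (see \code{\link{extinctionDefaults}}).
#'
#' @param od named list of optical-density matrices (\code{"760"},
#'   \code{"850"}), as produced by \code{\link{toOpticalDensity}}.
#' @param separation source-detector distance in cm.
#' @param dpf named numeric(2) of differential pathlength factors.
#' @param extinction 2 x 2 extinction matrix (rows wavelengths, cols
#'   \code{HbO}, \code{HbR}); must be nonsingular.
#' @param samplingRate sampling rate carried into the result.
#' @param provenance provenance list stored in the result.
#' @return an \linkS4class{HbSeries} at channel level.
#' @export
mbll <- function(od, separation = 3, dpf = dpfDefaults(),
                 extinction = extinctionDefaults(), samplingRate = 3.91,
                 provenance = list()) {
  if (!all(c("760", "850") %in% names(od)))
    stop("mbll needs optical density at both wavelengths (760, 850)")
  if (abs(det(extinction)) < .Machine$double.eps * 100 * max(abs(extinction))^2)
    stop("extinction matrix is singular")
  sc760 <- od[["760"]] / (separation * dpf[["760"]])
  sc850 <- od[["850"]] / (separation * dpf[["850"]])
  nch <- nrow(sc760); nt <- ncol(sc760)
  rhs <- rbind(as.vector(sc760), as.vector(sc850))
  conc <- solve(extinction, rhs)
  hboM <- matrix(conc[1, ], nch, nt, dimnames = dimnames(sc760))
  hbrM <- matrix(conc[2, ], nch, nt, dimnames = dimnames(sc760))
  prov <- modifyList(list(separation_cm = separation, dpf = dpf,
                          extinction = extinction), provenance)
  HbSeries(hboM, hbrM, samplingRate = samplingRate, level = "channel",
           provenance = prov, rowIds = rownames(sc760))
}

#' Quality control and conversion of one recording
#'
#' The two-step preprocessing protocol: (1) channel quality control on the
#' raw intensities (CV rejection), (2) optical-density conversion, zero-phase
#' band-pass, and modified Beer-Lambert conversion of the retained channels.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @param cvThreshold CV rejection threshold (percent).
#' @param band numeric(2) filter band in Hz, or NULL to skip filtering.
#' @param dpf,extinction see \code{\link{mbll}}.
#' @return list with \code{hb} (channel-level \linkS4class{HbSeries} of the
#'   retained channels), \code{qc} (the rejection table) and \code{mask}
#'   (named logical, TRUE = retained).
#' @export
preprocessRecording <- function(rec, cvThreshold = 7.5, band = c(0.01, 0.2),
                                dpf = dpfDefaults(),
                                extinction = extinctionDefaults()) {
  qc <- rejectChannels(channelCV(rec), threshold = cvThreshold)
  mask <- !qc$rejected
  names(mask) <- qc$channel_id
  if (!any(mask))
    stop("quality control rejected all channels (CVs exceed ", cvThreshold,
         "%): ", paste(qc$channel_id, collapse = ", "))
  keep <- as.character(qc$channel_id[mask])
  od <- toOpticalDensity(rec)
  od <- lapply(od, function(m) m[keep, , drop = FALSE])
  sr <- samplingRate(rec)
  if (!is.null(band))
    od <- lapply(od, bandpassFilter, low = band[1], high = band[2],
                 samplingRate = sr)
  mont <- metadata(rec)$montage
  sep <- if (is.null(mont)) 3 else mont@separation
  hb <- mbll(od, separation = sep, dpf = dpf, extinction = extinction,
             samplingRate = sr,
             provenance = list(filter_band_Hz = band,
                               subject_id = subjectId(rec)))
  list(hb = hb, qc = qc, mask = mask)
}
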