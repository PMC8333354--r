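#' Raw dual-wavelength fNIRS recording
#'
#' A \linkS4class{SummarizedExperiment} with one assay per wavelength
#' (\code{"760"} and \code{"850"}, raw light intensities), rows = channels,
#' columns = time points.  \code{rowData} carries channel/source/detector
#' ids, \code{colData} the sample times, and \code{metadata} the sampling
#' rate (Hz), subject id and the \linkS4class{Montage}.
#'
#' @export
setClass("NirsRecording", contains = "SummarizedExperiment")

setValidity("NirsRecording", function(object) {
  msg <- character()
  if (!all(c("760", "850") %in% assayNames(object)))
    msg <- c(msg, "both wavelength assays ('760', '850') must be present")
  sr <- metadata(object)$sampling_rate
  if (is.null(sr) || sr <= 0)
    msg <- c(msg, "metadata$sampling_rate must be a positive Hz value")
  if (is.null(colData(object)$time_s))
    msg <- c(msg, "colData must carry time_s")
  if (length(msg)) msg else TRUE
})

#' Construct a raw recording
#'
#' @param intensities named list of two channels x time matrices, names
#'   \code{"760"} and \code{"850"} (nm).
#' @param samplingRate sampling rate in Hz (default 3.91).
#' @param montage a \linkS4class{Montage} (default \code{buildMontage()}).
#' @param subjectId subject identifier.
#' @param times optional vector of sample times (s); computed from the
#'   sampling rate when omitted.
#' @return a \linkS4class{NirsRecording}.
#' @export
NirsRecording <- function(intensities, samplingRate = 3.91,
                          montage = buildMontage(), subjectId = "S1",
                          times = NULL) {
  if (!all(c("760", "850") %in% names(intensities)))
    stop("intensities must be a named list with '760' and '850' matrices")
  dims <- vapply(intensities, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("intensity matrices must have identical dimensions")
  n <- dims[2, 1]
  if (is.null(times)) times <- (seq_len(n) - 1) / samplingRate
  nch <- dims[1, 1]
  rd <- montage@channels[seq_len(nch), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = intensities[c("760", "850")],
    rowData = DataFrame(rd),
    colData = DataFrame(time_s = times),
    metadata = list(sampling_rate = samplingRate, subject_id = subjectId,
                    montage = montage, wavelengths_nm = c(760, 850))
  )
  rownames(se) <- rd$channel_id
  new("NirsRecording", se)
}

#' Hemoglobin concentration-change series
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{HbO} and \code{HbR}
#' (concentration changes on the instrument's mM-labelled scale), rows =
#' channels or ROIs, columns = time points.  \code{metadata} records the
#' sampling rate, the aggregation level (\code{"channel"} or \code{"roi"})
#' and a provenance list (filter band, DPF, extinction source).
#'
#' @export
setClass("HbSeries", contains = "SummarizedExperiment")

setValidity("HbSeries", function(object) {
  msg <- character()
  if (!all(c("HbO", "HbR") %in% assayNames(object)))
    msg <- c(msg, "assays HbO and HbR must be present")
  if (is.null(metadata(object)$sampling_rate))
    msg <- c(msg, "metadata$sampling_rate required")
  if (length(msg)) msg else TRUE
})

#' Construct an HbSeries
#'
#' @param hbo,hbr matrices (channels or ROIs x time).
#' @param samplingRate Hz.
#' @param times sample times (s); computed when omitted.
#' @param level \code{"channel"} or \code{"roi"}.
#' @param provenance free-form list (filter band, DPF, extinction source...).
#' @param rowIds row identifiers (channel ids or ROI labels).
#' @return an \linkS4class{HbSeries}.
#' @export
HbSeries <- function(hbo, hbr = -hbo / 3, samplingRate = 3.91, times = NULL,
                     level = c("channel", "roi"), provenance = list(),
                     rowIds = NULL) {
  level <- match.arg(level)
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr)))
    stop("HbO and HbR must have identical dimensions")
  if (is.null(times)) times <- (seq_len(ncol(hbo)) - 1) / samplingRate
  se <- SummarizedExperiment(assays = list(HbO = hbo, HbR = hbr),
                             colData = DataFrame(time_s = times),
                             metadata = list(sampling_rate = samplingRate,
                                             level = level,
                                             provenance = provenance))
  if (!is.null(rowIds)) rownames(se) <- rowIds
  new("HbSeries", se)
}

#' @rdname accessors
#' @param x a \linkS4class{NirsRecording} or \linkS4class{HbSeries}.
#' @export
samplingRate <- function(x) metadata(x)$sampling_rate

#' @rdname accessors
#' @export
sampleTimes <- function(x) colData(x)$time_s

#' @rdname accessors
#' @export
subjectId <- function(x) metadata(x)$subject_id

#' Accessors for recordings and hemoglobin series
#'
#' \code{samplingRate}, \code{sampleTimes}, \code{subjectId},
#' \code{intensity}, \code{hbo} and \code{hbr} extract the corresponding
#' pieces of a \linkS4class{NirsRecording} or \linkS4class{HbSeries}.
#'
#' @param wavelength \code{"760"} or \code{"850"}.
#' @name accessors
#' @export
intensity <- function(x, wavelength = c("760", "850")) {
  wavelength <- match.arg(as.character(wavelength), c("760", "850"))
  assay(x, wavelength)
}

#' @rdname accessors
#' @export
hbo <- function(x) assay(x, "HbO")

#' @rdname accessors
#' @export
hbr <- function(x) assay(x, "HbR")
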