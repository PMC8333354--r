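#' Optode montage with region-of-interest channel groups
#'
#' An S4 container describing a 40-channel fNIRS montage: source/detector
#' pairing per channel, the source-detector separation, and the assignment of
#' channels to cortical regions of interest (ROIs).  The default montage
#' covers the bilateral prefrontal cortex (PFC) and motor cortex (MC) with
#' 16 sources and 16 detectors spaced at 3 cm:
#' left PFC = channels 1-9 plus 11 and 12, right PFC = channels 12-20 plus
#' 9 and 10, right MC = channels 21-30, left MC = channels 31-40.  Channels
#' 9 and 12 belong to both PFC ROIs.
#'
#' @slot channels data.frame with columns \code{channel_id}, \code{source_id},
#'   \code{detector_id}.
#' @slot separation numeric(1), source-detector distance in cm.
#' @slot roiMap named list mapping each ROI label to an integer vector of
#'   member channel ids.
#' @export
setClass("Montage", slots = c(
  channels   = "data.frame",
  separation = "numeric",
  roiMap     = "list"
))

setValidity("Montage", function(object) {
  ch <- object@channels
  msg <- character()
  if (!all(c("channel_id", "source_id", "detector_id") %in% names(ch)))
    msg <- c(msg, "channels must have channel_id, source_id, detector_id")
  if (nrow(ch) != 40L || !identical(sort(ch$channel_id), 1:40))
    msg <- c(msg, "montage must have exactly channels 1..40")
  if (length(object@separation) != 1L || object@separation <= 0)
    msg <- c(msg, "separation must be a single positive length (cm)")
  ids <- unlist(object@roiMap, use.names = FALSE)
  if (length(object@roiMap) == 0L || is.null(names(object@roiMap)))
    msg <- c(msg, "roiMap must be a named list")
  else {
    if (any(!ids %in% ch$channel_id))
      msg <- c(msg, "roiMap refers to channel ids outside the montage")
    if (!all(ch$channel_id %in% ids))
      msg <- c(msg, "every channel must belong to at least one ROI")
  }
  if (length(msg)) msg else TRUE
})

#' ROI labels used by the default montage
#' @export
ROI_LABELS <- c("left_PFC", "right_PFC", "right_MC", "left_MC")

.defaultRoiMap <- function() {
  list(
    left_PFC  = c(1:9, 11L, 12L),
    right_PFC = c(12:20, 9L, 10L),
    right_MC  = 21:30,
    left_MC   = 31:40
  )
}

#' Build an fNIRS montage
#'
#' Construct a \linkS4class{Montage}.  With no arguments this returns the
#' default 40-channel bilateral PFC/MC montage (16 sources, 16 detectors,
#' 3 cm separation).
#'
#' @param channels optional data.frame (channel_id, source_id, detector_id);
#'   the default wires channel \eqn{k} to source/detector pair
#'   \code{ceiling(k/2.5)} in a compact layout.
#' @param separation source-detector distance in cm (default 3).
#' @param roiMap named list of ROI label -> integer channel ids; defaults to
#'   the bilateral PFC/MC grouping described above.
#' @return a validated \linkS4class{Montage}.
#' @examples
#' m <- buildMontage()
#' channelRois(m, 25)   # "right_MC"
#' channelRois(m, 12)   # both PFC ROIs
#' @export
buildMontage <- function(channels = NULL, separation = 3, roiMap = NULL) {
  if (is.null(channels)) {
    channels <- data.frame(
      channel_id  = 1:40,
      source_id   = ((0:39) %/% 5) * 2 + 1 + (0:39) %% 2,
      detector_id = ((0:39) %/% 5) * 2 + 1 + ((0:39) %/% 2) %% 2
    )
  }
  if (is.null(roiMap)) roiMap <- .defaultRoiMap()
  roiMap <- lapply(roiMap, function(x) as.integer(sort(unique(x))))
  bad <- setdiff(unlist(roiMap), channels$channel_id)
  if (length(bad))
    stop("invalid montage: ROI map refers to unknown channel id(s) ",
         paste(bad, collapse = ", "))
  new("Montage", channels = channels, separation = separation, roiMap = roiMap)
}

#' @describeIn buildMontage channels belonging to one ROI.
#' @param montage a \linkS4class{Montage}.
#' @param roi ROI label.
#' @export
roiChannels <- function(montage, roi) {
  if (!roi %in% names(montage@roiMap))
    stop("unknown ROI label: ", roi)
  montage@roiMap[[roi]]
}

#' @describeIn buildMontage ROI label(s) a channel belongs to.
#' @param channel channel id (1..40 in the default montage).
#' @export
channelRois <- function(montage, channel) {
  if (length(channel) != 1L || !channel %in% montage@channels$channel_id)
    stop("invalid montage query: channel id ", channel, " is out of range")
  names(montage@roiMap)[vapply(montage@roiMap, function(x) channel %in% x,
                               logical(1))]
}

#' @describeIn buildMontage source-detector separation in cm.
#' @export
separation <- function(montage) montage@separation

setMethod("show", "Montage", function(object) {
  cat("Montage with", nrow(object@channels), "channels, separation",
      object@separation, "cm\n")
  for (r in names(object@roiMap))
    cat("  ", r, ": ", length(object@roiMap[[r]]), " channels\n", sep = "")
})
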