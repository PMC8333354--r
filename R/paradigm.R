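#' Cold-pressor experimental paradigm timeline
#'
#' Timing of the thermal-stimulation paradigm: an initial rest period, a
#' pre-stimulus baseline window, hand immersion at 25 degC (primary,
#' innocuous) and 5 degC (secondary, noxious) separated by an inter-stimulus
#' rest, and a post-stimulus analysis window after each immersion.
#'
#' @slot restDuration numeric(1), initial rest (s).
#' @slot baselineWindow numeric(1), baseline window length immediately before
#'   the primary onset (s).
#' @slot events data.frame with columns \code{label}, \code{onset},
#'   \code{duration}, \code{temperature_C}, chronologically ordered and
#'   non-overlapping.
#' @slot interStimulusRest numeric(1), rest between immersions (s).
#' @slot postWindow numeric(1), post-stimulus analysis window (s).
#' @export
setClass("ParadigmTimeline", slots = c(
  restDuration      = "numeric",
  baselineWindow    = "numeric",
  events            = "data.frame",
  interStimulusRest = "numeric",
  postWindow        = "numeric"
))

setValidity("ParadigmTimeline", function(object) {
  ev <- object@events
  msg <- character()
  scalars <- c(rest = object@restDuration, baseline = object@baselineWindow,
               isi = object@interStimulusRest, post = object@postWindow)
  if (any(scalars <= 0)) msg <- c(msg, "all paradigm durations must be > 0")
  if (!all(c("label", "onset", "duration") %in% names(ev)))
    msg <- c(msg, "events need label, onset, duration")
  else {
    if (any(ev$duration <= 0)) msg <- c(msg, "event durations must be > 0")
    if (is.unsorted(ev$onset, strictly = TRUE))
      msg <- c(msg, "events must be in chronological order")
    if (nrow(ev) > 1 &&
        any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)]))
      msg <- c(msg, "events must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Build a paradigm timeline
#'
#' Onsets are computed from the component durations: the primary immersion
#' starts after the initial rest, the secondary immersion after the primary
#' plus the inter-stimulus rest.  Defaults follow the cold-pressor protocol
#' (60 s rest, 30 s baseline, up to 30 s immersions, 2 min between trials,
#' 15 s post-stimulus window): with all defaults the secondary onset is at
#' 60 + 30 + 120 = 210 s.
#'
#' @param restDuration initial rest (s).
#' @param baselineWindow baseline window before the primary onset (s).
#' @param durations immersion durations, numeric(2) (primary, secondary) (s).
#' @param interStimulusRest rest between immersions (s).
#' @param postWindow post-stimulus analysis window (s).
#' @return a \linkS4class{ParadigmTimeline}.
#' @examples
#' makeParadigm()                       # secondary onset at 210 s
#' makeParadigm(durations = c(20, 30))  # secondary onset at 200 s
#' @export
makeParadigm <- function(restDuration = 60, baselineWindow = 30,
                         durations = c(primary = 30, secondary = 30),
                         interStimulusRest = 120, postWindow = 15) {
  if (any(c(restDuration, baselineWindow, durations, interStimulusRest,
            postWindow) <= 0))
    stop("invalid paradigm: all durations must be > 0")
  if (length(durations) != 2L)
    stop("invalid paradigm: need two immersion durations")
  onset1 <- restDuration
  onset2 <- onset1 + durations[[1]] + interStimulusRest
  ev <- data.frame(
    label = c("primary_25C", "secondary_5C"),
    onset = c(onset1, onset2),
    duration = as.numeric(durations),
    temperature_C = c(25, 5),
    stringsAsFactors = FALSE
  )
  new("ParadigmTimeline", restDuration = restDuration,
      baselineWindow = baselineWindow, events = ev,
      interStimulusRest = interStimulusRest, postWindow = postWindow)
}

#' @describeIn makeParadigm the event table (label, onset, duration,
#'   temperature_C).
#' @param paradigm a \linkS4class{ParadigmTimeline}.
#' @export
paradigmEvents <- function(paradigm) paradigm@events

#' @describeIn makeParadigm onset of the primary (25 degC) stimulus (s).
#' @export
primaryOnset <- function(paradigm)
  paradigm@events$onset[paradigm@events$label == "primary_25C"]

#' @describeIn makeParadigm total recording length needed to cover the
#'   paradigm with room for the post-stimulus window and return to rest (s).
#' @export
paradigmSpan <- function(paradigm) {
  ev <- paradigm@events
  max(ev$onset + ev$duration) + paradigm@postWindow + 60
}

setMethod("show", "ParadigmTimeline", function(object) {
  cat("ParadigmTimeline: rest", object@restDuration, "s, baseline",
      object@baselineWindow, "s, post-window", object@postWindow, "s\n")
  print(object@events, row.names = FALSE)
})
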