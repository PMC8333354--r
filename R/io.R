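#' Write / read a recording as long-format CSV
#'
#' Canonical interchange format: columns \code{time_s}, \code{channel_id},
#' \code{wavelength_nm}, \code{intensity}.  \code{readRecording} validates
#' the schema, requires both wavelengths per channel and equal series
#' lengths, and reports malformed rows by line number.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @param path CSV file path.
#' @export
writeRecording <- function(rec, path) {
  times <- sampleTimes(rec)
  rows <- do.call(rbind, lapply(c("760", "850"), function(wl) {
    m <- intensity(rec, wl)
    data.frame(time_s = rep(times, each = nrow(m)),
               channel_id = rep(as.integer(rownames(m)), ncol(m)),
               wavelength_nm = as.integer(wl),
               intensity = as.vector(m))
  }))
  rows <- rows[order(rows$channel_id, rows$wavelength_nm, rows$time_s), ]
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecording
#' @param path CSV file path.
#' @param samplingRate Hz (used when times are not equally spaced metadata).
#' @param montage a \linkS4class{Montage} for the result.
#' @param subjectId subject identifier.
#' @return \code{readRecording}: a \linkS4class{NirsRecording}.
#' @export
readRecording <- function(path, samplingRate = 3.91,
                          montage = buildMontage(), subjectId = "S1") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path)
  need <- c("time_s", "channel_id", "wavelength_nm", "intensity")
  if (!all(need %in% names(d)))
    stop("recording CSV is missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(!complete.cases(d[need]))
  if (length(bad))
    stop("malformed recording rows (file line numbers): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  mats <- list()
  chans <- sort(unique(d$channel_id))
  lens <- integer(0)
  for (wl in c(760L, 850L)) {
    sub <- d[d$wavelength_nm == wl, ]
    miss <- setdiff(chans, unique(sub$channel_id))
    if (length(miss))
      stop("channel(s) ", paste(miss, collapse = ", "),
           " lack wavelength ", wl, " nm")
    sub <- sub[order(sub$channel_id, sub$time_s), ]
    cnt <- as.integer(table(sub$channel_id))
    lens <- c(lens, cnt)
    n <- length(unique(sub$time_s))
    if (length(unique(c(cnt, n))) != 1L)
      stop("unequal series lengths across channels/wavelengths")
    mats[[as.character(wl)]] <- matrix(sub$intensity, nrow = length(chans),
                                       ncol = n, byrow = TRUE,
                                       dimnames = list(chans, NULL))
  }
  if (length(unique(lens)) != 1L)
    stop("unequal series lengths across channels/wavelengths")
  times <- sort(unique(d$time_s))
  NirsRecording(mats, samplingRate = samplingRate, montage = montage,
                subjectId = subjectId, times = times)
}

#' Write / read a paradigm timeline as JSON
#' @param paradigm a \linkS4class{ParadigmTimeline}.
#' @param path JSON path.
#' @export
writeParadigm <- function(paradigm, path) {
  jsonlite::write_json(list(
    rest_duration = paradigm@restDuration,
    baseline_window = paradigm@baselineWindow,
    inter_stimulus_rest = paradigm@interStimulusRest,
    post_window = paradigm@postWindow,
    events = paradigmEvents(paradigm)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParadigm
#' @return \code{readParadigm}: a \linkS4class{ParadigmTimeline}.
#' @export
readParadigm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  makeParadigm(restDuration = j$rest_duration,
               baselineWindow = j$baseline_window,
               durations = j$events$duration,
               interStimulusRest = j$inter_stimulus_rest,
               postWindow = j$post_window)
}

#' Default pipeline configuration
#'
#' Every analysis parameter with its protocol default: seed, group sizes,
#' QC threshold (7.5 percent CV), filter band (0.01-0.2 Hz), DPF pair
#' (7.25 / 6.38), separation (3 cm), windows (30 s baseline, 15 s
#' post-stimulus, peak search confined to the stimulation period),
#' delta-HbO* summary method, screening orientation and fixed cutoffs
#' (-0.175 left PFC / -0.205 right PFC), severity split quantile, and AUC
#' CI method.
#'
#' @param ... overrides of the default fields; unknown names are rejected.
#' @return a classed list (\code{PipelineConfig}).
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    seed = 1L,
    n_fibromyalgia = 22L,
    n_control = 19L,
    sampling_rate = 3.91,
    cv_threshold = 7.5,
    band_low = 0.01,
    band_high = 0.2,
    dpf_760 = 7.25,
    dpf_850 = 6.38,
    separation_cm = 3,
    rest_s = 60,
    baseline_window_s = 30,
    inter_stimulus_rest_s = 120,
    post_window_s = 15,
    peak_window_extension_s = 0,
    star_method = "mean",
    screen_orientation = "low_positive",
    severity_orientation = "high_positive",
    severity_quantile = 0.5,
    fixed_cutoff_left_pfc = -0.175,
    fixed_cutoff_right_pfc = -0.205,
    ci_method = "hanley",
    kernel = "offset",
    artifact_rate = 0.05,
    output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  .validateConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$cv_threshold > 0,
            cfg$band_low > 0, cfg$band_low < cfg$band_high,
            cfg$band_high < cfg$sampling_rate / 2,
            cfg$separation_cm > 0, cfg$post_window_s > 0,
            cfg$severity_quantile > 0, cfg$severity_quantile < 1,
            cfg$n_fibromyalgia >= 1, cfg$n_control >= 1)
  invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror \code{\link{pipelineConfig}}; unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  do.call(pipelineConfig, y)
}

#' @rdname pipelineConfig
#' @param config a \code{PipelineConfig}.
#' @param path output YAML path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
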