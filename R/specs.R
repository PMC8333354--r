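## Group-level generator parameters.  Means and standard errors follow the
## study's reported group summaries (feature means per ROI x temperature for
## fibromyalgia n = 22 and controls n = 19); SDs are reconstructed as
## SE * sqrt(n), the only defensible reconstruction from group summaries.

.paramRow <- function(roi, temp, lat, lat_se, dh, dh_se, ds, ds_se) {
  data.frame(roi = roi, temperature = temp,
             latency_mean = lat, latency_se = lat_se,
             dhbo_mean = dh, dhbo_se = dh_se,
             dhbostar_mean = ds, dhbostar_se = ds_se)
}

.fibroParams <- function() rbind(
  .paramRow("left_PFC",  25, 4.95, 0.51, 0.35, 0.05, 0.23, 0.03),
  .paramRow("left_PFC",   5, 6.33, 0.71, 0.41, 0.05, 0.34, 0.06),
  .paramRow("right_PFC", 25, 5.73, 0.67, 0.35, 0.07, 0.22, 0.04),
  .paramRow("right_PFC",  5, 5.74, 0.66, 0.44, 0.06, 0.34, 0.07),
  .paramRow("left_MC",   25, 5.61, 0.52, 0.39, 0.06, 0.17, 0.04),
  .paramRow("left_MC",    5, 6.48, 0.62, 0.57, 0.08, 0.37, 0.06),
  .paramRow("right_MC",  25, 5.36, 0.56, 0.35, 0.05, 0.15, 0.03),
  .paramRow("right_MC",   5, 5.40, 0.78, 0.45, 0.06, 0.24, 0.05))

.controlParams <- function() rbind(
  .paramRow("left_PFC",  25, 7.26, 0.79, 0.39, 0.10, 0.30, 0.05),
  .paramRow("left_PFC",   5, 6.71, 0.81, 0.49, 0.10, 0.53, 0.14),
  .paramRow("right_PFC", 25, 7.08, 0.73, 0.32, 0.05, 0.25, 0.05),
  .paramRow("right_PFC",  5, 6.07, 0.71, 0.44, 0.06, 0.38, 0.08),
  .paramRow("left_MC",   25, 8.09, 0.90, 0.44, 0.06, 0.28, 0.05),
  .paramRow("left_MC",    5, 8.00, 0.73, 0.72, 0.13, 0.54, 0.11),
  .paramRow("right_MC",  25, 6.98, 0.79, 0.50, 0.07, 0.26, 0.05),
  .paramRow("right_MC",   5, 5.53, 0.83, 0.44, 0.05, 0.35, 0.07))

#' Group specification for the synthetic cohort generator
#'
#' Bundles everything the generator needs for one group: the number of
#' subjects, the feature targets (per ROI x temperature: peak latency,
#' delta-HbO and delta-HbO* means and SDs), the immersion-duration model,
#' and the clinical-score model (marginal mean/SD per score plus the rank
#' correlations, through a Gaussian copula, between scores and the left-PFC
#' delta-HbO* at 5 degC).
#'
#' @param group group label, e.g. \code{"fibromyalgia"} or \code{"control"}.
#' @param n number of subjects (>= 1).
#' @param params data.frame with columns roi, temperature, latency_mean,
#'   latency_se, dhbo_mean, dhbo_se, dhbostar_mean, dhbostar_se.  SDs are
#'   derived as \code{se * sqrt(n)}.
#' @param durationRange immersion duration range in s, numeric(2); equal
#'   values give a fixed duration.  Fibromyalgia subjects withdraw at first
#'   pain, modelled as uniform on [10, 30] s; controls complete 30 s.
#' @param clinical list with \code{scores} (data.frame score, mean, sd, min,
#'   max), \code{rho} (named Spearman correlations of each score with the
#'   left-PFC delta-HbO* at 5 degC) and \code{interRho} (Spearman correlation
#'   between the two scores).
#' @param amplitudeCorr latent correlation between the delta-HbO and
#'   delta-HbO* draws of one response (both measure the same curve).
#' @return a validated \code{GroupSpec} (classed list).
#' @export
groupSpec <- function(group, n, params, durationRange = c(30, 30),
                      clinical = NULL, amplitudeCorr = 0.9) {
  stopifnot(n >= 1, is.data.frame(params))
  need <- c("roi", "temperature", "latency_mean", "latency_se",
            "dhbo_mean", "dhbo_se", "dhbostar_mean", "dhbostar_se")
  if (!all(need %in% names(params)))
    stop("params is missing columns: ",
         paste(setdiff(need, names(params)), collapse = ", "))
  if (any(params[grep("_se$", names(params))] < 0))
    stop("standard errors must be >= 0")
  if (abs(amplitudeCorr) > 1) stop("|amplitudeCorr| must be <= 1")
  if (!is.null(clinical) && any(abs(unlist(clinical$rho)) > 1))
    stop("|rho| must be <= 1")
  ## freeze the SE -> SD conversion at the configured group size, so that
  ## simulating a larger cohort from this spec keeps the same per-subject
  ## distribution
  if (!all(c("latency_sd", "dhbo_sd", "dhbostar_sd") %in% names(params))) {
    params$latency_sd <- params$latency_se * sqrt(n)
    params$dhbo_sd <- params$dhbo_se * sqrt(n)
    params$dhbostar_sd <- params$dhbostar_se * sqrt(n)
  }
  structure(list(group = group, n = as.integer(n), params = params,
                 durationRange = durationRange, clinical = clinical,
                 amplitudeCorr = amplitudeCorr),
            class = "GroupSpec")
}

#' Default group specifications
#'
#' The two study groups with their reported sizes (fibromyalgia n = 22,
#' controls n = 19), feature targets per ROI x temperature, immersion
#' behaviour, and clinical-score models: disability due to pain (screening
#' profile total, 0-91) and central sensitization inventory (0-100), with
#' rank correlations 0.40 and 0.60 to the left-PFC delta-HbO* at 5 degC and
#' 0.64 between the scores.
#'
#' @return named list of two \code{GroupSpec}s.
#' @export
defaultGroupSpecs <- function() {
  fmClin <- list(
    scores = data.frame(
      score = c("disability", "csi"),
      mean = c(71.95, 71.18), sd = c(15.56, 13.72),
      min = c(0, 0), max = c(91, 100)),
    rho = c(disability = 0.40, csi = 0.60),
    interRho = 0.64)
  ctClin <- list(
    scores = data.frame(
      score = c("disability", "csi"),
      mean = c(14.11, 21.37), sd = c(15.54, 11.19),
      min = c(0, 0), max = c(91, 100)),
    rho = c(disability = 0.40, csi = 0.60),
    interRho = 0.64)
  list(
    fibromyalgia = groupSpec("fibromyalgia", 22, .fibroParams(),
                             durationRange = c(10, 30), clinical = fmClin),
    control = groupSpec("control", 19, .controlParams(),
                        durationRange = c(30, 30), clinical = ctClin))
}

#' Physiological-noise and artifact specification
#'
#' Additive noise applied to the channel-level hemoglobin series before the
#' optical encoding, plus the motion-artifact model applied to the encoded
#' intensities.  Oscillatory components are sinusoids with per-channel
#' random phase and slight frequency jitter: cardiac (~1.2 Hz), respiratory
#' (~0.25 Hz) and Mayer waves (~0.095 Hz).  Amplitudes are on the
#' concentration scale (mM-labelled); the linear drift slope is drawn per
#' channel from N(0, drift_sd) per second.  Motion artifacts corrupt a
#' channel with probability \code{artifact_rate}, driving its intensity CV
#' to about \code{artifact_cv} percent.
#'
#' @param cardiac,respiratory,mayer lists with \code{freq} (Hz) and
#'   \code{amp} (concentration units).
#' @param white_sd white-noise SD (concentration units).
#' @param drift_sd SD of the per-channel linear drift slope (units/s).
#' @param artifact_rate per-channel corruption probability in [0, 1].
#' @param artifact_cv target intensity CV (percent) for corrupted channels.
#' @return a validated \code{NoiseSpec} (classed list).
#' @export
noiseSpec <- function(cardiac = list(freq = 1.2, amp = 0.008),
                      respiratory = list(freq = 0.25, amp = 0.012),
                      mayer = list(freq = 0.095, amp = 0.01),
                      white_sd = 0.02, drift_sd = 2e-4,
                      artifact_rate = 0.05, artifact_cv = 12) {
  comps <- list(cardiac = cardiac, respiratory = respiratory, mayer = mayer)
  for (nm in names(comps)) {
    cp <- comps[[nm]]
    if (cp$amp < 0) stop(nm, " amplitude must be >= 0")
    if (cp$freq >= 3.91 / 2)
      stop(nm, " frequency must be below the Nyquist frequency (1.955 Hz)")
  }
  if (white_sd < 0 || drift_sd < 0) stop("noise SDs must be >= 0")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must be in [0, 1]")
  structure(c(comps, list(white_sd = white_sd, drift_sd = drift_sd,
                          artifact_rate = artifact_rate,
                          artifact_cv = artifact_cv)),
            class = "NoiseSpec")
}

#' A noise specification with every component switched off
#' @return a \code{NoiseSpec} with all amplitudes and rates 0.
#' @export
silentNoiseSpec <- function() {
  noiseSpec(cardiac = list(freq = 1.2, amp = 0),
            respiratory = list(freq = 0.25, amp = 0),
            mayer = list(freq = 0.095, amp = 0),
            white_sd = 0, drift_sd = 0, artifact_rate = 0, artifact_cv = 12)
}
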