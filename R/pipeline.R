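## End-to-end pipeline: synthesis (or supplied recordings) -> QC ->
## optical density -> band-pass -> modified Beer-Lambert -> ROI features ->
## group statistics -> ROC screening, with a reproducibility manifest.

.stageStop <- function(stage, e) {
  stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
}

.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg)[order(names(unclass(cfg)))], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

.cfgGroups <- function(cfg) {
  gs <- defaultGroupSpecs()
  gs$fibromyalgia$n <- as.integer(cfg$n_fibromyalgia)
  gs$control$n <- as.integer(cfg$n_control)
  gs
}

.cfgParadigm <- function(cfg) {
  makeParadigm(restDuration = cfg$rest_s,
               baselineWindow = cfg$baseline_window_s,
               interStimulusRest = cfg$inter_stimulus_rest_s,
               postWindow = cfg$post_window_s)
}

.cfgNoise <- function(cfg) noiseSpec(artifact_rate = cfg$artifact_rate)

## preprocess + feature extraction for one subject
.subjectFeatures <- function(rec, paradigm, cfg) {
  pre <- tryCatch(
    preprocessRecording(rec, cvThreshold = cfg$cv_threshold,
                        band = c(cfg$band_low, cfg$band_high),
                        dpf = c("760" = cfg$dpf_760, "850" = cfg$dpf_850)),
    error = function(e) .stageStop(paste0("preprocess ", subjectId(rec)), e))
  mont <- metadata(rec)$montage
  roiHb <- tryCatch(
    roiAverage(pre$hb, mont, pre$mask),
    error = function(e) .stageStop(paste0("roi ", subjectId(rec)), e))
  fe <- tryCatch(
    extractFeatures(roiHb, paradigm,
                    peakWindowExtension = cfg$peak_window_extension_s,
                    starMethod = cfg$star_method),
    error = function(e) .stageStop(paste0("features ", subjectId(rec)), e))
  list(features = fe, qc = pre$qc)
}

#' Run the full analysis pipeline
#'
#' Generates (or consumes) a cohort, preprocesses every subject, extracts
#' the per-ROI features, fits the group x temperature GEE models per ROI and
#' outcome, builds the correlation and severity models within the patient
#' group, and performs the ROC screening analyses.  Fully deterministic for
#' a fixed seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param cohort optional pre-built cohort as returned by
#'   \code{\link{generateCohort}}; when NULL one is generated from the
#'   configuration (streamed subject by subject to bound memory).
#' @return list: \code{features} (tidy table), \code{metadata}, \code{qc}
#'   (per-subject rejection tables), \code{stats} (GEE results, cohort
#'   characterization, Spearman table, severity GLMs), \code{screening}
#'   (group ROC per PFC side and severity screens), \code{truth} (when
#'   simulated), \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig(), cohort = NULL) {
  t0 <- Sys.time()
  paradigmTemplate <- .cfgParadigm(config)
  featRows <- list(); qcList <- list(); rejected <- 0L
  if (is.null(cohort)) {
    groups <- .cfgGroups(config)
    noise <- .cfgNoise(config)
    montage <- buildMontage(separation = config$separation_cm)
    set.seed(config$seed)
    metaRows <- list(); truthRows <- list()
    for (g in groups) {
      for (i in seq_len(g$n)) {
        sid <- sprintf("%s_%02d", substr(g$group, 1, 2), i)
        s <- .generateSubjectRecording(g, sid, paradigmTemplate, noise,
                                       c(config$band_low, config$band_high),
                                       montage, config$kernel,
                                       config$sampling_rate)
        metaRows[[sid]] <- s$metadata
        truthRows[[sid]] <- s$truth
        sf <- .subjectFeatures(s$recording, s$paradigm, config)
        featRows[[sid]] <- cbind(subject = sid, group = g$group, sf$features)
        qcList[[sid]] <- sf$qc
        rejected <- rejected + sum(sf$qc$rejected)
      }
    }
    metadata <- do.call(rbind, c(metaRows, list(make.row.names = FALSE)))
    truth <- do.call(rbind, c(truthRows, list(make.row.names = FALSE)))
  } else {
    metadata <- cohort$metadata
    truth <- cohort$truth
    for (sid in names(cohort$recordings)) {
      rec <- cohort$recordings[[sid]]
      par <- cohort$paradigms[[sid]]
      grp <- metadata$group[metadata$subject == sid]
      sf <- .subjectFeatures(rec, par, config)
      featRows[[sid]] <- cbind(subject = sid, group = grp, sf$features)
      qcList[[sid]] <- sf$qc
      rejected <- rejected + sum(sf$qc$rejected)
    }
  }
  features <- do.call(rbind, c(featRows, list(make.row.names = FALSE)))

  stats <- tryCatch(.pipelineStats(features, metadata),
                    error = function(e) .stageStop("stats", e))
  screening <- tryCatch(.pipelineScreening(features, metadata, config),
                        error = function(e) .stageStop("screening", e))

  nSubj <- length(unique(features$subject))
  manifest <- list(
    package_version = as.character(packageVersion("thermoHb")),
    config_hash = .configHash(config),
    seed = config$seed,
    subjects_in = nrow(metadata),
    subjects_analyzed = nSubj,
    subjects_excluded = nrow(metadata) - nSubj,
    channels_rejected = rejected,
    rois_missing = sum(is.na(features$peak_latency)) / 2,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  out <- list(features = features, metadata = metadata, qc = qcList,
              stats = stats, screening = screening, truth = truth,
              manifest = manifest)
  if (!is.null(config$output_dir)) .writePipelineOutputs(out, config)
  out
}

.pipelineStats <- function(features, metadata) {
  rois <- unique(features$roi)
  outcomes <- c("peak_latency", "delta_hbo", "delta_hbo_star")
  ## degenerate layouts (e.g. < 2 subjects per group) yield NA rows rather
  ## than aborting the whole run
  gee <- do.call(rbind, lapply(rois, function(r)
    do.call(rbind, lapply(outcomes, function(o)
      tryCatch(geeWald(features, o, r), error = function(e)
        data.frame(roi = r, outcome = o,
                   effect = c("group", "temperature", "interaction"),
                   wald_chisq = NA_real_, df = 1, p = NA_real_,
                   cramers_v = NA_real_, n_subjects = NA_integer_,
                   alpha = NA_real_))))))
  scoreCols <- intersect(c("disability", "csi"), names(metadata))
  characterization <- characterizeCohort(
    metadata, vars = c(scoreCols, "duration_primary_s",
                       "duration_secondary_s"))
  ## Spearman table within the patient group: scores vs delta-HbO* (5 degC)
  fmIds <- metadata$subject[metadata$group == "fibromyalgia"]
  fm5 <- features[features$subject %in% fmIds & features$temperature == 5, ]
  wide <- stats::reshape(fm5[, c("subject", "roi", "delta_hbo_star")],
                         idvar = "subject", timevar = "roi",
                         direction = "wide")
  names(wide) <- sub("^delta_hbo_star\\.", "dhbostar_", names(wide))
  md <- metadata[match(wide$subject, metadata$subject),
                 c("subject", scoreCols)]
  tab <- cbind(md[scoreCols], wide[setdiff(names(wide), "subject")])
  spear <- spearmanTable(tab)
  ## severity models on bilateral PFC delta-HbO*
  sev <- lapply(setNames(scoreCols, scoreCols), function(sc)
    tryCatch(glmSeverity(md[[sc]], wide$dhbostar_left_PFC,
                         wide$dhbostar_right_PFC),
             error = function(e) conditionMessage(e)))
  list(gee = gee, characterization = characterization, spearman = spear,
       severity_glm = sev)
}

.pipelineScreening <- function(features, metadata, cfg) {
  f5 <- features[features$temperature == 5, ]
  grp <- metadata$group[match(f5$subject, metadata$subject)]
  out <- list()
  for (side in c("left_PFC", "right_PFC")) {
    sel <- f5$roi == side & !is.na(f5$delta_hbo_star)
    out[[paste0("group_", side)]] <- rocCurve(
      f5$delta_hbo_star[sel], grp[sel] == "fibromyalgia",
      orientation = cfg$screen_orientation, ciMethod = cfg$ci_method)
  }
  cutoffs <- c(left_PFC = cfg$fixed_cutoff_left_pfc,
               right_PFC = cfg$fixed_cutoff_right_pfc)
  scoreCols <- intersect(c("disability", "csi"), names(metadata))
  fmIds <- metadata$subject[metadata$group == "fibromyalgia"]
  for (sc in scoreCols) {
    for (side in c("left_PFC", "right_PFC")) {
      sel <- f5$roi == side & f5$subject %in% fmIds &
        !is.na(f5$delta_hbo_star)
      feat <- f5$delta_hbo_star[sel]
      cli <- metadata[[sc]][match(f5$subject[sel], metadata$subject)]
      out[[paste0("severity_", sc, "_", side)]] <- tryCatch(
        severityScreen(feat, cli, fixedCutoffs = unname(cutoffs[side]),
                       quantileSplit = cfg$severity_quantile,
                       orientation = cfg$severity_orientation),
        error = function(e) conditionMessage(e))
    }
  }
  out
}

.writePipelineOutputs <- function(out, cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$output_dir, f)
  write.csv(out$features, pth("features.csv"), row.names = FALSE)
  write.csv(out$metadata, pth("metadata.csv"), row.names = FALSE)
  write.csv(out$stats$gee, pth("gee.csv"), row.names = FALSE)
  rocRows <- do.call(rbind, lapply(names(out$screening), function(nm) {
    x <- out$screening[[nm]]
    roc <- if (is(x, "RocResult")) x else if (is.list(x)) x$roc else NULL
    if (is.null(roc)) return(NULL)
    data.frame(analysis = nm, auc = roc@auc, ci_lower = roc@ci[1],
               ci_upper = roc@ci[2], youden_cutoff = roc@cutoff,
               j = roc@j)
  }))
  write.csv(rocRows, pth("roc.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    gee = out$stats$gee,
    spearman_rho = out$stats$spearman$rho,
    roc = rocRows,
    manifest = out$manifest
  ), pth("stats.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(out$manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
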