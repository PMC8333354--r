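#' ROC screening result
#'
#' Empirical ROC analysis of a continuous biomarker against a binary label:
#' the cutoff table at every attained score value, the trapezoidal AUC
#' (equal to the normalized Mann-Whitney U statistic), its confidence
#' interval, and the Youden-optimal cutoff.
#'
#' @slot table data.frame: cutoff, sensitivity, one_minus_specificity,
#'   specificity, youden_j (cutoffs at attained score values).
#' @slot auc numeric(1).
#' @slot ci numeric(2) confidence interval for the AUC.
#' @slot ciMethod character.
#' @slot cutoff Youden-optimal cutoff.
#' @slot j Youden index at that cutoff.
#' @slot orientation \code{"low_positive"} (positives score low) or
#'   \code{"high_positive"}.
#' @slot n numeric(2): positives, negatives.
#' @export
setClass("RocResult", slots = c(
  table = "data.frame", auc = "numeric", ci = "numeric",
  ciMethod = "character", cutoff = "numeric", j = "numeric",
  orientation = "character", n = "numeric"
))

setValidity("RocResult", function(object) {
  tb <- object@table
  msg <- character()
  if (any(tb$sensitivity < -1e-12 | tb$sensitivity > 1 + 1e-12) ||
      any(tb$specificity < -1e-12 | tb$specificity > 1 + 1e-12))
    msg <- c(msg, "sensitivity/specificity must lie in [0, 1]")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "AUC must be in [0, 1]")
  if (is.unsorted(tb$cutoff)) msg <- c(msg, "cutoff table must be ordered")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RocResult", function(object) {
  cat("RocResult (", object@orientation, "): AUC = ",
      signif(object@auc, 3), " [", signif(object@ci[1], 3), ", ",
      signif(object@ci[2], 3), "] (", object@ciMethod, ")\n",
      "Youden cutoff ", signif(object@cutoff, 4), " (J = ",
      signif(object@j, 3), "); ", object@n[1], " positives / ",
      object@n[2], " negatives\n", sep = "")
})

.positiveScore <- function(scores, orientation) {
  if (orientation == "low_positive") -scores else scores
}

#' Empirical ROC curve
#'
#' ROC over all attained score values.  Under \code{"high_positive"} a case
#' is called positive when its score is >= the cutoff; under
#' \code{"low_positive"} when it is <= the cutoff.  The AUC is the
#' trapezoidal area, identical to the normalized Mann-Whitney U statistic
#' (ties credited 1/2).
#'
#' @param scores numeric biomarker values.
#' @param labels logical or two-level vector; TRUE / \code{positive} marks
#'   the positive class.
#' @param orientation \code{"high_positive"} or \code{"low_positive"}.
#' @param positive value of \code{labels} identifying the positive class
#'   when \code{labels} is not logical.
#' @param ciMethod AUC CI method, see \code{\link{aucCI}}.
#' @return a \linkS4class{RocResult}.
#' @examples
#' r <- rocCurve(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))
#' aucOf(r)  # 0.75
#' @export
rocCurve <- function(scores, labels, orientation = c("high_positive",
                                                     "low_positive"),
                     positive = NULL, ciMethod = "hanley") {
  orientation <- match.arg(orientation)
  if (!is.logical(labels)) {
    if (is.null(positive)) {
      lv <- sort(unique(as.character(labels)))
      if (length(lv) != 2) stop("labels must have exactly two levels")
      positive <- lv[2]
    }
    labels <- as.character(labels) == positive
  }
  ok <- complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  s <- .positiveScore(scores, orientation)
  ## Mann-Whitney U with half credit for ties
  pos <- s[labels]; neg <- s[!labels]
  gt <- vapply(pos, function(v) sum(v > neg) + 0.5 * sum(v == neg),
               numeric(1))
  auc <- sum(gt) / (n1 * n0)
  cuts <- sort(unique(scores))
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    call <- if (orientation == "high_positive") scores >= cuts[i]
            else scores <= cuts[i]
    sens[i] <- sum(call & labels) / n1
    spec[i] <- sum(!call & !labels) / n0
  }
  tb <- data.frame(cutoff = cuts, sensitivity = sens,
                   one_minus_specificity = 1 - spec, specificity = spec,
                   youden_j = sens + spec - 1)
  ## Youden: max J, ties -> higher sensitivity, then smaller |cutoff|
  o <- order(-tb$youden_j, -tb$sensitivity, abs(tb$cutoff))
  bestRow <- tb[o[1], ]
  res <- new("RocResult", table = tb, auc = auc, ci = c(NA_real_, NA_real_),
             ciMethod = ciMethod, cutoff = bestRow$cutoff,
             j = bestRow$youden_j, orientation = orientation,
             n = c(positives = n1, negatives = n0))
  res@ci <- aucCI(res, method = ciMethod)
  validObject(res)
  res
}

#' @rdname rocCurve
#' @param roc a \linkS4class{RocResult}.
#' @export
aucOf <- function(roc) roc@auc

#' @rdname rocCurve
#' @export
youdenCutoff <- function(roc) roc@cutoff

#' Confidence interval for an AUC
#'
#' Default: the Hanley-McNeil standard-error interval
#' \eqn{AUC \pm 1.96 \, SE} with
#' \eqn{SE^2 = (A(1-A) + (n_1-1)(Q_1-A^2) + (n_0-1)(Q_2-A^2))/(n_1 n_0)},
#' \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}, clipped to [0, 1].
#' Alternatively a seeded percentile bootstrap (resampling within classes).
#'
#' @param roc a \linkS4class{RocResult}.
#' @param method \code{"hanley"} or \code{"bootstrap"}.
#' @param level confidence level.
#' @param nboot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param scores,labels original data, required for the bootstrap.
#' @return numeric(2) (lower, upper).
#' @export
aucCI <- function(roc, method = c("hanley", "bootstrap"), level = 0.95,
                  nboot = 2000, seed = 1, scores = NULL, labels = NULL) {
  method <- match.arg(method)
  A <- roc@auc
  n1 <- roc@n[[1]]; n0 <- roc@n[[2]]
  if (method == "hanley") {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    se <- sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) +
                (n0 - 1) * (q2 - A^2)) / (n1 * n0))
    if ((A == 0 || A == 1) && (n1 + n0) < 10)
      warning("degenerate AUC with tiny n: interval clipped")
    z <- qnorm(1 - (1 - level) / 2)
    return(pmin(pmax(c(A - z * se, A + z * se), 0), 1))
  }
  if (is.null(scores) || is.null(labels))
    stop("bootstrap CI needs the original scores and labels")
  if (!is.logical(labels)) stop("labels must be logical for the bootstrap")
  set.seed(seed)
  ip <- which(labels); ineg <- which(!labels)
  reps <- vapply(seq_len(nboot), function(b) {
    i <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    s <- .positiveScore(scores[i], roc@orientation)
    l <- labels[i]
    pos <- s[l]; neg <- s[!l]
    gt <- vapply(pos, function(v) sum(v > neg) + 0.5 * sum(v == neg),
                 numeric(1))
    sum(gt) / (sum(l) * sum(!l))
  }, numeric(1))
  unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Classifies by the orientation rule (\code{low_positive}: positive when
#' score <= cutoff; \code{high_positive}: score >= cutoff) and returns the
#' empirical rates.
#'
#' @inheritParams rocCurve
#' @param cutoff finite cutoff value.
#' @return named numeric(2): sensitivity, specificity.
#' @export
applyCutoff <- function(scores, labels, cutoff, orientation = c(
                          "high_positive", "low_positive"), positive = NULL) {
  orientation <- match.arg(orientation)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (!is.logical(labels)) {
    if (is.null(positive)) stop("supply 'positive' for non-logical labels")
    labels <- as.character(labels) == positive
  }
  if (!any(labels) || all(labels)) stop("both classes must be present")
  call <- if (orientation == "high_positive") scores >= cutoff
          else scores <= cutoff
  c(sensitivity = sum(call & labels) / sum(labels),
    specificity = sum(!call & !labels) / sum(!labels))
}

#' Severity screening within the patient group
#'
#' Dichotomizes a clinical severity score (default: median split, strictly
#' above the quantile = severe) and evaluates a delta-HbO* feature as a
#' screening marker for the severe stratum: full ROC plus sensitivity /
#' specificity at externally fixed cutoffs (e.g. the group-discrimination
#' cutoffs).  The dichotomization rule is a reporting choice, not a
#' clinical standard, and is recorded in the result.
#'
#' @param feature numeric delta-HbO* values (one per subject).
#' @param clinical numeric severity scores, same length.
#' @param fixedCutoffs optional numeric vector of cutoffs to evaluate.
#' @param quantileSplit quantile for the severity split (default 0.5).
#' @param orientation passed to \code{\link{rocCurve}}; the default
#'   \code{"high_positive"} matches the positive feature-severity
#'   correlation.
#' @return list: \code{roc} (\linkS4class{RocResult}), \code{fixed}
#'   (data.frame cutoff, sensitivity, specificity), \code{rule}.
#' @export
severityScreen <- function(feature, clinical, fixedCutoffs = NULL,
                           quantileSplit = 0.5,
                           orientation = "high_positive") {
  ok <- complete.cases(feature, clinical)
  feature <- feature[ok]; clinical <- clinical[ok]
  thr <- quantile(clinical, quantileSplit, names = FALSE)
  severe <- clinical > thr
  if (!any(severe) || all(severe))
    stop("degenerate severity split: one class is empty")
  roc <- rocCurve(feature, severe, orientation = orientation)
  fixed <- NULL
  if (!is.null(fixedCutoffs)) {
    fixed <- do.call(rbind, lapply(fixedCutoffs, function(cv) {
      ss <- applyCutoff(feature, severe, cv, orientation = orientation)
      data.frame(cutoff = cv, sensitivity = ss[["sensitivity"]],
                 specificity = ss[["specificity"]])
    }))
  }
  list(roc = roc, fixed = fixed,
       rule = sprintf("severe = score > %g (quantile %.2f)", thr,
                      quantileSplit))
}
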