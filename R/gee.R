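#' Generalized estimating equations for clustered Gaussian outcomes
#'
#' Marginal linear model fitted by generalized estimating equations with an
#' exchangeable (or independence) working correlation and robust sandwich
#' covariance.  Designed for the repeated-measures layout of the thermal
#' paradigm (two observations -- 25 degC and 5 degC -- per subject), but
#' handles arbitrary cluster sizes.
#'
#' With the independence working structure the coefficient estimates equal
#' ordinary least squares and the sandwich covariance equals the
#' cluster-robust (CR0) OLS covariance, which is used as an oracle
#' equivalence in the test-suite.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @param id cluster identifier (bare column name as string).
#' @param corstr working correlation: \code{"exchangeable"} or
#'   \code{"independence"}.
#' @param maxit,tol iteration control.
#' @return object of class \code{geeFit}: coefficients, robust covariance
#'   \code{vcov}, working correlation \code{alpha}, scale \code{phi},
#'   \code{wald} table (per-coefficient Wald chi-square, df 1, p).
#' @export
geeFit <- function(formula, data, id, corstr = c("exchangeable",
                                                 "independence"),
                   maxit = 50, tol = 1e-10) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  idv <- data[[id]]
  dropped <- attr(mf, "na.action")
  if (!is.null(dropped)) idv <- idv[-dropped]
  cl <- factor(idv)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  p <- ncol(X)
  idx <- split(seq_along(y), cl)
  beta <- qr.solve(X, y)
  alpha <- 0
  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (length(y) - p)
    if (corstr == "exchangeable") {
      num <- 0; npair <- 0
      for (ix in idx) {
        if (length(ix) < 2) next
        ri <- r[ix]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        npair <- npair + choose(length(ix), 2)
      }
      alpha <- if (npair > p) (num / phi) / (npair - p) else 0
      nmax <- max(lengths(idx))
      alpha <- min(max(alpha, -1 / (nmax - 1) + 1e-6), 1 - 1e-6)
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in idx) {
      ni <- length(ix)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Wi <- solve(Ri) / phi
      Xi <- X[ix, , drop = FALSE]
      A <- A + crossprod(Xi, Wi %*% Xi)
      b <- b + crossprod(Xi, Wi %*% y[ix])
    }
    betaNew <- solve(A, b)
    done <- max(abs(betaNew - beta)) < tol
    beta <- betaNew
    if (done || corstr == "independence") break
  }
  r <- y - X %*% beta
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in idx) {
    ni <- length(ix)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Wi <- solve(Ri) / phi
    Xi <- X[ix, , drop = FALSE]
    ui <- crossprod(Xi, Wi %*% r[ix])
    B <- B + crossprod(Xi, Wi %*% Xi)
    M <- M + tcrossprod(ui)
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  se <- sqrt(diag(V))
  wald <- (as.vector(beta) / se)^2
  out <- list(coefficients = setNames(as.vector(beta), colnames(X)),
              vcov = V, alpha = alpha, phi = phi,
              n_clusters = length(idx), n_obs = length(y),
              wald = data.frame(term = colnames(X),
                                estimate = as.vector(beta), se = se,
                                wald_chisq = wald, df = 1,
                                p = pchisq(wald, 1, lower.tail = FALSE)),
              corstr = corstr, formula = formula)
  class(out) <- "geeFit"
  out
}

#' @export
print.geeFit <- function(x, ...) {
  cat("GEE (", x$corstr, " working correlation), ", x$n_clusters,
      " clusters / ", x$n_obs, " observations; alpha = ",
      signif(x$alpha, 3), "\n", sep = "")
  print(x$wald, row.names = FALSE)
  invisible(x)
}

#' Group x temperature GEE comparison for one ROI and outcome
#'
#' Fits, for one ROI, the marginal model
#' \code{outcome ~ group + temperature + group:temperature} with subject as
#' the cluster (two observations per subject, one per temperature), an
#' exchangeable working correlation and sandwich covariance, and reports the
#' Wald chi-square (df 1), p-value and Cramer's V for the group effect, the
#' temperature effect and their interaction.
#'
#' @param features tidy feature table (columns subject, group, roi,
#'   temperature and the outcome).
#' @param outcome outcome column: \code{"peak_latency"}, \code{"delta_hbo"}
#'   or \code{"delta_hbo_star"}.
#' @param roi ROI label to analyse.
#' @param corstr working correlation (default exchangeable).
#' @return data.frame: effect, wald_chisq, df, p, cramers_v (V computed with
#'   the number of subjects in the model).
#' @export
geeWald <- function(features, outcome, roi,
                    corstr = "exchangeable") {
  d <- features[features$roi == roi & !is.na(features[[outcome]]), ]
  keep <- names(which(table(d$subject) == 2))
  d <- d[d$subject %in% keep, ]
  if (length(unique(d$group)) < 2)
    stop("both groups must be present for ROI ", roi)
  if (min(table(unique(d[, c("subject", "group")])$group)) < 2)
    stop("need at least two subjects per group")
  d$y <- d[[outcome]]
  d$group <- factor(d$group)
  d$temperature <- factor(d$temperature, levels = c(25, 5))
  fit <- geeFit(y ~ group * temperature, d, id = "subject", corstr = corstr)
  w <- fit$wald
  eff <- c("group", "temperature", "interaction")
  rows <- w[match(c(grep("^group", w$term, value = TRUE)[1],
                    grep("^temperature", w$term, value = TRUE)[1],
                    grep(":", w$term, value = TRUE)[1]), w$term), ]
  nsub <- length(unique(d$subject))
  data.frame(roi = roi, outcome = outcome, effect = eff,
             wald_chisq = rows$wald_chisq, df = 1, p = rows$p,
             cramers_v = cramersV(rows$wald_chisq, nsub),
             n_subjects = nsub, alpha = fit$alpha)
}
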