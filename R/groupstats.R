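#' Cramer's V effect size from a Wald chi-square
#'
#' \eqn{V = \sqrt{\chi^2 / (n \cdot df)}}.  With df = 1 the conventional
#' interpretation is small 0.1, medium 0.3, large 0.5.
#'
#' @param chi2 chi-square statistic (>= 0).
#' @param n total number of subjects in the model (> 0).
#' @param df degrees of freedom of the comparison.
#' @return V (full precision; round for reporting).
#' @examples
#' round(cramersV(5.33, 41), 2)   # 0.36
#' round(cramersV(13.15, 41), 2)  # 0.57
#' @export
cramersV <- function(chi2, n, df = 1) {
  if (any(chi2 < 0)) stop("chi2 must be >= 0")
  if (any(n <= 0)) stop("n must be > 0")
  sqrt(chi2 / (n * df))
}

#' Between-group cohort characterization
#'
#' Per-variable group comparison of a two-group metadata table:
#' Mann-Whitney U (Wilcoxon rank-sum, tie-corrected) for continuous
#' variables and Fisher's exact test for categorical ones, alongside group
#' means/SDs or counts.
#'
#' @param metadata data.frame with a group column.
#' @param groupCol name of the group column.
#' @param vars variables to compare (default: all other columns).
#' @return data.frame: variable, type, per-group summary, p.
#' @export
characterizeCohort <- function(metadata, groupCol = "group", vars = NULL) {
  g <- factor(metadata[[groupCol]])
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("exactly two non-empty groups are required")
  if (is.null(vars))
    vars <- setdiff(names(metadata), c(groupCol, "subject"))
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    x <- metadata[[v]]
    if (is.numeric(x)) {
      p <- suppressWarnings(wilcox.test(x ~ g, exact = FALSE)$p.value)
      data.frame(variable = v, type = "continuous",
                 mean_1 = mean(x[g == lv[1]], na.rm = TRUE),
                 sd_1 = sd(x[g == lv[1]], na.rm = TRUE),
                 mean_2 = mean(x[g == lv[2]], na.rm = TRUE),
                 sd_2 = sd(x[g == lv[2]], na.rm = TRUE),
                 p = p)
    } else {
      tab <- table(x, g)
      p <- fisher.test(tab)$p.value
      data.frame(variable = v, type = "categorical",
                 mean_1 = NA, sd_1 = NA, mean_2 = NA, sd_2 = NA, p = p)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}

#' Spearman correlation table
#'
#' Pairwise Spearman rank correlations (ties mid-ranked) with two-tailed
#' p-values, flagged at the 0.05 and 0.01 levels.  Constant columns give
#' undefined (NA) cells.
#'
#' @param data data.frame of numeric variables.
#' @return list: \code{rho}, \code{p} (matrices), \code{flags} (character
#'   matrix: "", "*" p < 0.05, "**" p < 0.01).
#' @export
spearmanTable <- function(data) {
  data <- as.data.frame(data)
  k <- ncol(data)
  nm <- names(data)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- data[[i]]; y <- data[[j]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  flags <- ifelse(is.na(p), "", ifelse(p < 0.01, "**",
                                       ifelse(p < 0.05, "*", "")))
  diag(flags) <- ""
  list(rho = rho, p = p, flags = flags)
}

#' Severity model: clinical score on bilateral PFC delta-HbO*
#'
#' Linear model of one clinical severity score on the left- and right-PFC
#' delta-HbO* values (plus intercept), reporting per coefficient the
#' estimate B, its standard error, the Wald 95 percent CI, the Wald
#' chi-square (df 1) and p-value.
#'
#' @param outcome numeric clinical score.
#' @param leftPfc,rightPfc delta-HbO* predictor vectors (mM).
#' @return data.frame, one row per coefficient.
#' @export
glmSeverity <- function(outcome, leftPfc, rightPfc) {
  ok <- complete.cases(outcome, leftPfc, rightPfc)
  if (sum(ok) < 10) stop("need at least 10 complete cases")
  if (abs(cor(leftPfc[ok], rightPfc[ok])) > 0.999)
    stop("predictors are collinear")
  fit <- lm(outcome ~ leftPfc + rightPfc, subset = ok)
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  wald <- (b / se)^2
  ## an exactly constant outcome carries no evidence of association
  degenerate <- !is.finite(se) |
    suppressWarnings(summary(fit))$sigma < 1e-10 * (abs(mean(outcome[ok])) + 1)
  wald[degenerate & abs(b) < 1e-8] <- 0
  z <- qnorm(0.975)
  data.frame(term = names(b), B = unname(b), se = unname(se),
             ci_lower = unname(b - z * se), ci_upper = unname(b + z * se),
             wald_chisq = unname(wald), df = 1,
             p = pchisq(unname(wald), 1, lower.tail = FALSE))
}

#' A priori sample size for a multiple-regression omnibus test
#'
#' Smallest N whose noncentral-F power for the omnibus test of a linear
#' regression with \code{predictors} terms reaches the target, using
#' noncentrality \eqn{\lambda = f^2 N} with numerator df = predictors and
#' denominator df = N - predictors - 1, then inflated for expected attrition.
#'
#' @param effectSize effect size (> 0).
#' @param alpha type-I error rate.
#' @param power target power.
#' @param predictors number of predictors.
#' @param inflation attrition inflation fraction (default 0.10).
#' @param type how \code{effectSize} is interpreted: Cohen's \code{"f2"}
#'   (default) or \code{"f"} (squared internally).
#' @param maxN search bound.
#' @return list: \code{base_n}, \code{inflated_n}, \code{power}.
#' @export
sampleSizeRegression <- function(effectSize, alpha = 0.05, power = 0.80,
                                 predictors = 2, inflation = 0.10,
                                 type = c("f2", "f"), maxN = 10000) {
  type <- match.arg(type)
  if (effectSize <= 0) stop("effectSize must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  f2 <- if (type == "f2") effectSize else effectSize^2
  u <- predictors
  pw <- function(N) {
    v <- N - u - 1
    if (v < 1) return(0)
    1 - pf(qf(1 - alpha, u, v), u, v, ncp = f2 * N)
  }
  for (N in (u + 2):maxN) {
    if (pw(N) >= power)
      return(list(base_n = N,
                  inflated_n = as.integer(ceiling(N * (1 + inflation))),
                  power = pw(N)))
  }
  stop("target power not reachable within maxN subjects")
}
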