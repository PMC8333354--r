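test_that("Cramer's V matches the reported worked examples and scales", {
  expect_equal(roundHalfUp(cramersV(5.33, 41), 2), 0.36)
  expect_equal(roundHalfUp(cramersV(13.15, 41), 2), 0.57)
  expect_equal(cramersV(0, 41), 0)
  ## scale consistency: V(c chi2, c n) = V(chi2, n)
  expect_equal(cramersV(3 * 5.33, 3 * 41), cramersV(5.33, 41))
  expect_error(cramersV(5.33, 0), "n must be")
  expect_error(cramersV(-1, 41), ">= 0")
})

test_that("cohort characterization applies the right test per variable type", {
  set.seed(20)
  md <- data.frame(
    group = rep(c("a", "b"), each = 20),
    same = rep(c(1, 2), 20),
    shifted = c(rnorm(20, 0), rnorm(20, 3)),   # 3 SD shift
    cat = factor(rep(c("x", "y"), c(20, 20)))  # perfectly separated 2x2
  )
  out <- characterizeCohort(md)
  expect_gt(out$p[out$variable == "same"], 0.9)
  expect_lt(out$p[out$variable == "shifted"], 0.001)
  ## Fisher exact on the (20,0 / 0,20)-style table; frozen hand value for
  ## the 10/10 case: 2 / choose(20, 10)
  md10 <- data.frame(group = rep(c("a", "b"), each = 10),
                     cat = factor(rep(c("x", "y"), c(10, 10))))
  p10 <- characterizeCohort(md10)$p
  expect_equal(p10, 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(characterizeCohort(md[md$group == "a", ]), "two non-empty")
})

test_that("GEE with independence working correlation equals robust OLS", {
  skip_if_not_installed("sandwich")
  set.seed(22)
  n <- 40
  d <- data.frame(subject = rep(1:n, each = 2),
                  group = rep(rep(c("fm", "ct"), each = 2), n / 2),
                  temperature = rep(c(25, 5), n))
  d$y <- rnorm(2 * n)
  d$temperature <- factor(d$temperature, levels = c(25, 5))
  fit <- geeFit(y ~ group * temperature, d, id = "subject",
                corstr = "independence")
  ols <- lm(y ~ group * temperature, d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  vc <- sandwich::vcovCL(ols, cluster = d$subject, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$vcov), unname(vc), tolerance = 1e-8)
  wOls <- unname(coef(ols)^2 / diag(vc))
  expect_equal(unname(fit$wald$wald_chisq), wOls, tolerance = 1e-6)
  ## singleton clusters reproduce heteroskedasticity-robust (HC0) OLS
  d$one <- seq_len(nrow(d))
  fit1 <- geeFit(y ~ group * temperature, d, id = "one",
                 corstr = "exchangeable")
  vc1 <- sandwich::vcovHC(ols, type = "HC0")
  expect_equal(unname(fit1$vcov), unname(vc1), tolerance = 1e-8)
})

test_that("GEE holds its size under the null and detects a 1 SD shift", {
  ## null data: each effect is rejected at ~ the nominal 5% rate
  set.seed(23)
  rej <- c(group = 0, temp = 0, int = 0)
  for (r in 1:200) {
    n <- 30
    d <- data.frame(subject = rep(1:n, each = 2),
                    group = rep(rep(c("fm", "ct"), each = 2), n / 2),
                    temperature = factor(rep(c(25, 5), n),
                                         levels = c(25, 5)))
    d$y <- 1 + rnorm(2 * n)
    fit <- geeFit(y ~ group * temperature, d, id = "subject")
    rej <- rej + (fit$wald$p[-1] < 0.05)
  }
  ## sandwich covariances run slightly liberal in small samples
  expect_true(all(rej / 200 < 0.15))

  ## power: temperature effect of 1 SD, 50 subjects/group, 200 replicates
  hits <- 0
  for (r in 1:200) {
    n2 <- 100
    dd <- data.frame(subject = rep(1:n2, each = 2),
                     group = rep(rep(c("fm", "ct"), each = 2), n2 / 2),
                     temperature = factor(rep(c(25, 5), n2),
                                          levels = c(25, 5)))
    dd$y <- (dd$temperature == 5) * 1 + rnorm(2 * n2)
    ft <- geeFit(y ~ group * temperature, dd, id = "subject")
    p <- ft$wald$p[ft$wald$term == "temperature5"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 200, 0.8)
})

test_that("geeWald reports the three effects with subject-count Cramer's V", {
  set.seed(24)
  subj <- sprintf("s%02d", 1:20)
  fe <- expand.grid(subject = subj, temperature = c(25, 5))
  fe$group <- ifelse(as.integer(sub("s", "", fe$subject)) <= 10,
                     "fibromyalgia", "control")
  fe$roi <- "left_PFC"
  fe$delta_hbo_star <- rnorm(nrow(fe), 0.3, 0.05) +
    0.15 * (fe$temperature == 5)
  out <- geeWald(fe, "delta_hbo_star", "left_PFC")
  expect_setequal(out$effect, c("group", "temperature", "interaction"))
  expect_equal(out$n_subjects, rep(20, 3))
  expect_equal(out$cramers_v, cramersV(out$wald_chisq, 20), tolerance = 1e-12)
  expect_lt(out$p[out$effect == "temperature"], 0.01)
  expect_error(geeWald(fe[fe$group == "control", ], "delta_hbo_star",
                       "left_PFC"), "both groups")
})

test_that("spearman correlations are rank-based and monotone-invariant", {
  x <- 1:5
  y <- c(1, 3, 2, 5, 4)
  out <- spearmanTable(data.frame(x = x, y = y))
  expect_equal(out$rho["x", "y"], 0.8)   # sum d^2 = 4 -> 1 - 24/120
  expect_equal(spearmanTable(data.frame(x = x, y = exp(x)))$rho["x", "y"], 1)
  expect_equal(spearmanTable(data.frame(x = x, y = -x))$rho["x", "y"], -1)
  ## invariance under random strictly monotone transforms
  set.seed(25)
  for (r in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    base <- spearmanTable(data.frame(a, b))$rho["a", "b"]
    f <- function(v) exp(runif(1, 0.2, 2) * v) + runif(1, 0, 3)
    tr <- spearmanTable(data.frame(a = f(a), b = b))$rho["a", "b"]
    expect_equal(tr, base, tolerance = 1e-12)
  }
  ## constant column -> undefined cell
  out2 <- spearmanTable(data.frame(a = 1:6, b = rep(2, 6)))
  expect_true(is.na(out2$rho["a", "b"]))
})

test_that("severity model recovers coefficients with nominal CI coverage", {
  set.seed(26)
  ## exactly constant outcome: zero slopes, no evidence of association
  xl <- rnorm(22, 0.3, 0.2); xr <- rnorm(22, 0.3, 0.2)
  out0 <- glmSeverity(rep(70, 22), xl, xr)
  expect_lt(max(abs(out0$B[-1])), 1e-8)
  expect_equal(out0$p[-1], c(1, 1))
  ## parameter recovery at the reported effect scale
  cover <- c(0, 0, 0)
  for (r in 1:200) {
    xL <- rnorm(22, 0.3, 0.2); xR <- 0.6 * xL + rnorm(22, 0.12, 0.16)
    y <- 70 + 49 * xL - 22 * xR + rnorm(22, 0, 5)
    fit <- glmSeverity(y, xL, xR)
    truth <- c(70, 49, -22)
    cover <- cover + (truth >= fit$ci_lower & truth <= fit$ci_upper)
  }
  expect_true(all(cover / 200 >= 0.90))
  ## closed-form OLS oracle
  xL <- rnorm(30, 0, 1); xR <- rnorm(30, 0, 1)
  y <- 2 + 3 * xL - xR + rnorm(30)
  X <- cbind(1, xL, xR)
  bHat <- solve(crossprod(X), crossprod(X, y))
  expect_equal(glmSeverity(y, xL, xR)$B, as.vector(bHat), tolerance = 1e-10)
  expect_error(glmSeverity(y, xL, xL * 1.0000001), "collinear")
  expect_error(glmSeverity(y[1:5], xL[1:5], xR[1:5]), "10 complete cases")
})

test_that("sample-size search matches Monte-Carlo power and inflates by 10%", {
  out <- sampleSizeRegression(0.6, type = "f2")
  expect_equal(out$inflated_n, as.integer(ceiling(out$base_n * 1.1)))
  expect_gte(out$power, 0.80)
  ## power is monotone non-decreasing in N
  pw <- vapply(5:100, function(N) {
    v <- N - 3
    1 - pf(qf(0.95, 2, v), 2, v, ncp = 0.6 * N)
  }, numeric(1))
  expect_true(all(diff(pw) > -1e-12))
  ## N - 1 must miss the target; Monte-Carlo agreement within +-1 subject
  N <- out$base_n
  vv <- N - 4
  expect_lt(1 - pf(qf(0.95, 2, vv), 2, vv, ncp = 0.6 * (N - 1)), 0.80)
  set.seed(27)
  mc <- function(N, reps = 50000) {
    u <- 2; v <- N - u - 1
    f <- (rchisq(reps, u, ncp = 0.6 * N) / u) / (rchisq(reps, v) / v)
    mean(f > qf(0.95, u, v))
  }
  pmc <- mc(N)
  expect_gte(pmc, 0.80 - 2 * sqrt(0.2 * 0.8 / 50000) - 0.01)
  ## the f interpretation squares the effect size
  expect_equal(sampleSizeRegression(sqrt(0.6), type = "f")$base_n,
               out$base_n)
  ## a base of 20 inflates to the reported 22
  expect_equal(as.integer(ceiling(20 * 1.1)), 22L)
  expect_error(sampleSizeRegression(1e-9, maxN = 50), "not reachable")
})
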