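test_that("normality gate routes raw, log and nonparametric cases", {
  set.seed(11)
  # plainly normal data stay on the raw route
  expect_equal(normality_gate(rnorm(100))$route, "normal-raw")
  # strongly lognormal data predominantly take the log route
  routes <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    normality_gate(exp(rnorm(200, 0, 1)))$route
  }, "")
  expect_gt(mean(routes == "normal-log"), 0.9)
  # zero or negative values forbid the log transform
  set.seed(2)
  x <- exp(rnorm(200)); x[1] <- 0
  expect_equal(normality_gate(x)$route, "nonparametric")
  # constant data cannot be tested and fall through to nonparametric
  expect_equal(normality_gate(rep(5, 10))$route, "nonparametric")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("univariate comparisons pick the right test and handle degeneracy", {
  # identical groups: Mann-Whitney on fully tied data gives p = 1
  y <- rep(c(3, 3, 3, 3), 2)
  g <- rep(c("a", "b"), each = 4)
  u <- univariate_test(y, g)
  expect_equal(u$test, "Mann-Whitney")
  expect_equal(u$p_uv, 1)

  # a 3 SD shift at n = 20 per group is detected decisively (the pooled
  # outcome is bimodal, so the gate legitimately routes nonparametric)
  set.seed(5)
  y2 <- c(rnorm(20), rnorm(20, 3))
  g2 <- rep(c("a", "b"), each = 20)
  u2 <- univariate_test(y2, g2)
  expect_lt(u2$p_uv, 0.001)
  # forced onto the parametric route it is the pooled t-test
  u2t <- univariate_test(y2, g2, gate = list(route = "normal-raw"))
  expect_equal(u2t$test, "t-test")
  expect_equal(u2t$p_uv, stats::t.test(y2 ~ g2, var.equal = TRUE)$p.value)
  # descriptives are the plain per-level mean (SD) on the original scale
  expect_equal(u2$descriptives$mean, c(mean(y2[1:20]), mean(y2[21:40])))
  expect_equal(u2$descriptives$sd, c(sd(y2[1:20]), sd(y2[21:40])))

  # three groups: ANOVA with Bonferroni post hoc = 3 x raw pairwise p
  set.seed(7)
  y3 <- rnorm(60); g3 <- rep(c("a", "b", "c"), each = 20)
  u3 <- univariate_test(y3, g3)
  expect_equal(u3$test, "ANOVA")
  raw <- stats::pairwise.t.test(y3, g3, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  expect_equal(u3$pairwise, pmin(raw * 3, 1))

  # log route: the test runs on log values but descriptives stay raw
  set.seed(8)
  yl <- exp(c(rnorm(30), rnorm(30, 1)))
  gl <- rep(c("a", "b"), each = 30)
  gate <- normality_gate(yl)
  ul <- univariate_test(yl, gl, gate = gate)
  expect_equal(ul$route, "normal-log")
  expect_equal(ul$p_uv,
               stats::t.test(log(yl) ~ gl, var.equal = TRUE)$p.value)
  expect_equal(ul$descriptives$mean[1], mean(yl[1:30]))

  # parametric route with a singleton group falls back with a warning
  expect_warning(u4 <- univariate_test(c(rnorm(10), 5), rep(c("a", "b"), c(10, 1)),
                                       gate = list(route = "normal-raw")),
                 "nonparametric")
  expect_equal(u4$test, "Mann-Whitney")
  expect_error(univariate_test(1:5, rep("a", 5)), "2 non-empty groups")
})

test_that("OLS with one binary predictor reproduces the pooled t-test", {
  set.seed(13)
  d <- data.frame(y = c(rnorm(15), rnorm(15, 1)),
                  g = factor(rep(c("a", "b"), each = 15)))
  mv <- multivariate_fit(d, "y", "g")
  tt <- stats::t.test(y ~ g, data = d, var.equal = TRUE)
  expect_lt(abs(mv$coefficients$p_mv - tt$p.value), 1e-10)
  # beta equals the group-mean difference
  expect_equal(mv$coefficients$beta,
               mean(d$y[d$g == "b"]) - mean(d$y[d$g == "a"]))
  expect_gte(mv$r_squared, 0); expect_lte(mv$r_squared, 1)

  # perfectly collinear predictors are dropped with a warning
  d$g2 <- d$g
  expect_warning(mv2 <- multivariate_fit(d, "y", c("g", "g2")), "collinear")
  expect_equal(mv2$dropped, "g2")
  expect_equal(nrow(mv2$coefficients), 1L)
})

test_that("paired change tests report mean (SD) and handle degeneracy", {
  set.seed(17)
  b <- rnorm(30, 120, 10)
  # identity: mean change 0, p = 1
  p0 <- paired_change(b, b)
  expect_equal(p0$mean_change, 0)
  expect_equal(p0$p, 1)
  expect_true(p0$degenerate)
  # constant non-zero shift: flagged, p at the machine floor
  p1 <- paired_change(b, b - 10)
  expect_equal(p1$mean_change, -10)
  expect_true(p1$degenerate)
  expect_lt(p1$p, 1e-300)
  # ordinary paired t
  f <- b + rnorm(30, -7, 11)
  p2 <- paired_change(b, f)
  expect_equal(p2$p, stats::t.test(f, b, paired = TRUE)$p.value)
  expect_equal(p2$mean_change, mean(f - b))
  expect_error(paired_change(1:5, 1:4), "length mismatch")
})

test_that("simulated blood-pressure drops are detected at trial size", {
  # mean -7, SD 11 at n = 64: the paired test is significant in most draws
  hits <- vapply(1:40, function(i) {
    set.seed(300 + i)
    b <- rnorm(64, 120, 10)
    f <- b + rnorm(64, -7, 11)
    paired_change(b, f)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("incidence tests switch between chi-squared and Fisher correctly", {
  # small expected counts force Fisher
  r <- incidence_test(matrix(c(1, 1, 1, 60), 2, byrow = TRUE))
  expect_equal(r$test, "fisher")
  # large balanced table uses Pearson chi-squared without correction
  big <- matrix(c(30, 70, 45, 55), 2)
  r2 <- incidence_test(big)
  expect_equal(r2$test, "chi2")
  expect_equal(r2$p, stats::chisq.test(big, correct = FALSE)$p.value)
  expect_equal(unname(r2$proportions), c(30 / 100, 45 / 100))
  expect_error(incidence_test(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(incidence_test(matrix(c(1.5, 1, 1, 1), 2)), "integers")
  expect_error(incidence_test(matrix(1:6, 3)), "2 x k")
})

test_that("Fisher p equals brute-force hypergeometric enumeration", {
  # a graded sweep of 2x2 tables with N up to 200, plus random tables
  tabs <- list(matrix(c(1, 1, 1, 60), 2, byrow = TRUE),
               matrix(c(2, 15, 0, 46), 2, byrow = TRUE),
               matrix(c(28, 30, 0, 6), 2, byrow = TRUE),
               matrix(c(0, 5, 5, 0), 2), matrix(c(1, 0, 0, 1), 2),
               matrix(c(10, 10, 10, 10), 2))
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:200, 1)
    a <- stats::rmultinom(1, n, rep(0.25, 4))
    tabs[[length(tabs) + 1]] <- matrix(a, 2)
  }
  for (tab in tabs) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_2x2(tab),
                 tolerance = 1e-10)
  }
})

test_that("the cascade gates, screens and models end to end", {
  set.seed(23)
  n <- 80
  g <- factor(rep(c("x", "y"), each = n / 2))
  noise <- factor(sample(c("u", "v"), n, TRUE))
  d <- data.frame(out = exp(rnorm(n, 0, 0.4) + 0.8 * (g == "y")),
                  g = g, noise = noise)
  cs <- assoc_cascade(d, "out", c("g", "noise"))
  expect_s3_class(cs, "assoc_cascade")
  expect_equal(cs$gate$route, "normal-log")
  expect_true(cs$screen$selected[cs$screen$predictor == "g"])
  expect_false(is.null(cs$multivariate))
  # the model includes exactly the screened predictors
  expect_setequal(unique(cs$multivariate$coefficients$predictor),
                  cs$screen$predictor[cs$screen$selected])
  s <- summary(cs)
  expect_true(all(c("outcome", "predictor", "p_uv", "beta", "p_mv",
                    "r_squared") %in% names(s)))

  # no predictor passing the screen: no model fitted
  set.seed(24)
  d0 <- data.frame(out = rnorm(40), a = factor(rep(c("x", "y"), 20)))
  d0$out <- d0$out - ave(d0$out, d0$a) # force exact group equality
  cs0 <- assoc_cascade(d0, "out", "a")
  expect_false(cs0$screen$selected[1])
  expect_null(cs0$multivariate)
})

test_that("a larger true difference does not raise the expected p-value", {
  # monotonicity in expectation: mean p over replicates decreases as the
  # injected shift grows
  mean_p <- vapply(c(0, 0.5, 1), function(delta) {
    ps <- vapply(1:60, function(i) {
      set.seed(5000 + i)
      y <- c(rnorm(25), rnorm(25, delta))
      univariate_test(y, rep(c("a", "b"), each = 25))$p_uv
    }, 0)
    mean(ps)
  }, 0)
  expect_true(all(diff(mean_p) < 0))
})
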