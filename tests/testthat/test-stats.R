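test_that("one-way ANOVA matches the aov decomposition", {
  set.seed(1)
  for (i in 1:5) {
    g <- split(rnorm(30, rep(runif(3, 0, 2), each = 10)),
               rep(1:3, each = 10))
    mine <- anova_oneway(g)
    ref <- summary(stats::aov(v ~ t, data.frame(
      v = unlist(g), t = factor(rep(1:3, each = 10)))))[[1]]
    expect_equal(mine$F, ref$`F value`[1])
    expect_equal(mine$p, ref$`Pr(>F)`[1])
  }
})

test_that("ANOVA handles degenerate and two-group cases", {
  ## identical values within and between -> F = 0, p = 1
  same <- list(rep(2, 5), rep(2, 5), rep(2, 5))
  expect_equal(anova_oneway(same)[c("F", "p")], list(F = 0, p = 1))
  ## two groups: F equals the square of the pooled t statistic
  set.seed(2)
  a <- rnorm(8); b <- rnorm(8, 1)
  t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(anova_oneway(list(a, b))$F, unname(t2))
  expect_error(anova_oneway(list(a)), "two groups")
  expect_error(anova_oneway(list(a, 1)), "two values")
})

test_that("ANOVA is invariant under shift and positive rescale", {
  set.seed(3)
  g <- split(rnorm(24, rep(c(0, 1, 2), each = 8)), rep(1:3, each = 8))
  base <- anova_oneway(g)
  shifted <- anova_oneway(lapply(g, function(v) v + 100))
  scaled <- anova_oneway(lapply(g, function(v) v * 7))
  expect_equal(shifted$F, base$F); expect_equal(scaled$F, base$F)
  expect_gte(base$F, 0)
  expect_true(base$p >= 0 && base$p <= 1)
})

test_that("Tukey HSD matches base R and the two-group t identity", {
  set.seed(4)
  g <- split(rnorm(24, rep(c(0, 0.5, 1, 3), each = 6)),
             rep(c("T0", "T1", "T2", "T3"), each = 6))
  tk <- tukey_hsd(g, alpha = 0.01)
  ref <- stats::TukeyHSD(stats::aov(v ~ t, data.frame(
    v = unlist(g), t = factor(rep(names(g), each = 6)))),
    conf.level = 0.99)$t
  ## base R orders pairs b-a; ours a-b
  expect_equal(tk$pairs$mean_diff, -ref[, "diff"], ignore_attr = TRUE)
  expect_equal(tk$pairs$interval_low, -ref[, "upr"], ignore_attr = TRUE)
  expect_equal(tk$pairs$interval_high, -ref[, "lwr"], ignore_attr = TRUE)
  expect_equal(tk$pairs$p, ref[, "p adj"], ignore_attr = TRUE)
  expect_identical(tk$pairs$significant,
                   !(tk$pairs$interval_low <= 0 & tk$pairs$interval_high >= 0))
  ## two groups: q = sqrt(2) |t|
  a <- rnorm(6); b <- rnorm(6, 2)
  tk2 <- tukey_hsd(list(A = a, B = b), alpha = 0.01)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  q <- sqrt(2) * abs(tt$statistic)
  expect_equal(tk2$pairs$p,
               stats::ptukey(unname(q), 2, 10, lower.tail = FALSE))
  ## identical groups: nothing significant
  tk3 <- tukey_hsd(list(rep(1, 4), rep(1, 4)))
  expect_false(any(tk3$pairs$significant))
})

test_that("Tukey significance is monotone in alpha", {
  set.seed(5)
  for (i in 1:10) {
    g <- split(rnorm(24, rep(runif(4, 0, 2), each = 6)), rep(1:4, each = 6))
    s01 <- tukey_hsd(g, 0.01)$pairs$significant
    s05 <- tukey_hsd(g, 0.05)$pairs$significant
    expect_true(all(!s01 | s05))   # sig at 1% implies sig at 5%
  }
})

test_that("growth regression recovers exact polynomial data", {
  x <- 0:7
  lin <- fit_growth_regression(x, 3 * x + 2, degree = 1)
  expect_equal(lin$coefficients, c(3, 2))
  expect_equal(lin$r_squared, 1)
  ## noiseless quadratic recovered to machine precision
  co <- c(2825, 3078, 8909)
  y <- co[1] * x^2 + co[2] * x + co[3]
  quad <- fit_growth_regression(x, y, degree = 2)
  expect_equal(quad$coefficients, co, tolerance = 1e-10)
  expect_equal(quad$r_squared, 1)
  expect_equal(predict(quad, c(0, 2)), y[c(1, 3)])
  ## constant data: zero slope, R^2 reported 0 with warning
  expect_warning(flat <- fit_growth_regression(x, rep(5, 8), 1), "constant")
  expect_equal(flat$coefficients[1], 0)
  expect_equal(flat$r_squared, 0)
  expect_error(fit_growth_regression(0:2, 1:3, 2), "at least")
})

test_that("R^2 never decreases from degree 1 to degree 2", {
  set.seed(6)
  for (i in 1:10) {
    x <- 0:7; y <- rnorm(8, 10 + 2 * x)
    r1 <- fit_growth_regression(x, y, 1)$r_squared
    r2 <- fit_growth_regression(x, y, 2)$r_squared
    expect_gte(r2, r1 - 1e-12)
  }
})

test_that("boxplot summary uses interpolated quartiles and 1.5 IQR fences", {
  s <- summarize_boxplot(1:7)
  expect_equal(unname(s$quartiles), c(2.5, 4, 5.5))  # type-7 interpolation
  expect_equal(unname(s$whiskers), c(1, 7))
  expect_length(s$outliers, 0)
  ## single value
  s1 <- summarize_boxplot(42)
  expect_true(all(s1$quartiles == 42))
  ## symmetric data: median equals mean
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(unname(summarize_boxplot(sym)$quartiles[2]), mean(sym))
  ## distant point is an outlier and excluded from the whisker
  s2 <- summarize_boxplot(c(1:10, 100))
  expect_equal(s2$outliers, 100)
  expect_equal(unname(s2$whiskers[2]), 10)
})

test_that("modified band depth matches the exhaustive oracle", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    curves <- matrix(rnorm(n * 5), n, 5)
    expect_equal(band_depth(curves), oracle_mbd(curves))
  }
})

test_that("functional boxplot centralizes deep curves and flags outliers", {
  weeks <- 0:4
  ## identical trajectories: bands collapse, no outliers
  m <- matrix(rep(weeks * 2 + 1, 5), 5, byrow = TRUE,
              dimnames = list(paste0("p", 1:5), weeks))
  fb <- functional_boxplot(m)
  expect_equal(fb$central_lower, fb$central_upper, ignore_attr = TRUE)
  expect_length(fb$outliers, 0)
  ## one far-displaced trajectory is excluded from the envelope: nine
  ## vertically offset copies of a line, the tenth displaced far above
  base <- outer(seq(-0.4, 0.4, length.out = 9), rep(1, 5)) +
    outer(rep(1, 9), weeks * 2 + 10)
  base <- rbind(base, base[5, ] + 50)
  rownames(base) <- paste0("p", 1:10); colnames(base) <- weeks
  fb2 <- functional_boxplot(base)
  expect_identical(fb2$outliers, "p10")
  expect_true(all(fb2$envelope_upper < 20))
  ## central 50% band nested in the envelope at every week
  expect_true(all(fb2$central_lower >= fb2$envelope_lower))
  expect_true(all(fb2$central_upper <= fb2$envelope_upper))
  ## contracts
  expect_error(functional_boxplot(base[1:2, ]), "3 complete")
  nay <- base; nay[1, 2] <- NA
  expect_error(functional_boxplot(nay), "incomplete")
})

test_that("weekly comparisons separate strongly different treatments", {
  tab <- generate_trial(trial_spec(models = growth_models()["Area"],
                                   seed = 10))
  cmp <- weekly_comparisons(tab, "Area", alpha = 0.01)
  expect_true(all(c("week", "group_a", "group_b", "significant",
                    "anova_p") %in% names(cmp)))
  w7 <- cmp[cmp$week == 7 & cmp$group_a == "T0" & cmp$group_b == "T3", ]
  expect_true(w7$significant)           # curves far apart by week 7
  expect_error(weekly_comparisons(tab, "Nope"), "no data")
})

test_that("refitting simulated trials recovers generator coefficients", {
  ## parameter recovery across seeded replications: per-week treatment
  ## means refit at the generating degree; coefficients within 3 SEs
  models <- growth_models()$Area
  hits <- 0L; runs <- 40L
  for (s in seq_len(runs)) {
    tab <- generate_trial(trial_spec(models = growth_models()["Area"],
                                     seed = 1000 + s))
    ok <- TRUE
    for (tr in c("T0", "T3")) {
      sub <- tab[tab$treatment == tr, ]
      mu <- tapply(sub$value, sub$week, mean)
      fit <- fit_growth_regression(as.numeric(names(mu)), as.numeric(mu),
                                   models[[tr]]$degree)
      z <- abs(fit$coefficients - models[[tr]]$coefficients) /
        fit$std_errors
      if (any(z > 3)) ok <- FALSE
    }
    hits <- hits + ok
  }
  expect_gte(hits / runs, 0.95)
})
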