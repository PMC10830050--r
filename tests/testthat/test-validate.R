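test_that("the protective-behaviour score sums five binary indicators", {
  ind <- data.frame(mask = c(1, 0, 1), dist = c(1, 0, 0),
                    crowd = c(1, 0, 0), wash = c(1, 0, 1),
                    window = c(1, 0, 0))
  expect_equal(protective_score(ind), c(5L, 0L, 2L))
  ind$mask[2] <- NA
  expect_equal(protective_score(ind, missing = "zero")[2], 0L)
  expect_true(is.na(protective_score(ind, missing = "exclude")[2]))
  expect_error(protective_score(ind[, 1:4]), "five")
  ind$mask[1] <- 2
  expect_error(protective_score(ind), "binary")
})

test_that("partial eta-squared reproduces the worked-example values", {
  # agreement with the printed 3-dp values at printed precision
  expect_lt(abs(partial_eta_squared(1751.359, 10340.288) - 0.145), 5e-4)
  expect_lt(abs(partial_eta_squared(153.335, 10340.288) - 0.015), 5e-4)
  expect_equal(partial_eta_squared(0, 10), 0)
  expect_warning(v <- partial_eta_squared(0, 0), "undefined")
  expect_true(is.nan(v))
  expect_error(partial_eta_squared(-1, 2), "nonnegative")
})

test_that("partial eta-squared is monotone in its arguments", {
  expect_gt(partial_eta_squared(2, 10), partial_eta_squared(1, 10))
  expect_lt(partial_eta_squared(2, 20), partial_eta_squared(2, 10))
})

test_that("the worked-example table rebuilds F, eta2 and R2 from SS/df", {
  tab <- example_glm_table()
  g <- function(src, col) tab[tab$source == src, col]
  # F from unrounded mean squares
  expect_lt(abs(g("Segments", "F") - 136.655), 1e-2)
  expect_lt(abs(g("Gender", "F") - 44.089), 1e-2)
  expect_lt(abs(g("Segments", "partial_eta2") - 0.145), 5e-4)
  expect_lt(abs(g("Intercept", "partial_eta2") - 0.124), 5e-4)
  expect_lt(abs(g("Income", "partial_eta2") - 0.007), 5e-4)
  expect_lt(abs(g("Age", "partial_eta2") - 0.015), 5e-4)
  fit <- model_fit_stats(tab)
  expect_lt(abs(fit$r_squared - 0.218), 5e-4)
  expect_lt(abs(fit$adj_r_squared - 0.216), 5e-4)
})

test_that("Type III SS equals classical one-way ANOVA on balanced data", {
  set.seed(1)
  g <- factor(rep(c("a", "b", "c"), each = 40))
  y <- rnorm(120) + c(a = 0, b = 0.5, c = 1)[g]
  tab <- fit_type3_anova(y, g)
  # closed-form between-groups SS
  means <- tapply(y, g, mean)
  ss_between <- sum(40 * (means - mean(y))^2)
  expect_equal(tab$ss[tab$source == "Segments"], ss_between,
               tolerance = 1e-9)
  expect_equal(tab$ss[tab$source == "Error"],
               sum((y - means[g])^2), tolerance = 1e-9)
  # SS additivity
  expect_equal(tab$ss[tab$source == "Corrected Model"] +
                 tab$ss[tab$source == "Error"],
               tab$ss[tab$source == "Corrected Total"], tolerance = 1e-9)
})

test_that("Type III SS equals sequential SS for orthogonal predictors", {
  set.seed(2)
  # balanced 2x2 layout: factors are orthogonal
  g <- factor(rep(c("a", "b"), each = 60))
  h <- factor(rep(rep(c("u", "v"), each = 30), 2))
  y <- rnorm(120) + (g == "b") * 0.8 + (h == "v") * 0.5
  tab <- fit_type3_anova(y, g, data.frame(h = h))
  seq_ss <- anova(lm(y ~ g + h))
  expect_equal(tab$ss[tab$source == "Segments"], seq_ss["g", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(tab$ss[tab$source == "h"], seq_ss["h", "Sum Sq"],
               tolerance = 1e-9)
})

test_that("a constant outcome gives zero effect SS", {
  g <- factor(rep(c("a", "b"), each = 20))
  tab <- fit_type3_anova(rep(2, 40), g)
  expect_equal(tab$ss[tab$source == "Segments"], 0, tolerance = 1e-9)
  expect_equal(tab$ss[tab$source == "Corrected Total"], 0, tolerance = 1e-9)
})

test_that("SS additivity holds on unbalanced multi-covariate fits", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 300
    seg <- factor(sample(letters[1:4], n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)))
    demo <- data.frame(age = rnorm(n, 45, 12),
                       gender = sample(c("f", "m"), n, TRUE),
                       income = sample(1:7, n, TRUE))
    y <- rnorm(n) + as.integer(seg) + 0.02 * demo$age
    tab <- fit_type3_anova(y, seg, demo)
    expect_equal(tab$ss[tab$source == "Corrected Model"] +
                   tab$ss[tab$source == "Error"],
                 tab$ss[tab$source == "Corrected Total"],
                 tolerance = 1e-6 * tab$ss[tab$source == "Corrected Total"])
    expect_equal(tab$ms[tab$source == "Error"],
                 tab$ss[tab$source == "Error"] /
                   tab$df[tab$source == "Error"])
  }
})

test_that("rank-deficient fits name the aliased terms", {
  g <- factor(rep(c("a", "b"), each = 10))
  dup <- data.frame(same = as.integer(g == "b"))   # aliased with segment
  expect_error(fit_type3_anova(rnorm(20), g, dup), "aliased")
})

test_that("Wald chi-square is near its df under the null", {
  set.seed(4)
  n <- 20000
  seg <- factor(sample(letters[1:7], n, TRUE))
  y <- rbinom(n, 1, 0.3)   # independent of the predictor
  rep <- fit_logistic_wald(y, seg)
  expect_equal(rep$df[rep$predictor == "Segments"], 6)
  expect_lt(abs(rep$wald_chisq[rep$predictor == "Segments"] - 6),
            3 * sqrt(2 * 6))   # chi-square(6): sd = sqrt(12)
})

test_that("logistic coefficients achieve nominal CI coverage", {
  # two-level segment with known log-odds difference of 1
  set.seed(5)
  covered <- logical(200)
  for (i in seq_along(covered)) {
    seg <- factor(rep(c("a", "b"), each = 150))
    eta <- ifelse(seg == "b", -0.5, 0.5)    # sum-to-zero coding: beta = 0.5
    y <- rbinom(300, 1, plogis(eta))
    fit <- suppressWarnings(
      glm(y ~ seg, family = binomial(),
          contrasts = list(seg = "contr.sum")))
    ci <- suppressMessages(confint.default(fit, "seg1"))
    covered[i] <- ci[1] <= 0.5 && 0.5 <= ci[2]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("degenerate logistic outcomes are rejected or flagged", {
  seg <- factor(rep(c("a", "b"), each = 20))
  expect_error(fit_logistic_wald(rep(1, 40), seg), "both classes")
  # complete separation: outcome == segment indicator
  y <- as.integer(seg == "b")
  expect_warning(rep <- fit_logistic_wald(y, seg), "separation")
  expect_true(attr(rep, "separation"))
})

test_that("segment-driven outcomes dominate the comparison report", {
  set.seed(6)
  n <- 2000
  seg <- factor(sample(letters[1:5], n, TRUE))
  demo <- data.frame(age = rnorm(n, 45, 12),
                     gender = sample(c("f", "m"), n, TRUE))
  y <- rnorm(n) + 2 * as.integer(seg)          # outcome driven by segment
  tab <- fit_type3_anova(y, seg, demo)
  wald <- fit_logistic_wald(rbinom(n, 1, plogis(as.integer(seg) - 3)),
                            seg, demo)
  rep <- predictor_comparison_report(tab, wald)
  expect_true(all(rep$segment_eta2 >
                    rep$terms$partial_eta2[rep$terms$term != "Segments"]))
  expect_lt(rep$eta2_ratio, 1)
  # table layout mirrors the standard Unianova row set
  expect_equal(tab$source[c(1, 2)], c("Corrected Model", "Intercept"))
  expect_equal(utils::tail(tab$source, 3),
               c("Error", "Total", "Corrected Total"))
})

test_that("null outcomes give near-zero effect sizes everywhere", {
  set.seed(7)
  n <- 3000
  seg <- factor(sample(letters[1:5], n, TRUE))
  demo <- data.frame(age = rnorm(n), income = sample(1:7, n, TRUE))
  tab <- fit_type3_anova(rnorm(n), seg, demo)
  terms <- !(tab$source %in% c("Corrected Model", "Intercept", "Error",
                               "Total", "Corrected Total"))
  expect_true(all(tab$partial_eta2[terms] < 0.01))
})
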