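test_that("design validation and degrees of freedom", {
  expect_error(surveyDesign(1, 1, -1), "positive")
  expect_error(surveyDesign(c(1, 1), 1:2, c(1, NA)), "positive|finite")
  des <- toy_design(40, n_strata = 4)
  expect_equal(degfSurvey(des), des$n_psu - des$n_strata)
})

test_that("weighted mean reduces to the arithmetic mean with an SRS oracle SE", {
  set.seed(3)
  x <- rnorm(60, 10, 2)
  des <- iid_design(60)
  ms <- svyMeanSE(x, des)
  expect_equal(unname(ms["mean"]), mean(x))
  # brute-force linearized SRS SE: sd/sqrt(n) with the n/(n-1) PSU factor
  expect_equal(unname(ms["se"]), sd(x) / sqrt(60), tolerance = 1e-12)
})

test_that("weight-splitting and weight-scaling leave estimates unchanged", {
  set.seed(4)
  n <- 50
  x <- rnorm(n)
  stratum <- rep(1:5, each = 10); psu <- rep(1:2, 25)
  w <- runif(n, 1, 3)
  des <- surveyDesign(stratum, psu, w)
  ms <- svyMeanSE(x, des)
  # split each record into two half-weight copies in the same PSU
  des2 <- surveyDesign(rep(stratum, 2), rep(psu, 2), rep(w / 2, 2))
  ms2 <- svyMeanSE(rep(x, 2), des2)
  expect_equal(ms2, ms, tolerance = 1e-12)
  # rescaling all weights changes nothing
  des3 <- surveyDesign(stratum, psu, 7.3 * w)
  expect_equal(svyMeanSE(x, des3), ms, tolerance = 1e-12)
})

test_that("weighted tables give weighted percentages and raw counts", {
  des <- surveyDesign(c(1, 1), c(1, 2), c(1, 3))
  tab <- svyTable(c("a", "b"), des)
  expect_equal(tab$pct, c(25, 75))
  expect_equal(tab$n, c(1L, 1L))
  tab1 <- svyTable(rep("only", 5), iid_design(5))
  expect_equal(tab1$pct, 100)
  expect_equal(sum(svyTable(sample(letters[1:4], 40, TRUE),
                            iid_design(40))$pct), 100)
})

test_that("Rao-Scott statistic reduces to Pearson under an iid design", {
  set.seed(5)
  x <- sample(c("a", "b", "c"), 200, TRUE)
  y <- sample(c("u", "v"), 200, TRUE)
  rs <- raoScottChi2(x, y, iid_design(200))
  ref <- suppressWarnings(chisq.test(table(x, y), correct = FALSE))
  expect_equal(rs$statistic, unname(ref$statistic), tolerance = 1e-6)
  # identical rows give a zero statistic
  x2 <- rep(c("a", "b"), each = 20)
  y2 <- rep(c("u", "v"), 20)
  expect_equal(raoScottChi2(x2, y2, iid_design(40))$statistic, 0,
               tolerance = 1e-10)
  expect_error(raoScottChi2(rep("a", 10), sample(c("u", "v"), 10, TRUE),
                            iid_design(10)), "levels")
})

test_that("Rao-Scott p-values are uniform under independence", {
  set.seed(6)
  ps <- replicate(500, {
    n <- 200
    x <- sample(c("a", "b"), n, TRUE)
    y <- sample(c("u", "v"), n, TRUE, prob = c(0.4, 0.6))
    des <- surveyDesign(rep(1:5, n / 5), sample(2, n, TRUE),
                        runif(n, 0.5, 2))
    raoScottChi2(x, y, des)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("survey logistic with equal weights matches the iid MLE", {
  set.seed(7)
  n <- 500
  x <- rnorm(n); z <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x - 0.5 * z))
  d <- data.frame(y = y, x = x, z = z)
  fit <- svyLogit(y ~ x + z, d, iid_design(n))
  ref <- glm(y ~ x + z, binomial, d)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)

  # weight-splitting invariance for the fit
  d2 <- rbind(d, d)
  des2 <- surveyDesign(rep(1, 2 * n), rep(seq_len(n), 2), rep(0.5, 2 * n))
  fit2 <- svyLogit(y ~ x + z, d2, des2)
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-8)

  # weight-scaling invariance of coefficients and design-based SEs
  des3 <- iid_design(n, weight = 13)
  fit3 <- svyLogit(y ~ x + z, d, des3)
  expect_equal(fit3$coef, fit$coef, tolerance = 1e-10)
  expect_equal(fit3$se, fit$se, tolerance = 1e-10)
})

test_that("survey logistic fails loudly on separation and rank deficiency", {
  d <- data.frame(y = c(rep(0, 20), rep(1, 20)), x = c(rnorm(20), rnorm(20) + 50))
  expect_error(svyLogit(y ~ x, d, iid_design(40)), "separation|converge")
  d2 <- data.frame(y = rbinom(40, 1, 0.5), a = rnorm(40))
  d2$b <- 2 * d2$a
  expect_error(svyLogit(y ~ a + b, d2, iid_design(40)), "rank")
})

test_that("odds-ratio intervals use the t reference with design df", {
  set.seed(8)
  n <- 120
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.5 * d$x))
  des <- toy_design(n, n_strata = 6, seed = 2)
  fit <- svyLogit(y ~ x, d, des)
  ci <- orCI(fit, "x")
  b <- fit$table$beta[2]; se <- fit$table$se[2]
  expect_equal(unname(ci["or"]), exp(b))
  expect_equal(unname(ci["lo"]), exp(b - qt(0.975, fit$df) * se))
  expect_equal(unname(ci["hi"]), exp(b + qt(0.975, fit$df) * se))
  expect_error(orCI(fit, "nope"), "unknown")

  # hand-computed t quantile oracle: beta = 0.1133, se = 0.027, df = 30
  lo <- exp(0.1133 - qt(0.975, 30) * 0.027)
  hi <- exp(0.1133 + qt(0.975, 30) * 0.027)
  expect_equal(exp(0.1133 + c(-1, 1) * 2.042272 * 0.027), c(lo, hi),
               tolerance = 1e-5)

  # zero variance collapses the interval
  expect_equal(exp(log(2) + c(-1, 1) * qt(0.975, 1000) * 0), c(2, 2))
})

test_that("trend test codes ordered levels 0,1,2 and equals the binary p for 2 levels", {
  set.seed(9)
  n <- 400
  g <- factor(sample(c("lo", "hi"), n, TRUE), levels = c("lo", "hi"),
              ordered = TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * (g == "hi")))
  d <- data.frame(y = y, g = g)
  des <- iid_design(n)
  p_trend <- trendTest(y ~ g, d, des, "g")
  d2 <- data.frame(y = y, g = as.numeric(g == "hi"))
  p_bin <- svyLogit(y ~ g, d2, des)$table$p[2]
  expect_equal(p_trend, p_bin, tolerance = 1e-10)

  # strongly monotone three-level effect is detected
  g3 <- factor(sample(c("a", "b", "c"), 1500, TRUE),
               levels = c("a", "b", "c"), ordered = TRUE)
  y3 <- rbinom(1500, 1, plogis(-1 + 0.8 * (as.numeric(g3) - 1)))
  expect_lt(trendTest(y ~ g, data.frame(y = y3, g = g3), iid_design(1500), "g"),
            0.001)
  expect_error(trendTest(y ~ g, data.frame(y = y3, g = as.character(g3)),
                         iid_design(1500), "g"), "ordered")
})

test_that("trend-test p-values are uniform under an exchangeable null", {
  set.seed(10)
  ps <- replicate(300, {
    n <- 300
    g <- factor(sample(c("a", "b", "c"), n, TRUE), ordered = TRUE,
                levels = c("a", "b", "c"))
    y <- rbinom(n, 1, 0.3)
    trendTest(y ~ g, data.frame(y = y, g = g), iid_design(n), "g")
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("interaction test detects effect modification and is calibrated", {
  set.seed(11)
  n <- 2000
  x <- rnorm(n); g <- sample(c("f", "m"), n, TRUE)
  y_op <- rbinom(n, 1, plogis(ifelse(g == "m", 1, -1) * x))
  d <- data.frame(y = y_op, x = x, g = g)
  expect_lt(interactionTest("y", "x", "g", character(), d, iid_design(n)),
            0.001)
  expect_error(interactionTest("y", "x", "g", character(),
                               transform(d, g = "f"), iid_design(n)),
               "constant")
  # equal slopes across subgroups: p uniform
  ps <- replicate(200, {
    m <- 400
    x <- rnorm(m); g <- sample(c("f", "m"), m, TRUE)
    y <- rbinom(m, 1, plogis(0.5 * x))
    interactionTest("y", "x", "g", character(),
                    data.frame(y = y, x = x, g = g), iid_design(m))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("model suite fits the crude/demographic/full adjustment ladder", {
  sim <- simulateCohort(simConfig(n_subjects = 2500), seed = 21)
  d <- deriveCohort(sim$cohort)
  d$latent <- sim$truth$latent_age
  dd <- d[d$dm, ]
  des <- surveyDesign(dd$stratum, dd$psu, dd$weight)
  ms <- suppressWarnings(modelSuite(dd, des, "latent"))
  expect_equal(ms$model, c("model1", "model2", "model3"))
  # null-effect covariates: the three exposure ORs agree within MC error
  expect_lt(max(abs(diff(log(ms$or)))), 0.06)
  # and all sit near the designed value
  expect_lt(max(abs(log(ms$or) - log(1.11))), 0.08)
  # guard: exposure duplicated among covariates
  expect_error(modelSuite(dd, des, "ca"), "covariates")
  # CA as exposure omits the age covariate and then runs
  ms_ca <- suppressWarnings(modelSuite(dd, des, "ca", adjust_age = FALSE))
  expect_equal(nrow(ms_ca), 3)
})

test_that("subgroup analysis flags degenerate cells and is symmetric", {
  set.seed(12)
  n <- 1200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1.5 + 0.6 * x))
  g <- rep(c("g1", "g2"), each = n / 2)
  # make the two subgroups literally identical
  x[g == "g2"] <- x[g == "g1"]; y[g == "g2"] <- y[g == "g1"]
  d <- data.frame(y = y, x = x, g = g,
                  stratum = rep(rep(1:6, each = 100), 2) ,
                  psu = rep(rep(1:2, 300), 2), w = 1)
  des <- surveyDesign(d$stratum, d$psu, d$w)
  sg <- subgroupAnalysis(d, des, "x", "g", outcome = "y", adjust_age = FALSE,
                         demographics = character(), lifestyle = character())
  expect_equal(sg$or[1], sg$or[2], tolerance = 1e-10)
  expect_equal(sg$lo[1], sg$lo[2], tolerance = 1e-10)

  # zero-case subgroup is flagged, not an error
  y2 <- y; y2[g == "g2"] <- 0
  d2 <- transform(d, y = y2)
  sg2 <- subgroupAnalysis(d2, des, "x", "g", outcome = "y",
                          adjust_age = FALSE, demographics = character(),
                          lifestyle = character())
  expect_true(any(sg2$note == "single outcome class"))
  expect_true(all(is.na(sg2$or[sg2$note != ""])))
})

test_that("lonely-PSU strata are handled with a warning, not an error", {
  x <- rnorm(30)
  des <- surveyDesign(c(rep(1, 28), 2, 2), c(rep(1:14, each = 2), 1, 1),
                      rep(1, 30))
  expect_warning(svyMeanSE(x, des), "single PSU")
})
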