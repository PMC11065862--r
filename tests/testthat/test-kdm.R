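test_that("biomarker regressions match the closed-form normal equations", {
  d <- data.frame(ca = c(40, 50, 60, 70, 80), x = c(10, 12, 13, 17, 18))
  fit <- kdmFitRegressions(d, "x")
  # hand-evaluated normal equations
  sxy <- sum((d$ca - 60) * (d$x - 14)); sxx <- sum((d$ca - 60)^2)
  k <- sxy / sxx; q <- 14 - k * 60
  res <- d$x - (q + k * d$ca)
  expect_equal(fit$k, k)
  expect_equal(fit$q, q)
  expect_equal(fit$s, sqrt(mean(res^2)))
  expect_equal(fit$r2, sxy^2 / (sxx * sum((d$x - 14)^2)))

  # near-exact linear recovers the generating line
  set.seed(1)
  d2 <- data.frame(ca = seq(40, 80, length.out = 50))
  d2$x <- 2 * d2$ca + 5 + rnorm(50, 0, 1e-6)
  fit2 <- kdmFitRegressions(d2, "x")
  expect_equal(fit2$k, 2, tolerance = 1e-3)
  expect_equal(fit2$q, 5, tolerance = 1e-3)

  # constant biomarker is a degenerate fit naming the column
  d2$flat <- 1
  expect_error(kdmFitRegressions(d2, "flat"), "flat")
})

test_that("BA_E follows the precision-weighted formula", {
  p1 <- structure(list(markers = data.frame(biomarker = "x", k = 2, q = 5,
                                            s = 3, r2 = 0.5),
                       m = 1L), class = "kdm_params")
  # single marker: (x - q)/k independent of s
  expect_equal(kdmBAE(65, p1), 30)
  p1$markers$s <- 0.1
  expect_equal(kdmBAE(65, p1), 30)

  # two markers, independent arithmetic oracle
  p2 <- structure(list(markers = data.frame(biomarker = c("a", "b"),
                                            k = c(1, 2), q = c(0, 0),
                                            s = c(1, 2), r2 = c(0.5, 0.5)),
                       m = 2L), class = "kdm_params")
  oracle <- ((50 - 0) * 1 / 1 + (110 - 0) * 2 / 4) / (1 + 1)
  expect_equal(kdmBAE(c(50, 110), p2), oracle)

  # markers exactly on their regression lines at age a give BA_E = a
  a <- 57.3
  expect_equal(kdmBAE(c(1 * a + 0, 2 * a + 0), p2), a, tolerance = 1e-8)

  expect_error(kdmBAE(c(50, NA), p2), "missing")
})

test_that("r_char collapses when correlations are equal and matches the formula", {
  expect_equal(kdmRChar(rep(0.36, 8)), 0.6)
  expect_equal(kdmRChar(0.09), 0.3)
  r <- c(0.3, 0.6)
  oracle <- sum(r^2 / sqrt(1 - r^2)) / sum(r / sqrt(1 - r^2))
  expect_equal(kdmRChar(r^2), oracle)
  expect_error(kdmRChar(c(0.5, 1)))
})

test_that("S_BA^2 matches a spreadsheet-style evaluation and scales correctly", {
  ba_e <- c(48, 60, 52, 78); ca <- c(40, 50, 60, 70)
  r_char <- 0.8; m <- 8
  d <- ba_e - ca
  oracle <- mean((d - mean(d))^2) - ((1 - 0.64) / 0.64) * (80 - 40)^2 / (12 * 8)
  expect_equal(kdmSBA2(ba_e, ca, r_char, 40, 80, m), oracle)

  # doubling each deviation quadruples the variance term
  v1 <- mean((d - mean(d))^2)
  d2 <- 2 * d
  expect_equal(mean((d2 - mean(d2))^2), 4 * v1)

  # both terms vanish in the idealized limit (then floored with a warning)
  expect_warning(s0 <- kdmSBA2(ca, ca, 1, 40, 70, 8), "floored")
  expect_gt(s0, 0)
  expect_error(kdmSBA2(ba_e, ca, 0, 40, 80, 8))
})

test_that("final BA is a convex combination of BA_E and CA", {
  p <- structure(list(markers = data.frame(biomarker = "x", k = 1, q = 0,
                                           s = 1, r2 = 0.5),
                      m = 1L, s_ba2 = 1), class = "kdm_params")
  # direct substitution: m=1, k=1, q=0, s=1, S_BA^2=1, x=60, CA=50
  r <- kdmBA(60, 50, p)
  expect_equal(r$ba, 55)
  expect_equal(r$ba_e, 60)
  expect_true(r$accelerated)

  # huge S_BA^2 removes the CA pull
  p$s_ba2 <- 1e12
  expect_equal(kdmBA(60, 50, p)$ba, 60, tolerance = 1e-6)

  # betweenness holds for random inputs
  set.seed(42)
  for (i in 1:25) {
    p$s_ba2 <- runif(1, 0.1, 50)
    x <- runif(1, -50, 150); ca <- runif(1, 40, 85)
    r <- kdmBA(x, ca, p)
    expect_gte(r$ba, min(r$ba_e, ca) - 1e-12)
    expect_lte(r$ba, max(r$ba_e, ca) + 1e-12)
  }
})

test_that("negative-slope biomarkers keep their sign and cancel correctly", {
  # a marker falling with age still recovers the age on its regression line
  set.seed(7)
  d <- data.frame(ca = runif(200, 40, 80))
  d$up <- 1.5 * d$ca + 3 + rnorm(200, 0, 1e-4)
  d$down <- -0.8 * d$ca + 90 + rnorm(200, 0, 1e-4)
  p <- suppressWarnings(kdmTrain(d, c("up", "down")))
  expect_lt(p$markers$k[p$markers$biomarker == "down"], 0)
  a <- 63
  on_line <- data.frame(up = 1.5 * a + 3, down = -0.8 * a + 90)
  expect_equal(kdmBAE(on_line, p), a, tolerance = 1e-2)
})

test_that("training/scoring round trip on a noise-free cohort recovers CA", {
  set.seed(11)
  load <- defaultLoadings()
  load$sd <- 1e-4
  cfg <- simConfig(n_subjects = 400, latent_sd = 0, biomarker_loadings = load)
  sim <- simulateCohort(cfg, seed = 3)
  p <- suppressWarnings(kdmTrain(sim$cohort, load$biomarker))
  sc <- suppressWarnings(kdmScore(sim$cohort, p))
  expect_lt(max(abs(sc$ba - sim$cohort$ca)), 0.1)
  expect_lt(max(abs(sc$ba_e - sim$cohort$ca)), 0.1)
})

test_that("parameter serialization round-trips through the flat text format", {
  set.seed(5)
  d <- data.frame(ca = runif(100, 40, 80))
  d$a <- 0.5 * d$ca + rnorm(100)
  d$b <- -0.2 * d$ca + 60 + rnorm(100)
  p <- suppressWarnings(kdmTrain(d, c("a", "b")))
  f <- tempfile(fileext = ".tsv")
  kdmWrite(p, f)
  p2 <- kdmRead(f)
  expect_equal(p2$markers$k, p$markers$k)
  expect_equal(p2$s_ba2, p$s_ba2)
  expect_equal(p2$r_char, p$r_char)
  x <- d[3, c("a", "b")]
  expect_equal(kdmBA(x, d$ca[3], p2)$ba, kdmBA(x, d$ca[3], p)$ba)
})

test_that("weighted training accepts survey weights", {
  set.seed(9)
  d <- data.frame(ca = runif(150, 40, 80))
  d$x <- 0.8 * d$ca + rnorm(150, 0, 2)
  w <- runif(150, 0.5, 3)
  p_u <- kdmFitRegressions(d, "x")
  p_w <- kdmFitRegressions(d, "x", weights = w)
  expect_false(isTRUE(all.equal(p_u$k, p_w$k)))
  # weighted fit matches lm's weighted solution
  ref <- lm(x ~ ca, d, weights = w)
  expect_equal(p_w$k, unname(coef(ref)[2]))
})
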