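# Normalized magnitude, the performance-scaling model, GLM and correlations.

test_that("region means reduce to the obvious answers and a loop oracle", {
  m <- matrix(7, 4, 10)
  region <- matrix(FALSE, 4, 10); region[2, 3] <- TRUE; region[4, 8] <- TRUE
  expect_equal(regionMean(m, region), 7)               # constant ERP
  single <- matrix(FALSE, 4, 10); single[3, 5] <- TRUE
  m2 <- matrix(rnorm(40), 4, 10)
  expect_equal(regionMean(m2, single), m2[3, 5])       # singleton region
  set.seed(80)
  region3 <- matrix(runif(40) < 0.3, 4, 10)
  region3[1, 1] <- TRUE
  acc <- 0; n <- 0
  for (i in 1:4) for (j in 1:10) if (region3[i, j]) {
    acc <- acc + m2[i, j]; n <- n + 1
  }
  expect_equal(regionMean(m2, region3), acc / n, tolerance = 1e-12)
  expect_error(regionMean(m2, matrix(FALSE, 4, 10)), "nonempty")
})

test_that("the performance-scaling model is linear and exact at the anchors", {
  expect_identical(predictedCorrectMagnitude(4, 0.75), 3)
  expect_identical(predictedCorrectMagnitude(5, 1.0), 5)
  expect_identical(predictedCorrectMagnitude(6, 0.5), 3)
  # homogeneity in both arguments
  set.seed(81)
  for (i in 1:10) {
    m <- runif(1, 0, 10); a <- runif(1)
    expect_equal(predictedCorrectMagnitude(2 * m, a),
                 2 * predictedCorrectMagnitude(m, a))
    expect_equal(predictedCorrectMagnitude(m, a / 2),
                 predictedCorrectMagnitude(m, a) / 2)
  }
  expect_error(predictedCorrectMagnitude(4, 1.2), "\\[0, 1\\]")
})

test_that("NM is ~1 for a perfect participant and scale-invariant", {
  cfg <- simConfig(noiseSD = 0,
                   accuracyWM = c("4" = 1, "6" = 1, "8" = 1), accuracyAR = 1)
  sched <- buildSchedule(seed = 82)
  set.seed(82)
  ag <- simulateAgent(sched, cfg)
  tr <- scheduleTrials(sched)
  atwm <- tr$trial[tr$task %in% c("AT", "WM")]
  rec <- synthesizeRecording(sched, ag, cfg, trials = atwm)
  ep <- baselineCorrect(epochRecording(rec))
  region <- matrix(FALSE, 16, 308)
  region[match(c("CPZ", "PZ", "POZ"), channelNames(ep)),
         epochTimes(ep) > 0.35 & epochTimes(ep) < 0.55] <- TRUE
  nm <- computeNM(ep, sched, ag, region)
  expect_identical(nrow(nm), 3L)
  expect_identical(nm$set_size, c(4L, 6L, 8L))
  expect_equal(nm$nm, rep(1, 3), tolerance = 0.15)  # kernel bleed only
  expect_equal(nm$performance, rep(1, 3))
  # global voltage rescaling leaves NM untouched
  ep2 <- ep
  ep2@data <- ep2@data * 3.7
  nm2 <- computeNM(ep2, sched, ag, region)
  expect_equal(nm2$nm, nm$nm, tolerance = 1e-12)
})

test_that("the GLM finds a constructed NM dependence and not a null one", {
  set.seed(83)
  mkRecords <- function(perf) {
    data.frame(participant = rep(sprintf("P%02d", 1:14), each = 3),
               set_size = rep(c(4L, 6L, 8L), 14),
               nm = NA_real_, performance = perf)
  }
  # performance exactly equals nm (values on the k/8 grid)
  perf <- rep(sample(seq(2, 8) / 8, 14, replace = TRUE), each = 3)
  rec <- mkRecords(perf)
  rec$nm <- rec$performance
  out <- glmPerformance(rec)
  expect_identical(out$anova$term, c("set_size", "nm", "set_size:nm"))
  expect_lt(out$anova$p[out$anova$term == "nm"], 1e-4)
  expect_gt(out$anova$p[out$anova$term == "set_size"], 0.05)
  # independent nm under a correctly specified binomial: NM p ~ uniform
  ps <- replicate(120, {
    r <- mkRecords(rbinom(42, 8, 0.7) / 8)
    r$nm <- runif(42)
    glmPerformance(r)$anova$p[2]
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
  # a set-size-dependent slope shows up as an interaction
  r <- mkRecords(NA)
  r$nm <- runif(42, 0.2, 1)
  slope <- c("4" = 0.2, "6" = 1.0, "8" = 2.2)[as.character(r$set_size)]
  eta <- -1 + slope * (r$nm * 4)
  r$performance <- round(8 * stats::plogis(eta)) / 8
  out2 <- glmPerformance(r)
  expect_lt(out2$anova$p[3], 0.05)
  expect_error(glmPerformance(rec[rec$set_size == 4, ]), "set sizes")
})

test_that("per-set-size correlations behave at the anchors and the oracle", {
  rec <- data.frame(set_size = rep(8L, 14),
                    nm = seq(0.3, 1, length.out = 14))
  rec$performance <- 0.2 + 0.7 * rec$nm
  out <- perSetSizeCorrelation(rec, 8)
  expect_equal(out$r, 1, tolerance = 1e-9)
  # ceiling performance: undefined correlation is an error
  recC <- rec; recC$performance <- 1
  expect_error(perSetSizeCorrelation(recC, 8), "variance")
  # covariance-formula oracle on noisy data
  set.seed(84)
  rec$performance <- rec$performance + rnorm(14, sd = 0.1)
  out2 <- perSetSizeCorrelation(rec, 8)
  x <- rec$nm; y <- rec$performance
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out2$r, rOracle, tolerance = 1e-12)
  expect_identical(out2$n, 14L)
  expect_error(perSetSizeCorrelation(rec[1:2, ], 8), "at least 3")
})
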