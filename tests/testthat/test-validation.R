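test_that("LOO cross-validation reproduces the published internal summary", {
  ds <- qsarFixture("table4")
  loo <- looCrossValidation(ds)
  expect_equal(loo$q2, 0.81, tolerance = 0.01 / 0.81)
  expect_equal(loo$rmse, 0.31, tolerance = 0.015 / 0.31)
  expect_equal(loo$mae, 0.27, tolerance = 0.01 / 0.27)
  expect_equal(unname(loo$predictions["8b"]), 6.8746, tolerance = 1e-3)
  ## every published LOO prediction to +/-0.01
  published <- compoundProperties(trainSet(ds))$pIC50_loo
  expect_equal(unname(loo$predictions), published, tolerance = 0.01)
})

test_that("refit-loop LOO equals the hat-matrix shortcut", {
  for (seed in c(1, 7)) {
    ds <- makeToyDataset(n = 14, p = 3, noiseSd = 0.4, seed = seed)
    loop <- looCrossValidation(ds, method = "refit")
    hat <- looCrossValidation(ds, method = "hat")
    expect_equal(loop$predictions, hat$predictions, tolerance = 1e-8)
  }
  ds <- qsarFixture("table4")
  expect_equal(looCrossValidation(ds, "refit")$predictions,
               looCrossValidation(ds, "hat")$predictions, tolerance = 1e-8)
})

test_that("PRESS >= SSE, hence Q2 <= r2, on arbitrary datasets", {
  for (seed in 1:8) {
    ds <- makeToyDataset(n = 12 + seed, p = 3, noiseSd = 0.3 + 0.1 * seed,
                         seed = seed)
    loo <- looCrossValidation(ds)
    st <- fitStatistics(fitQSAR(ds), ds)
    expect_gte(loo$press, st$sse)
    expect_lte(loo$q2, st$r2)
  }
})

test_that("noiseless linear data cross-validates perfectly", {
  ds <- makeToyDataset(n = 10, p = 2, noiseSd = 0, seed = 2)
  loo <- looCrossValidation(ds)
  expect_equal(loo$q2, 1, tolerance = 1e-9)
  expect_lt(max(abs(loo$predictions - activityValues(ds, "train"))), 1e-8)
})

test_that("Rm2 metrics behave at the identity and under argument swap", {
  y <- c(5.1, 6.3, 5.9, 7.2, 6.8, 5.5)
  same <- rmMetrics(y, y)
  expect_equal(same$k, 1)
  expect_equal(same$kPrime, 1)
  expect_equal(same$rm2, 1)
  expect_equal(same$rm2Prime, 1)
  expect_equal(same$deltaRm2, 0)

  yp <- y + c(0.3, -0.2, 0.1, -0.4, 0.2, 0.05)
  a <- rmMetrics(y, yp)
  b <- rmMetrics(yp, y)
  expect_equal(a$k, b$kPrime)
  expect_equal(a$rm2, b$rm2Prime)
  expect_equal(a$rm2Prime, b$rm2)
  expect_false(isTRUE(all.equal(a$rm2, a$rm2Prime)))
  expect_equal(a$deltaRm2, abs(a$rm2 - a$rm2Prime))
  expect_equal(a$rm2Mean, (a$rm2 + a$rm2Prime) / 2)

  expect_error(rmMetrics(rep(1, 5), 1:5), "constant")
  expect_error(rmMetrics(1:2, 1:2), "at least 3")
})

test_that("origin-constrained slopes on the published test predictions", {
  ds <- qsarFixture("table4")
  te <- testSet(ds)
  yObs <- activityValues(te)
  yPredPublished <- compoundProperties(te)$pIC50_pred
  rm <- rmMetrics(yObs, yPredPublished)
  expect_equal(rm$k, 0.96, tolerance = 0.01 / 0.96)
  expect_equal(rm$kPrime, 1.04, tolerance = 0.01 / 1.04)
})

test_that("scaled Rm2 on LOO predictions reproduces the published 0.57", {
  ds <- qsarFixture("table4")
  loo <- looCrossValidation(ds)
  rmS <- rmMetrics(activityValues(ds, "train"), loo$predictions,
                   scaled = TRUE)
  ## the reported cross-validated Rm2 corresponds to the scaled,
  ## reversed-axes variant (see the methods vignette)
  expect_equal(rmS$rm2Prime, 0.57, tolerance = 0.05 / 0.57)
})

test_that("Y-randomization is seeded, bijective and null-behaved", {
  ds <- qsarFixture("table4")
  a <- yRandomization(ds, nRuns = 30, seed = 7)
  b <- yRandomization(ds, nRuns = 30, seed = 7)
  expect_identical(a$runs, b$runs)
  c <- yRandomization(ds, nRuns = 30, seed = 8)
  expect_false(identical(a$runs, c$runs))
  ## random-model fits are much worse than the original
  expect_lt(a$avgR2, 0.5)
  expect_lt(a$avgQ2, 0)
  expect_equal(a$originalR2, 0.881, tolerance = 1e-3)
  expect_true(all(a$runs$R2 >= 0 & a$runs$R2 <= 1))
})

test_that("the identity permutation reproduces the original fit exactly", {
  ds <- qsarFixture("table4")
  n <- sum(splitLabels(ds) == "train")
  yr <- yRandomization(ds, permutations = list(seq_len(n)))
  expect_equal(yr$runs$R2[1], yr$originalR2, tolerance = 1e-12)
  expect_equal(yr$runs$Q2[1], yr$originalQ2, tolerance = 1e-12)
  ## degenerate limit: random models as good as the original -> cRp2 = 0
  expect_equal(yr$crp2, 0)
})

test_that("cRp2 averaging conventions agree to first order", {
  ds <- qsarFixture("table4")
  a <- yRandomization(ds, nRuns = 50, seed = 5, average = "r2")
  b <- yRandomization(ds, nRuns = 50, seed = 5, average = "r")
  expect_identical(a$runs, b$runs)
  expect_lt(abs(a$crp2 - b$crp2), 0.05)
})

test_that("external validation reproduces the published test-set metrics", {
  ds <- qsarFixture("table4")
  ext <- externalValidation(fitQSAR(ds), ds)
  expect_equal(ext$r2Test, 0.71, tolerance = 0.01 / 0.71)
  expect_equal(ext$q2F2, 0.52, tolerance = 0.02 / 0.52)
  expect_equal(ext$k, 0.96, tolerance = 0.01 / 0.96)
  expect_equal(ext$kPrime, 1.04, tolerance = 0.01 / 1.04)
  expect_true(all(ext$checklist$pass))
})

test_that("Q2F2 agrees with the hand-computable sum over printed residuals", {
  ds <- qsarFixture("table4")
  te <- testSet(ds)
  yObs <- activityValues(te)
  yPredPublished <- compoundProperties(te)$pIC50_pred
  trainMean <- mean(activityValues(ds, "train"))
  direct <- 1 - sum((yObs - yPredPublished)^2) /
    sum((yObs - trainMean)^2)
  expect_equal(direct, 0.529, tolerance = 1e-3)
  ext <- externalValidation(fitQSAR(ds), ds)
  expect_equal(ext$q2F2, direct, tolerance = 5e-3)
})

test_that("perfect predictions pass the whole external checklist", {
  ds <- makeToyDataset(n = 15, p = 2, noiseSd = 0, seed = 9,
                       split = rep(c("train", "train", "test"), 5))
  ext <- externalValidation(fitQSAR(ds), ds)
  expect_equal(ext$r2Test, 1, tolerance = 1e-9)
  expect_equal(ext$q2F2, 1, tolerance = 1e-9)
  expect_true(all(ext$checklist$pass))
  ## empty test set is an explicit error
  allTrain <- makeToyDataset(n = 10, p = 2, noiseSd = 0.1, seed = 1)
  expect_error(externalValidation(fitQSAR(allTrain), allTrain), "empty")
})
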