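test_that("training-set correlations reproduce the published matrix", {
  ds <- qsarFixture("table4")
  R <- correlationMatrix(ds, subset = "train")
  published <- qsarFixture("table3")
  expect_equal(R[rownames(published), colnames(published)],
               published, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(unname(R["SlogP_VSA4", "pIC50"]), 0.7195, tolerance = 1e-3)
  expect_equal(unname(diag(R)), rep(1, 5))
  expect_identical(R, t(R))
})

test_that("correlation handles exact affine dependence and constants", {
  x <- 1:10
  X <- cbind(d1 = x, d2 = 2 * x + 3, d3 = rep(1, 10))
  rownames(X) <- paste0("c", 1:10)
  ds <- QSARDataset(X, activity = rnorm(10) + x, split = rep("train", 10))
  R <- correlationMatrix(ds)
  expect_equal(unname(R["d1", "d2"]), 1.0)
  expect_true(all(is.na(R["d3", ])))
  expect_identical(attr(R, "undefined"), "d3")
})

test_that("VIF and tolerance reproduce the published collinearity table", {
  ds <- qsarFixture("table4")
  v <- vifValues(ds, subset = "train")
  t2 <- qsarFixture("table2")
  expect_equal(unname(v[t2$descriptor]), t2$vif, tolerance = 0.05 / 1.5)
  expect_equal(unname(toleranceValues(ds)[t2$descriptor]), t2$tolerance,
               tolerance = 2e-3)
  expect_equal(unname(v["BCUT_SMR_2"]), 1.9545, tolerance = 1e-3)
  expect_true(all(v < 5))
  expect_equal(v, 1 / toleranceValues(ds))
})

test_that("VIF is 1 for orthogonal columns and unbounded for duplicates", {
  set.seed(3)
  ## mutually orthogonal centred columns -> no mutual explanation
  Q <- qr.Q(qr(scale(matrix(rnorm(18), 6, 3), scale = FALSE)))[, 1:2]
  dimnames(Q) <- list(paste0("c", 1:6), c("d1", "d2"))
  ds <- QSARDataset(Q, activity = rnorm(6), split = rep("train", 6))
  expect_equal(unname(vifValues(ds)), c(1, 1), tolerance = 1e-10)

  dup <- matrix(rnorm(8), 8, 1)[, c(1, 1)]
  dimnames(dup) <- list(paste0("c", 1:8), c("d1", "d2"))
  ds2 <- QSARDataset(dup, activity = rnorm(8), split = rep("train", 8))
  expect_true(all(is.infinite(vifValues(ds2))))
})

test_that("regression-definition VIF equals inverse-correlation diagonal", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30; p <- 4
    X <- matrix(rnorm(n * p), n, p) %*%
      chol(0.5 * diag(p) + 0.5)         # induce collinearity
    dimnames(X) <- list(paste0("c", 1:n), paste0("d", 1:p))
    ds <- QSARDataset(X, activity = rnorm(n), split = rep("train", n))
    viaInverse <- diag(solve(cor(X)))
    expect_equal(unname(vifValues(ds)), unname(viaInverse),
                 tolerance = 1e-9)
  }
})

test_that("screening keeps all four published descriptors under VIF < 5", {
  rep <- screenDescriptors(qsarFixture("table4"), maxVIF = 5)
  expect_setequal(rep$kept, c("BCUT_SMR_2", "logP(o/w)", "SlogP_VSA4",
                              "vsurf_IW3"))
  expect_length(rep$dropped, 0)
  expect_false(rep$empty)
})

test_that("screening drops constant columns and breaks exact collinearity", {
  ds <- makeToyDataset(n = 15, p = 3, noiseSd = 0.1, seed = 2)
  X <- descriptorMatrix(ds)
  X <- cbind(X, d4 = rep(2, 15), d5 = X[, "d1"])  # constant + duplicate
  ds2 <- QSARDataset(X, activity = activityValues(ds),
                     split = splitLabels(ds))
  rep <- screenDescriptors(ds2, maxVIF = 5)
  expect_identical(unname(rep$dropped["d4"]), "zero-variance")
  ## exactly one of the identical pair survives, and the survivor set is
  ## verified collinearity-free by brute force
  expect_identical(sum(c("d1", "d5") %in% rep$kept), 1L)
  expect_true(all(rep$vif <= 5))
  sub <- ds2[rep$kept, ]
  expect_true(all(vifValues(sub) <= 5))
})

test_that("screening is idempotent", {
  ds <- makeToyDataset(n = 20, p = 4, noiseSd = 0.3, seed = 6)
  X <- descriptorMatrix(ds)
  X <- cbind(X, d5 = X[, "d1"] + 0.01 * rnorm(20))  # near-duplicate
  ds2 <- QSARDataset(X, activity = activityValues(ds),
                     split = splitLabels(ds))
  first <- screenDescriptors(ds2, maxVIF = 5)
  again <- screenDescriptors(ds2[first$kept, ], maxVIF = 5)
  expect_identical(sort(again$kept), sort(first$kept))
  expect_length(again$dropped, 0)
})

test_that("screening reports an explicit empty result, not silent success", {
  X <- matrix(1, 6, 2, dimnames = list(paste0("c", 1:6), c("d1", "d2")))
  ds <- QSARDataset(X, activity = rnorm(6), split = rep("train", 6))
  rep <- screenDescriptors(ds)
  expect_true(rep$empty)
  expect_length(rep$kept, 0)
  expect_identical(unname(rep$dropped), rep("zero-variance", 2))
})
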