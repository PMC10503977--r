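test_that("ic50ToPIC50 converts micromolar IC50 to molar -log10", {
  expect_equal(ic50ToPIC50(0.016), 7.7959, tolerance = 1e-4)
  expect_equal(ic50ToPIC50(8.39), 5.0762, tolerance = 1e-4)
  expect_identical(ic50ToPIC50(1.0), 6.0)
  expect_identical(ic50ToPIC50(1.0, unit = "M"), 0)
  expect_identical(ic50ToPIC50(1.0, unit = "nM"), 9)
  expect_error(ic50ToPIC50(0), "positive")
  expect_error(ic50ToPIC50(-3), "positive")
})

test_that("pIC50 conversion is strictly decreasing and log-linear", {
  x <- c(0.01, 0.5, 1, 7, 100)
  expect_true(all(diff(ic50ToPIC50(sort(x))) < 0))
  expect_equal(ic50ToPIC50(10 * x), ic50ToPIC50(x) - 1)
})

test_that("the packaged modelling table loads with its published split", {
  ds <- qsarFixture("table4")
  expect_s4_class(ds, "QSARDataset")
  expect_identical(ncol(ds), 25L)
  expect_identical(length(descriptorNames(ds)), 4L)
  expect_identical(sum(splitLabels(ds) == "train"), 20L)
  expect_identical(sort(names(which(splitLabels(ds) == "test"))),
                   sort(c("10d", "10h", "11a", "11b", "12a")))
  expect_equal(unname(activityValues(ds)["12a"]), 5.0762)
  ## published predictions ride along as compound properties
  expect_true(all(c("pIC50_pred", "pIC50_loo") %in%
                    colnames(compoundProperties(ds))))
})

test_that("table loading rejects malformed input with informative errors", {
  dup <- tempfile(fileext = ".csv")
  writeLines(c("compound,d1,pIC50", "a,1,5", "a,2,6"), dup)
  expect_error(readQSARTable(dup), "duplicate compound ids.*a")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("compound,d1,pIC50", "a,1,5", "b,oops,6"), bad)
  expect_error(readQSARTable(bad), "non-numeric.*'d1'.*row 2")

  empty <- tempfile(fileext = ".csv")
  writeLines("compound,d1,pIC50", empty)
  expect_error(readQSARTable(empty), "no compound rows")

  one <- tempfile(fileext = ".csv")
  writeLines(c("compound,d1", "solo,0.5"), one)
  ds1 <- readQSARTable(one)
  expect_identical(ncol(ds1), 1L)
  expect_identical(descriptorNames(ds1), "d1")
  expect_true(is.na(activityValues(ds1)))
})

test_that("missing cells load as NA, never zero", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound,d1,d2,pIC50", "a,1,,5", "b,2,3,6", "c,4,5,7"), f)
  ds <- readQSARTable(f)
  expect_true(is.na(descriptorMatrix(ds)["a", "d2"]))
  expect_false(any(descriptorMatrix(ds) == 0, na.rm = TRUE))
})

test_that("write/read round trip preserves every numeric cell exactly", {
  ds <- makeToyDataset(n = 9, p = 3, noiseSd = 0.2, seed = 4,
                       split = rep(c("train", "test", "train"), 3))
  f <- tempfile(fileext = ".csv")
  writeQSARTable(ds, f)
  back <- readQSARTable(f)
  expect_identical(descriptorMatrix(back), descriptorMatrix(ds))
  expect_identical(activityValues(back), activityValues(ds))
  expect_identical(splitLabels(back), splitLabels(ds))
})

test_that("splitDataset assigns round(n*fraction) reproducibly", {
  ds <- qsarFixture("table4")
  s1 <- splitDataset(ds, 0.8, seed = 11)
  expect_identical(sum(splitLabels(s1) == "train"), 20L)
  expect_identical(sum(splitLabels(s1) == "test"), 5L)
  s2 <- splitDataset(ds, 0.8, seed = 11)
  expect_identical(splitLabels(s1), splitLabels(s2))
  expect_identical(unique(splitLabels(splitDataset(ds, 1.0, seed = 1))),
                   "train")
  expect_error(splitDataset(ds, 0), "0, 1")
  expect_error(splitDataset(ds, 1.2), "0, 1")
  ## the global RNG stream is not consumed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(splitDataset(ds, 0.8, seed = 3)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("dataset validity catches duplicate ids and missing activity", {
  X <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "b"), c("d1", "d2")))
  expect_error(QSARDataset(X, activity = 1:3, split = rep("train", 3)),
               "duplicate")
  rownames(X) <- c("a", "b", "c")
  expect_error(
    QSARDataset(X, activity = c(1, NA, 3), split = rep("train", 3)),
    "activity")
  ## NA activity is fine for unassigned compounds
  expect_s4_class(
    QSARDataset(X, activity = c(1, NA, 3),
                split = c("train", "unassigned", "train")),
    "QSARDataset")
})

test_that("per-table fixtures keep their published values verbatim", {
  t1 <- qsarFixture("table1")
  expect_identical(nrow(t1), 25L)
  expect_false("9b" %in% t1$compound)           # absent from this table
  expect_equal(t1$pIC50[t1$compound == "10b"], 7.7959)
  s4 <- qsarFixture("tableS4")
  expect_identical(nrow(s4), 25L)
  expect_false("12a" %in% s4$compound)          # absent from this table
  expect_equal(s4$pIC50[s4$compound == "10b"], 7.7958)
  t3 <- qsarFixture("table3")
  expect_identical(dim(t3), c(5L, 5L))
  expect_identical(t3, t(t3))
})
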