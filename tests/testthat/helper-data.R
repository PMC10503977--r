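## Small deterministic datasets built in code for the unit tests.

# n compounds, p independent standard-normal descriptors, exact linear
# response unless noiseSd > 0.
makeToyDataset <- function(n = 12, p = 3, coefs = seq_len(p), intercept = 1,
                           noiseSd = 0, seed = 1, split = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%02d", seq_len(n)),
                              paste0("d", seq_len(p))))
  y <- intercept + drop(X %*% coefs) + rnorm(n, sd = noiseSd)
  if (is.null(split)) split <- rep("train", n)
  QSARDataset(X, activity = y, split = split)
}

table4Train <- function() trainSet(qsarFixture("table4"))
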