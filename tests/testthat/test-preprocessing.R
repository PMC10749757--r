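test_that("TPM matches the hand-computed definition and normalizes to 1e6", {
  counts <- matrix(c(10, 20), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- tpmFromCounts(counts, lengths = c(1000, 2000))
  expect_equal(as.numeric(tpm), c(5e5, 5e5))

  one <- tpmFromCounts(matrix(7, 1, 1), lengths = 500)
  expect_equal(as.numeric(one), 1e6)

  set.seed(11)
  counts <- matrix(rpois(60, 40), nrow = 12)
  lengths <- runif(12, 200, 5000)
  tpm <- tpmFromCounts(counts, lengths)
  expect_equal(colSums(tpm), rep(1e6, 5), tolerance = 1e-6)
  # scale invariance per sample
  expect_equal(tpmFromCounts(counts * 2, lengths), tpm)

  zero <- counts; zero[, 3] <- 0
  expect_error(tpmFromCounts(zero, lengths), "3",
               class = "crossGEx_validation_error")
})

test_that("dispersion trend recovery on NB data with known alpha(mu)", {
  set.seed(42)
  mu <- exp(runif(500, log(5), log(5000)))
  alpha <- 0.05 + 2 / mu
  y <- matrix(rnbinom(500 * 50, mu = rep(mu, 50), size = rep(1 / alpha, 50)),
              nrow = 500)
  tr <- fitDispersionTrend(y)
  p <- trendParams(tr)
  expect_lt(abs(p[["a0"]] - 0.05) / 0.05, 0.5)
  expect_lt(abs(p[["a1"]] - 2) / 2, 0.5)

  # Poisson data: asymptotic dispersion collapses towards zero
  set.seed(43)
  yp <- matrix(rpois(500 * 50, rep(mu, 50)), nrow = 500)
  expect_lt(trendParams(fitDispersionTrend(yp))[["a0"]], 0.01)

  expect_error(fitDispersionTrend(matrix(5, 20, 10)),
               class = "crossGEx_fit_error")
  expect_error(fitDispersionTrend(matrix(1:8, 4, 2)),
               class = "crossGEx_fit_error")
})

test_that("the closed-form VST matches its stabilizing integral", {
  set.seed(7)
  qs <- c(1, 2, 5, 10, 50, 100, 1000, 1e4)
  for (i in 1:20) {
    a0 <- runif(1, 0.01, 0.5); a1 <- runif(1, 0, 5)
    tr <- DispersionTrend(a0, a1)
    f <- vstTransform(qs, tr)
    oracle <- vapply(qs, function(q)
      integrate(function(m) 1 / sqrt((1 + a1) * m + a0 * m^2),
                lower = 1, upper = q, rel.tol = 1e-12)$value,
      numeric(1)) * sqrt(a0) / log(2)
    expect_equal(f - f[1L], oracle, tolerance = 1e-6)
  }
})

test_that("VST is strictly monotone with a log2-like tail", {
  set.seed(8)
  for (i in 1:10) {
    tr <- DispersionTrend(runif(1, 0.01, 1), runif(1, 0, 5))
    q <- sort(c(0, runif(50, 0, 1e4)))
    f <- vstTransform(q, tr)
    expect_true(all(diff(f) > 0))
  }
  tr <- DispersionTrend(0.05, 2)
  expect_equal(vstTransform(2e5, tr) - vstTransform(1e5, tr), log2(2),
               tolerance = 1e-3)
  expect_error(vstTransform(c(1, NA), tr), class = "crossGEx_validation_error")
})

test_that("VST flattens the variance-mean relationship of NB data", {
  set.seed(21)
  decades <- 10^(1:4)
  rawVar <- vstVar <- numeric(length(decades))
  tr <- DispersionTrend(0.05, 2)
  for (d in seq_along(decades)) {
    mu <- decades[d]
    y <- matrix(rnbinom(100 * 50, mu = mu, size = 1 / (0.05 + 2 / mu)),
                nrow = 100)
    rawVar[d] <- mean(apply(y, 1, var))
    vstVar[d] <- mean(apply(vstTransform(y, tr), 1, var))
  }
  expect_gt(max(rawVar) / min(rawVar), 10)
  expect_lt(max(vstVar) / min(vstVar), 3)
})

test_that("applyVst fits per species by default and honors the fallback", {
  spec <- SimSpec(nGenes = 50, nSpecies = 2, nTissues = 3,
                  nSamplesPerCell = 6, seed = 5)
  tab <- simulateCounts(spec)
  fitted <- applyVst(tab)
  expect_identical(exprScale(fitted), "vst")
  expect_length(grep("vst per species", provenance(fitted)), 2L)

  fb <- applyVst(tab, fallbackLog2 = TRUE)
  expect_equal(exprData(fb)$value, log2(exprData(tab)$value + 1))
  expect_error(applyVst(fb), class = "crossGEx_usage_error")
})

test_that("medianByGroup uses the conventional median and marks missing cells", {
  rec <- data.frame(
    gene_id = c(rep("g1", 3), rep("g2", 2)),
    species = "human",
    tissue = c("a", "a", "a", "a", "a"),
    sample_id = c("s1", "s2", "s3", "s1", "s2"),
    value = c(1, 2, 10, 1, 3))
  rec <- rbind(rec, data.frame(gene_id = "g1", species = "human", tissue = "b",
                               sample_id = "s1", value = 7))
  tab <- ExpressionTable(rec, "vst")
  mm <- medianByGroup(tab, axis = "tissue")
  v <- medianValues(mm)
  expect_equal(v["g1", "a"], 2)       # odd n: middle value
  expect_equal(v["g2", "a"], 2)       # even n: midpoint
  expect_true(is.na(v["g2", "b"]))    # no samples: missing, not 0
  expect_equal(medianContext(mm), "human")

  # permutation invariance under sample relabeling
  rec2 <- rec
  rec2$sample_id <- sub("s1", "sx", rec2$sample_id)
  mm2 <- medianByGroup(ExpressionTable(rec2, "vst"), axis = "tissue")
  expect_equal(medianValues(mm2), v)
})

test_that("medianByGroup slices per species/tissue as requested", {
  vst <- exampleVst(seed = 3)
  expect_error(medianByGroup(vst, axis = "tissue"),
               class = "crossGEx_usage_error")
  mm <- medianByGroup(vst, axis = "tissue", species = "human")
  expect_equal(dim(medianValues(mm)), c(5L, 5L))
  ms <- medianByGroup(vst, axis = "species", tissue = "tissue1")
  expect_equal(colnames(medianValues(ms)), c("human", "mouse"))
  expect_equal(medianContext(ms), "tissue1")
})

test_that("min-max scaling maps onto [0,1] preserving order", {
  expect_equal(as.numeric(minMaxScale(c(3, 5, 9))), c(0, 1/3, 1))

  const <- minMaxScale(c(7, 7, 7))
  expect_equal(as.numeric(const), c(0, 0, 0))
  expect_true(attr(const, "degenerate"))

  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(10)
    s <- minMaxScale(x)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(rank(s), rank(x))
    # affine invariance
    a <- rnorm(1); b <- runif(1, 0.1, 10)
    expect_equal(as.numeric(minMaxScale(a + b * x)), as.numeric(s))
  }

  withNA <- minMaxScale(c(1, NA, 3))
  expect_true(is.na(withNA[2]))
  expect_error(minMaxScale(c(NA_real_, NA_real_)),
               class = "crossGEx_validation_error")
})
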