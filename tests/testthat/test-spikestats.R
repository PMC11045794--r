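test_that("binarization uses half-open windows and saturates", {
  # one neuron firing at timestep 7 with width-5 bins: second bin only
  r <- makeRaster(times = 7L, neurons = 1L, nTimesteps = 10L, nNeurons = 1L)
  b <- binarize(r, 5)
  expect_equal(nBins(b), 2L)
  expect_equal(as.vector(sigmaMatrix(b)), c(-1L, 1L))
  # empty raster of length 10: two all-down bins
  e <- binarize(makeRaster(integer(), integer(), 10L, 2L), 5)
  expect_true(all(sigmaMatrix(e) == -1L))
  # three firings inside one bin still one up-state
  r3 <- makeRaster(c(0L, 1L, 3L), c(1L, 1L, 1L), 5L, 1L)
  expect_equal(as.vector(sigmaMatrix(binarize(r3, 5))), 1L)
  # trailing partial bin is discarded
  r4 <- makeRaster(11L, 1L, 12L, 1L)
  expect_equal(nBins(binarize(r4, 5)), 2L)
  expect_error(binarize(r4, 0), "binWidth")
})

test_that("moments reproduce hand-computed toy cases", {
  m <- computeMoments(toyRaster("alternating_pair"), withTriplets = TRUE)
  expect_equal(meanSigma(m), c(0, 0))
  expect_equal(pairSigma(m)[1, 2], 1)
  expect_equal(correlations(m)[1, 2], 1)

  up <- computeMoments(toyRaster("all_up"), withTriplets = TRUE)
  expect_equal(meanSigma(up), rep(1, 3))
  expect_equal(correlations(up)[upper.tri(diag(3))], rep(0, 3))
  expect_equal(tripleCorrelations(up)$value, 0)
  expect_equal(upCountDistribution(up), c(0, 0, 0, 1))  # P(K = N) = 1

  st <- computeMoments(toyRaster("staircase_4bins"))
  expect_equal(upCountDistribution(st), c(0.25, 0.5, 0.25))

  tri <- computeMoments(toyRaster("alternating_triplet"),
                        withTriplets = TRUE)
  expect_equal(tripleCorrelations(tri)$value, 0)
})

test_that("moment identities hold exactly on random binned data", {
  set.seed(11)
  for (rep in 1:5) {
    b <- sampleIndependentRaster(runif(6, 0.1, 0.9), nBins = 200)
    m <- computeMoments(b)
    off <- upper.tri(diag(6))
    expect_true(all(abs(pairSigma(m)) <= 1 + 1e-12))
    expect_equal(correlations(m)[off],
                 (pairSigma(m) - outer(meanSigma(m), meanSigma(m)))[off],
                 tolerance = 1e-12)
    expect_true(all(abs(correlations(m)[off]) <= 2))
    pk <- upCountDistribution(m)
    expect_equal(sum(pk), 1, tolerance = 1e-12)
    # mean up-count consistency: sum_K K P(K) = sum_i (1 + <sigma_i>)/2
    expect_equal(sum((seq_along(pk) - 1) * pk),
                 sum((meanSigma(m) + 1) / 2), tolerance = 1e-12)
    # firing-rate identity
    expect_equal(firingRates(m, 5), (meanSigma(m) + 1) / 10)
  }
})

test_that("independent-spin correlations shrink as 1/sqrt(Nb)", {
  set.seed(12)
  nbs <- c(400, 1600, 6400, 25600)
  maxC <- vapply(nbs, function(nb) {
    m <- computeMoments(sampleIndependentRaster(rep(0.3, 8), nb))
    max(abs(correlations(m)[upper.tri(diag(8))]))
  }, numeric(1))
  slope <- coef(lm(log(maxC) ~ log(nbs)))[2]
  expect_lt(abs(slope - (-0.5)), 0.2)
})

test_that("the discrete MLE recovers known power-law exponents", {
  set.seed(13)
  for (tau in c(1.5, 2.0)) {
    x <- rPowerLaw(1e5, tau, 1, 1e4)
    f <- fitPowerLaw(x, xMin = 1, xMax = 1e4, nBoot = 10)
    expect_lt(abs(f$exponent - tau), 0.05)
    expect_true(is.finite(f$se) && f$se < 0.05)
    expect_lt(f$ks, 0.05)
  }
})

test_that("power-law fitting rejects unusable input", {
  expect_error(fitPowerLaw(rep(5, 50), xMin = 2), "fewer than 100")
  expect_error(fitPowerLaw(rep(5, 500), xMin = 2), "degenerate")
})

test_that("moment serialization round-trips", {
  set.seed(14)
  m <- computeMoments(sampleIndependentRaster(runif(5, 0.2, 0.8), 500))
  pre <- file.path(withr::local_tempdir(), "mom")
  writeMoments(m, pre)
  back <- readMoments(pre)
  expect_equal(meanSigma(back), meanSigma(m), tolerance = 1e-12)
  expect_equal(pairSigma(back), pairSigma(m), tolerance = 1e-12)
  expect_equal(upCountDistribution(back), upCountDistribution(m),
               tolerance = 1e-12)
  expect_equal(nBins(back), nBins(m))
})

test_that("block-bootstrap SEs agree with iid SEs on independent bins", {
  set.seed(15)
  b <- sampleIndependentRaster(rep(0.3, 4), 4000)
  se <- blockBootstrapSE(b, blockLength = 10, nBoot = 60)
  iid <- sqrt((1 - meanSigma(computeMoments(b))^2) / 4000)
  expect_true(all(se / iid > 0.5 & se / iid < 2))
  expect_error(blockBootstrapSE(b, blockLength = 3000), "too short")
})
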