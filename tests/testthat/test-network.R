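test_that("configuration validation rejects inconsistent parameters", {
  expect_error(networkConfig(N = 1), "N must be")
  expect_error(networkConfig(N = 50, koutMin = 0), "koutMin")
  expect_error(networkConfig(N = 50, koutMin = 8, koutMax = 4), "koutMin")
  expect_error(networkConfig(N = 10, koutMax = 10), "koutMax must be < N")
  expect_error(networkConfig(N = 50, pIn = 0.7), "pIn")
  expect_error(networkConfig(N = 50, gInitLow = 0.06, gInitHigh = 0.04),
               "gInitLow")
})

test_that("cube side follows L = (N/rho)^(1/3)", {
  net <- buildNetwork(networkConfig(N = 500, seed = 1))
  expect_equal(sideLength(net), (500 / 0.016)^(1 / 3), tolerance = 1e-12)
  expect_equal(sideLength(net), 31.498, tolerance = 1e-4)
  expect_true(all(neuronPositions(net) >= 0 &
                  neuronPositions(net) <= sideLength(net)))
})

test_that("networks are reproducible under a fixed seed", {
  a <- buildNetwork(networkConfig(N = 80, seed = 7))
  b <- buildNetwork(networkConfig(N = 80, seed = 7))
  expect_identical(edgeTable(a), edgeTable(b))
  expect_identical(neuronPositions(a), neuronPositions(b))
})

test_that("degree sequence respects the configured bounds and repair", {
  for (N in c(30, 120)) {
    for (s in 1:4) {
      net <- suppressMessages(
        buildNetwork(networkConfig(N = N, seed = 1000 * N + s)))
      kout <- outDegree(net)
      # repair may add one edge to a donor, capped at koutMax
      expect_true(all(kout >= 2 & kout <= 20))
      expect_true(all(inDegree(net) >= 1))
      expect_false(any(edgeTable(net)$source == edgeTable(net)$target))
    }
  }
})

test_that("out-degrees follow the truncated power law with exponent 2", {
  set.seed(42)
  net <- buildNetwork(networkConfig(N = 2000, seed = 42))
  f <- fitPowerLaw(outDegree(net), xMin = 2, xMax = 20, nBoot = 30)
  expect_lt(abs(f$exponent - 2), 2 * max(f$se, 0.03))
})

test_that("edge distances decay exponentially with the configured scale", {
  net <- suppressMessages(buildNetwork(networkConfig(N = 1000, seed = 3)))
  ed <- edgeTable(net)
  p <- neuronPositions(net)
  r <- sqrt(rowSums((p[ed$source, ] - p[ed$target, ])^2))
  # near field (r < L/2): the edge-distance frequency relative to the
  # all-pair distance frequency isolates the kernel from the geometry;
  # its log regression slope should be -1/r0
  L <- sideLength(net)
  rAll <- as.vector(dist(p))
  breaks <- seq(0, L / 2, length.out = 15)
  hE <- hist(r[r < L / 2], breaks = breaks, plot = FALSE)
  hA <- hist(rAll[rAll < L / 2], breaks = breaks, plot = FALSE)
  keep <- hE$counts > 10 & hA$counts > 10
  ratio <- hE$counts[keep] / hA$counts[keep]
  slope <- coef(lm(log(ratio) ~ hE$mids[keep]))[2]
  expect_lt(abs(slope - (-1 / 5)), 0.2 * (1 / 5))
})

test_that("inhibitory labels are an exact count, chosen at random", {
  net <- buildNetwork(networkConfig(N = 101, pIn = 0.2, seed = 5))
  expect_identical(sum(isInhibitory(net)), as.integer(round(0.2 * 101)))
  net0 <- buildNetwork(networkConfig(N = 120, pIn = 0, seed = 5))
  expect_false(any(isInhibitory(net0)))
  expect_true(all(edgeTable(net0)$sign == 1L))
})

test_that("network serialization round-trips exactly", {
  net <- buildNetwork(networkConfig(N = 40, pIn = 0.1, seed = 9))
  pre <- file.path(withr::local_tempdir(), "net")
  writeNetwork(net, pre)
  back <- readNetwork(pre)
  expect_identical(back@edgeSrc, net@edgeSrc)
  expect_identical(back@edgeDst, net@edgeDst)
  expect_equal(back@strength, net@strength, tolerance = 0)
  expect_equal(back@positions, net@positions, tolerance = 0,
               ignore_attr = TRUE)
  expect_identical(back@inhibitory, net@inhibitory)
  expect_equal(back@sideLength, net@sideLength, tolerance = 0)
})
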