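test_that("the Hamiltonian matches hand evaluation and symmetry", {
  m <- isingModel(h = c(0.5, -0.5), J = matrix(c(0, 1, 1, 0), 2))
  expect_equal(isingHamiltonian(m, c(1, -1)), 0)
  expect_equal(isingEnergy(m, c(1, -1)), 0)
  z <- isingModel(h = rep(0, 4), J = matrix(0, 4, 4))
  for (s in list(c(1, 1, 1, 1), c(-1, 1, -1, 1)))
    expect_equal(isingHamiltonian(z, s), 0)
  # Z2 symmetry of the coupling term at zero field
  set.seed(1)
  jm <- randomIsingModel(5, hSd = 0)
  s <- sample(c(-1, 1), 5, replace = TRUE)
  expect_equal(isingHamiltonian(jm, s), isingHamiltonian(jm, -s),
               tolerance = 1e-12)
  expect_error(isingHamiltonian(m, c(1, -1, 1)), "length")
  expect_error(isingHamiltonian(m, c(1, 0)), "-1 or \\+1")
})

test_that("exact enumeration reproduces closed forms", {
  one <- isingModel(h = 0.5, J = matrix(0, 1, 1))
  expect_equal(meanSigma(exactMoments(one, 1)), tanh(0.5),
               tolerance = 1e-12)
  two <- isingModel(h = c(0, 0), J = matrix(c(0, 0.3, 0.3, 0), 2))
  expect_equal(pairSigma(exactMoments(two, 1))[1, 2], tanh(0.3),
               tolerance = 1e-12)
  # factorized model: zero connected correlations
  set.seed(2)
  free <- isingModel(rnorm(6), matrix(0, 6, 6))
  C <- correlations(exactMoments(free, 1))
  expect_lt(max(abs(C[upper.tri(C)])), 1e-12)
  expect_equal(meanSigma(exactMoments(free, 1)), tanh(free@h),
               tolerance = 1e-12)
  expect_error(exactMoments(randomIsingModel(21)), "N > 20")
})

test_that("Metropolis sampling agrees with enumeration", {
  set.seed(3)
  mod <- randomIsingModel(5)
  ex <- exactMoments(mod, 1)
  s <- metropolisSample(mod, nSamples = 8000, seed = 4, withPK = TRUE)
  n <- 8000
  seM <- pmax(sqrt((1 - meanSigma(ex)^2) / n), 1e-3)
  expect_true(all(abs(meanSigma(s$moments) - meanSigma(ex)) < 4 * seM))
  off <- upper.tri(diag(5))
  seP <- pmax(sqrt((1 - pairSigma(ex)[off]^2) / n), 1e-3)
  expect_true(all(abs(pairSigma(s$moments)[off] - pairSigma(ex)[off]) <
                    4 * seP))
  # free spins stay unbiased at any temperature
  free <- isingModel(rep(0, 6), matrix(0, 6, 6))
  sf <- metropolisSample(free, T = 2.5, nSamples = 5000, seed = 5)
  expect_true(all(abs(meanSigma(sf$moments)) < 4 / sqrt(5000)))
})

test_that("a deep all-down model frozen at low T stays in its ground state", {
  mod <- isingModel(rep(-1, 6), matrix(0, 6, 6))
  s <- metropolisSample(mod, T = 0.01, nSamples = 500, burnIn = 100,
                        initPolicy = "all_down", seed = 6)
  expect_equal(unique(s$M), -6)
  expect_equal(meanSigma(s$moments), rep(-1, 6))
  expect_error(metropolisSample(mod, initPolicy = "sideways"))
})

test_that("detailed balance: N = 3 visit frequencies match Boltzmann", {
  set.seed(7)
  mod <- randomIsingModel(3)
  b <- sampleIsingRaster(mod, 30000, method = "metropolis", thin = 6,
                         seed = 9)
  code <- colSums((sigmaMatrix(b) > 0) * c(1L, 2L, 4L))  # 0..7
  obs <- tabulate(code + 1L, nbins = 8L)
  S <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  H <- apply(S, 1, function(ss) isingHamiltonian(mod, ss))
  p <- exp(-H) / sum(exp(-H))
  ord <- order(((S > 0) %*% c(1, 2, 4))[, 1])
  expect_gt(suppressWarnings(chisq.test(obs, p = p[ord])$p.value), 0.01)
})

test_that("the learning update moves parameters by the printed rule", {
  m <- isingModel(h = c(0, 0), J = matrix(0, 2, 2))
  cfg <- bmConfig(2, eta0 = 0.1, alpha = 0.4)
  tgt <- methods::new("MomentSet", meanSigma = c(0.2, 0),
                      pairSigma = diag(2), correlation = diag(2) * NA,
                      nSamples = 1, pk = numeric(),
                      triples = data.frame(i = integer(), j = integer(),
                                           k = integer(), value = numeric()),
                      meta = list())
  cur <- methods::new("MomentSet", meanSigma = c(0.4, 0),
                      pairSigma = diag(2), correlation = diag(2) * NA,
                      nSamples = 1, pk = numeric(),
                      triples = data.frame(i = integer(), j = integer(),
                                           k = integer(), value = numeric()),
                      meta = list())
  # mismatch 0.2 at x = 1 with eta_h = 0.1: h decreases by 0.02
  up <- bmUpdate(m, tgt, cur, 1, cfg)
  expect_equal(fields(up), c(-0.02, 0), tolerance = 1e-12)
  # zero mismatch is a fixed point
  same <- bmUpdate(m, tgt, tgt, 1, cfg)
  expect_equal(fields(same), fields(m))
  expect_equal(couplings(same), couplings(m))
  # eta_h / eta_J = 2 exactly at every iteration: couple a pair mismatch
  tgt2 <- tgt; tgt2@pairSigma[1, 2] <- tgt2@pairSigma[2, 1] <- 0.0
  cur2 <- cur; cur2@pairSigma[1, 2] <- cur2@pairSigma[2, 1] <- 0.2
  for (x in c(1, 7, 100)) {
    up2 <- bmUpdate(m, tgt2, cur2, x, cfg)
    dh <- fields(up2)[1] - fields(m)[1]
    dJ <- couplings(up2)[1, 2] - couplings(m)[1, 2]
    expect_equal(dh / dJ, 2, tolerance = 1e-12)
  }
})

test_that("exact-gradient learning recovers a known model", {
  set.seed(10)
  gen <- randomIsingModel(6, hSd = 0.4, jSd = 0.2)
  target <- exactMoments(gen, 1)
  fit <- bmFit(target, bmConfig(6, nIter = 4000, seed = 11),
               gradientMode = "exact")
  expect_lt(max(abs(fields(fit$model) - gen@h)), 1e-3)
  expect_lt(max(abs(couplings(fit$model) - gen@J)), 1e-3)
})

test_that("uncorrelated targets yield the factorized closed form", {
  set.seed(12)
  ms <- runif(5, -0.6, 0.2)
  tgt <- methods::new("MomentSet", meanSigma = ms,
                      pairSigma = outer(ms, ms) + diag(1 - ms^2),
                      correlation = matrix(0, 5, 5), nSamples = 1,
                      pk = numeric(),
                      triples = data.frame(i = integer(), j = integer(),
                                           k = integer(), value = numeric()),
                      meta = list())
  fit <- bmFit(tgt, bmConfig(5, nIter = 3000, seed = 13),
               gradientMode = "exact")
  expect_lt(max(abs(couplings(fit$model))), 5e-3)
  expect_equal(fields(fit$model), atanh(ms), tolerance = 5e-3)
})

test_that("masked couplings stay pinned at zero during learning", {
  set.seed(14)
  gen <- randomIsingModel(5, hSd = 0.4, jSd = 0.2)
  target <- exactMoments(gen, 1)
  mask <- matrix(FALSE, 5, 5); diag(mask) <- TRUE
  fit <- bmFit(target, bmConfig(5, nIter = 500, seed = 15), mask = mask,
               gradientMode = "exact")
  expect_true(all(couplings(fit$model) == 0))
  expect_gt(max(abs(fields(fit$model))), 0)  # fields were learned
})

test_that("fitting a permutation-symmetric target preserves the symmetry", {
  # exchangeable 4-spin target: any permutation leaves moments invariant
  tgt <- methods::new("MomentSet", meanSigma = rep(-0.4, 4),
                      pairSigma = matrix(0.2, 4, 4) + diag(0.8, 4),
                      correlation = matrix(0.04, 4, 4), nSamples = 1,
                      pk = numeric(),
                      triples = data.frame(i = integer(), j = integer(),
                                           k = integer(), value = numeric()),
                      meta = list())
  fit <- bmFit(tgt, bmConfig(4, nIter = 3000, seed = 16),
               gradientMode = "exact")
  expect_lt(diff(range(fields(fit$model))), 1e-4)
  offd <- couplings(fit$model)[upper.tri(diag(4))]
  expect_lt(diff(range(offd)), 1e-4)
})

test_that("pruning masks pairs below the relative threshold", {
  C <- matrix(NA_real_, 3, 3)
  C[1, 2] <- C[2, 1] <- 0.5
  C[1, 3] <- C[3, 1] <- 0.05
  C[2, 3] <- C[3, 2] <- 0.3
  m <- pruneMask(C, 0.2)   # threshold 0.1
  expect_true(m[1, 2] && m[2, 3])
  expect_false(m[1, 3])
  expect_equal(attr(m, "removedFraction"), 1 / 3)
  # eta = 0 keeps everything
  m0 <- pruneMask(C, 0)
  expect_true(all(m0))
  expect_equal(attr(m0, "removedFraction"), 0)
  # eta = 1 keeps only the maximum
  m1 <- pruneMask(C, 1)
  expect_true(m1[1, 2])
  expect_false(m1[1, 3] || m1[2, 3])
  expect_error(pruneMask(matrix(numeric(), 0, 0), 0.1), "empty")
  expect_error(pruneMask(C, 1.5), "eta")
})

test_that("Ising model serialization round-trips exactly", {
  set.seed(17)
  mod <- randomIsingModel(6)
  mask <- pruneMask(correlations(exactMoments(mod, 1)), 0.3)
  mod2 <- isingModel(mod@h, mod@J, mask, meta = list(note = "x"))
  path <- file.path(withr::local_tempdir(), "model.json")
  writeIsingModel(mod2, path)
  back <- readIsingModel(path)
  expect_equal(fields(back), fields(mod2), tolerance = 0)
  expect_equal(couplings(back), couplings(mod2), tolerance = 0)
  expect_identical(unname(couplingMask(back)), unname(couplingMask(mod2)))
})
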