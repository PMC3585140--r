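test_that("no mutation rate means no alleles", {
  cfg <- simulationConfig(N = 100, theta = 0, seed = 1)
  tr <- simulateTrajectories(cfg)
  expect_equal(nrow(tr$sites), 0L)
})

test_that("stochastic simulation refuses to run without a seed", {
  cfg <- simulationConfig(N = 100)
  expect_error(simulateTrajectories(cfg), "seed")
  expect_error(simulatePopulation(cfg), "seed")
})

test_that("identical seed and config give identical trajectories", {
  cfg <- simulationConfig(N = 100, runLength = 150, seed = 33)
  a <- simulateTrajectories(cfg)
  b <- simulateTrajectories(cfg)
  expect_identical(a$sites, b$sites)
})

test_that("neutral fixation probability is about 1/(2N)", {
  cfg <- simulationConfig(N = 100, gamma = 0, fractionSelected = 0,
                          seed = 71)
  tr <- simulateTrajectories(cfg, nMutations = 1e5, mode = "absorption")
  nFix <- sum(tr$sites$fate == "fixation")
  expected <- 1e5 / (2 * 100)
  se <- sqrt(1e5 * (1 / 200) * (1 - 1 / 200))
  expect_lt(abs(nFix - expected), 3 * se)
})

test_that("age tables handle single alleles and empty bins explicitly", {
  traj <- structure(list(
    sites = data.frame(id = 1L, origin_generation = 10L, gamma = 0,
                       fate = "segregating", final_count = 6L,
                       final_freq = 0.03, end_generation = 67L),
    occupancy = NULL, sizes = rep(100L, 67), generations = 67L,
    nIntroduced = 1L,
    config = simulationConfig(N = 100, seed = 1)),
    class = "AlleleTrajectories")
  tab <- ageByFrequency(traj, bins = seq(0, 0.1, 0.01))
  hit <- tab[tab$bin_low == 0.03, ]
  expect_equal(hit$n, 1L)
  expect_equal(hit$mean_age, 57)
  expect_true(is.na(hit$se))           # undefined, flagged not dropped
  expect_equal(sum(tab$n == 0), nrow(tab) - 1L)
  expect_true(all(is.na(tab$mean_age[tab$n == 0])))
})

test_that("selection classes with identical trajectories give identical rows", {
  sites <- data.frame(id = 1:2, origin_generation = 5L, gamma = c(0, -10),
                      fate = "segregating", final_count = 4L,
                      final_freq = 0.02, end_generation = 30L)
  traj <- structure(list(sites = sites, occupancy = NULL,
                         sizes = rep(100L, 30), generations = 30L,
                         nIntroduced = 2L,
                         config = simulationConfig(N = 100, seed = 1)),
                    class = "AlleleTrajectories")
  tab <- ageByFrequency(traj, bins = c(0.02, 0.03))
  expect_equal(tab$mean_age[tab$gamma == 0], tab$mean_age[tab$gamma == -10])
  expect_equal(tab$n[tab$gamma == 0], tab$n[tab$gamma == -10])
})

test_that("simulated neutral ages agree with diffusion theory", {
  cfg <- simulationConfig(N = 400, gamma = 0, fractionSelected = 0,
                          seed = 91)
  tr <- simulateTrajectories(cfg, nMutations = 4e4, recordOccupancy = TRUE,
                             mode = "absorption")
  bins <- seq(0.01, 0.06, 0.01)
  ab <- ageByFrequency(tr, bins = bins, at = "occupancy")
  th <- predictedAgeByFrequency(bins, 0)
  z <- (ab$mean_age - th$mean_age * 2 * cfg$N) / ab$se
  expect_true(all(abs(z) < 3))
})

test_that("deleterious alleles are younger than neutral ones per bin", {
  cfg <- simulationConfig(N = 300, gamma = -10, fractionSelected = 0.5,
                          seed = 92)
  tr <- simulateTrajectories(cfg, nMutations = 4e4, recordOccupancy = TRUE,
                             mode = "absorption")
  ab <- ageByFrequency(tr, bins = seq(0.01, 0.06, 0.01), at = "occupancy")
  neu <- ab[ab$gamma == 0, ]
  del <- ab[ab$gamma == -10, ]
  ok <- neu$n >= 50 & del$n >= 50
  expect_true(any(ok))
  expect_true(all(neu$mean_age[ok] > del$mean_age[ok]))
})

test_that("population size schedules implement the demography presets", {
  cfg <- simulationConfig(N = 100, demography = "expansion", seed = 1)
  s <- popSizeSchedule(cfg)
  expect_true(all(s[1:200] == 100))              # flat until 2N
  expect_equal(s[length(s)], 100 * 100, tolerance = 0.05)  # 100-fold growth
  cfgB <- simulationConfig(N = 100, demography = "bottleneck", seed = 1)
  sb <- popSizeSchedule(cfgB)
  expect_equal(sb[201], 50)                      # instantaneous halving
  expect_true(all(diff(sb[201:length(sb)]) >= 0))
  expect_equal(sb[length(sb)], 50 * 100, tolerance = 0.05)
})

test_that("the individual-based simulation is reproducible and consistent", {
  cfg <- simulationConfig(N = 60, theta = 1e-3, rho = 1e-3,
                          regionLength = 3e4, seed = 14)
  a <- simulatePopulation(cfg)
  b <- simulatePopulation(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$variants, b$variants)
  # population counts match the genotype matrix
  expect_equal(rowSums(a$genotypes), a$variants$pop_count)
  expect_true(all(a$variants$origin_generation >= 1))
  expect_true(all(a$variants$gamma %in% c(0, cfg$gamma)))
})

test_that("panel sampling preserves counts, is seeded, and guards n", {
  cfg <- simulationConfig(N = 60, theta = 1e-3, rho = 1e-3,
                          regionLength = 3e4, seed = 15)
  pop <- simulatePopulation(cfg)
  full <- samplePanel(pop, pop$nHaplotypes, seed = 2)
  vi <- variantInfo(full)
  expect_equal(vi$altCount,
               pop$variants$pop_count[match(vi$pos - 1L,
                                            floor(pop$variants$pos))])
  a <- samplePanel(pop, 30, seed = 7)
  b <- samplePanel(pop, 30, seed = 7)
  expect_identical(hapMatrix(a), hapMatrix(b))
  expect_error(samplePanel(pop, pop$nHaplotypes + 1), "exceeds")
})

test_that("sample frequencies are unbiased for population frequencies", {
  cfg <- simulationConfig(N = 60, theta = 1e-3, rho = 0, regionLength = 3e4,
                          seed = 16)
  pop <- simulatePopulation(cfg)
  popFreq <- pop$variants$pop_count / pop$nHaplotypes
  nHap <- 40
  reps <- 60
  sampFreq <- matrix(NA_real_, reps, length(popFreq))
  set.seed(99)
  for (r in seq_len(reps)) {
    idx <- sample.int(pop$nHaplotypes, nHap)
    sampFreq[r, ] <- rowSums(pop$genotypes[, idx, drop = FALSE]) / nHap
  }
  # binomial (finite-sample hypergeometric) sampling: mean sample frequency
  # matches population frequency within 3 SE, averaged over variants
  dev <- colMeans(sampFreq) - popFreq
  se <- sqrt(popFreq * (1 - popFreq) / (nHap * reps))
  ok <- se > 0
  expect_gt(mean(abs(dev[ok]) < 3 * se[ok]), 0.95)
})
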