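test_that("frequency spectra count exactly, including empty cells", {
  v <- data.frame(mac = c(2, 2, 2, 2, 3, 3, 5, 2, 3, 4),
                  category = c(rep("synonymous", 4), "benign", "benign",
                               "benign", "probably_damaging",
                               "probably_damaging", "probably_damaging"))
  sfs <- sfsByCategory(v, macRange = 2:6)
  expect_equal(sfs$synonymous[sfs$mac == 2], 4L)
  expect_equal(sfs$synonymous[sfs$mac == 6], 0L)
  expect_equal(sum(sfs$benign), 3L)
  tot <- attr(sfs, "totals")
  expect_equal(unname(tot["synonymous"]), sum(sfs$synonymous))
  empty <- sfsByCategory(v[0, ], macRange = 2:3)
  expect_equal(nrow(empty), 2L)
})

test_that("the deleterious fraction is the excess over the neutral expectation", {
  # MAC-2 spectrum counts of a Dutch whole-genome population panel
  expect_equal(deleteriousFraction(4335, 46946, 3102, 39454), 0.1485,
               tolerance = 1e-3)
  # a category matching the synonymous spectrum exactly is 0% deleterious
  expect_equal(deleteriousFraction(500, 5000, 1000, 10000), 0)
  expect_error(deleteriousFraction(0, 10, 5, 10))
})

test_that("identical category and baseline give null effect and p about 1/2", {
  set.seed(1)
  x <- round(rnorm(120, 3, 0.5), 2)
  nc <- data.frame(nc = c(x, x), mac = 2,
                   category = rep(c("synonymous", "missense"), each = 120))
  out <- compareNC(nc, mac = 2, nBoot = 200)
  mis <- out[out$category == "missense", ]
  expect_equal(mis$effect_size, 0)
  expect_equal(mis$p, 0.5, tolerance = 0.02)
})

test_that("a shifted category is detected, matching a rank-sum oracle", {
  set.seed(2)
  base <- rnorm(200, 3, 0.5)
  shifted <- rnorm(200, 3, 0.5) + 0.3 * 0.5
  nc <- data.frame(nc = c(base, shifted), mac = 2,
                   category = rep(c("synonymous", "missense"), each = 200))
  out <- compareNC(nc, mac = 2, nBoot = 200)
  mis <- out[out$category == "missense", ]
  expect_gt(mis$effect_size, 0)
  expect_lt(mis$p, 0.01)
  # independent normal-approximation oracle for the one-sided rank-sum test
  r <- rank(c(shifted, base))
  W <- sum(r[1:200]) - 200 * 201 / 2
  mu <- 200 * 200 / 2
  sigma <- sqrt(200 * 200 * 401 / 12)
  pOracle <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  expect_equal(mis$p, pOracle, tolerance = 0.05)
  # effect size uses the baseline SD at the same MAC
  expect_equal(mis$effect_size,
               (mean(shifted) - mean(base)) / sd(base))
})

test_that("bootstrap CIs are deterministic under a seed and degenerate on constants", {
  a <- rep(2, 30); b <- rep(2, 40)
  expect_equal(bootstrapCI(a, b, nBoot = 50, seed = 3), c(0, 0))
  x <- rnorm(50); y <- rnorm(50)
  expect_identical(bootstrapCI(x, y, nBoot = 100, seed = 7),
                   bootstrapCI(x, y, nBoot = 100, seed = 7))
})

test_that("bootstrap CIs cover a known normalized shift", {
  set.seed(8)
  hits <- 0L
  for (r in 1:100) {
    base <- rnorm(500)
    cat <- rnorm(500, mean = 0.3)
    ci <- bootstrapCI(cat, base, nBoot = 1000)
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("weighted Z-score combination matches closed forms", {
  expect_equal(metaCombine(0.05, 10), 0.05, tolerance = 1e-12)
  # two studies at p = 0.05 with equal n: Z = 1.6449 * sqrt(2) = 2.3262
  expect_equal(metaCombine(c(0.05, 0.05), c(50, 50)),
               pnorm(qnorm(0.95) * sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(metaCombine(c(0.05, 0.05), c(50, 50)), 0.010,
               tolerance = 1e-3)
  expect_equal(metaCombine(c(0.05, 0.95), c(50, 50)), 0.5, tolerance = 1e-10)
  # monotone decreasing in each study's evidence
  expect_lt(metaCombine(c(0.01, 0.05), c(50, 50)),
            metaCombine(c(0.02, 0.05), c(50, 50)))
  expect_warning(p <- metaCombine(c(0, 0.5), c(50, 50)), "clipped")
  expect_true(p > 0 && p < 1)
})

test_that("Spearman correlation with damage scores is one-sided", {
  s <- spearmanVsScore(1:10, (1:10)^2)
  expect_equal(s$rho, 1)
  expect_lt(s$p, 0.01)
  r <- spearmanVsScore(1:10, rev(1:10))
  expect_equal(r$rho, -1)
  expect_gt(r$p, 0.99)
  expect_warning(z <- spearmanVsScore(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(z$rho))
  # simulated rank dependence recovers the generative correlation
  set.seed(11)
  x <- rnorm(100); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(100)
  rhoExp <- 6 / pi * asin(0.5 / 2)    # Pearson 0.5 -> Spearman for normals
  est <- spearmanVsScore(x, y)
  expect_lt(abs(est$rho - rhoExp), 3 / sqrt(97))
})

test_that("population-private fractions count single-population alleles", {
  v <- data.frame(category = c("synonymous", "synonymous", "missense"),
                  mac = c(2, 2, 3),
                  populations = I(list("NL", c("NL", "DE"), "NL")))
  out <- privateFraction(v)
  expect_equal(out$prop_private[out$category == "synonymous"], 0.5)
  expect_equal(out$prop_private[out$category == "missense"], 1)
  # a single-population dataset is 100% private by definition
  v1 <- data.frame(category = "synonymous", mac = c(2, 3),
                   populations = c("NL", "NL"))
  expect_true(all(privateFraction(v1)$prop_private == 1))
  vbad <- data.frame(category = "x", mac = 1, populations = I(list(character(0))))
  expect_error(privateFraction(vbad), "empty")
})

test_that("private fractions fall with frequency in a two-deme island model", {
  # independent island-model oracle: two demes, symmetric migration,
  # binomial Wright-Fisher per deme
  set.seed(21)
  N <- 100; mig <- 0.002; M <- 6000; gens <- 100
  f <- matrix(0, M, 2)
  f[cbind(seq_len(M), sample(2, M, TRUE))] <- 1 / (2 * N)
  for (g in seq_len(gens)) {
    fm <- f + mig * (f[, 2:1] - f)
    f <- matrix(rbinom(2 * M, 2 * N, pmin(pmax(fm, 0), 1)) / (2 * N), M, 2)
  }
  tot <- rowMeans(f)
  seg <- tot > 0 & tot < 1
  pops <- lapply(which(seg), function(i)
    c("A", "B")[which(f[i, ] > 0)])
  cls <- cut(tot[seg], c(0, 0.05, 0.2, 1), labels = c("rare", "low", "common"))
  v <- data.frame(category = "any", freq_class = as.character(cls))
  v$populations <- I(pops)
  out <- privateFraction(v, classColumn = "freq_class")
  pr <- setNames(out$prop_private, out$freq_class)
  expect_gt(pr["rare"], pr["low"])
  expect_gt(pr["low"], pr["common"])
})

test_that("the MAC-range table appends meta-combined p-values", {
  set.seed(31)
  rows <- list()
  for (k in 2:3) {
    rows[[length(rows) + 1]] <- data.frame(
      nc = rnorm(80, 3), mac = k, category = "synonymous")
    rows[[length(rows) + 1]] <- data.frame(
      nc = rnorm(80, 3.4), mac = k, category = "missense")
  }
  nc <- do.call(rbind, rows)
  tab <- compareNCTable(nc, macRange = 2:3, nBoot = 100, seed = 5)
  comb <- tab[is.na(tab$mac), ]
  expect_equal(nrow(comb), 1L)
  perMac <- tab[!is.na(tab$mac) & tab$category == "missense", ]
  expect_lt(comb$p, max(perMac$p))
  expect_equal(comb$n, sum(perMac$n))
})
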