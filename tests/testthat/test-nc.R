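test_that("carrier sets are the minor-allele haplotypes", {
  m <- rbind(c(0L, 1L, 1L, 0L, 0L, 0L),
             c(1L, 0L, 1L, 1L, 1L, 1L))   # minor allele of row 2 is REF
  p <- makePanel(m)
  expect_equal(carrierSet(p, 1), c(2L, 3L))
  expect_equal(carrierSet(p, 2), 2L)
  # carriers of alt and ref alleles partition the panel
  expect_setequal(c(which(hapMatrix(p)[1, ] == 1),
                    which(hapMatrix(p)[1, ] == 0)), 1:6)
})

test_that("the four-gamete test enumerates two-locus haplotypes", {
  # carriers {2,3} vs subset {2}: gamete 01 absent
  m <- rbind(c(0L, 1L, 1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L, 0L, 0L))
  expect_false(fourGamete(makePanel(m), 1, 2))
  # carriers {1,2} vs {1,3}: all four gametes present
  m2 <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L, 0L, 0L))
  expect_true(fourGamete(makePanel(m2), 1, 2))
  # complementary variants: only gametes 10 and 01 exist
  m3 <- rbind(c(1L, 1L, 1L, 0L, 0L, 0L), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_false(fourGamete(makePanel(m3), 1, 2))
})

test_that("fully linked rarer means a strict non-empty carrier subset", {
  m <- rbind(c(1L, 1L, 1L, 0L, 0L, 0L),
             c(1L, 1L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 1L, 0L, 0L))
  p <- makePanel(m)
  expect_true(fullyLinkedRarer(p, 1, 2))
  expect_false(fullyLinkedRarer(p, 1, 3))   # identical sets are not strict
  expect_false(fullyLinkedRarer(p, 1, 4))   # {1,4} not a subset of {1,2,3}
})

test_that("NC is the log10 sum of the two stop distances", {
  # index carriers {1,2} at pos 1000; singleton subset at 940 (stop with
  # singletons admitted); {3,4} at 1040 shows only 3 gametes (skipped);
  # {1,3} at 1100 shows four gametes (stop)
  m <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 0L, 0L, 0L, 0L),
             c(0L, 0L, 1L, 1L, 0L, 0L),
             c(1L, 0L, 1L, 0L, 0L, 0L))
  p <- makePanel(m, pos = c(940L, 1000L, 1040L, 1100L))
  r <- ncStatistic(p, 2, includeSingletons = TRUE)
  expect_equal(r$d_up, 60L)
  expect_equal(r$reason_up, "linked_rarer")
  expect_equal(r$d_down, 100L)
  expect_equal(r$reason_down, "recombination")
  expect_equal(r$nc, log10(160), tolerance = 1e-12)
  # default candidate filter excludes the singleton: upstream is censored
  r2 <- ncStatistic(p, 2)
  expect_equal(r2$reason_up, "censored")
  expect_true(is.na(r2$nc))
})

test_that("distances add before the logarithm", {
  m <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 0L, 0L, 0L),
             c(1L, 0L, 1L, 0L, 0L, 0L))
  p <- makePanel(m, pos = c(960L, 1000L, 1060L))
  r <- ncStatistic(p, 2)
  expect_equal(r$d_up + r$d_down, 100L)
  expect_equal(r$nc, 2, tolerance = 1e-12)
})

test_that("a contig end censors the direction and the NC value", {
  m <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L, 0L, 0L))
  p <- makePanel(m, pos = c(100L, 150L))
  r <- ncStatistic(p, 1)
  expect_equal(r$reason_up, "censored")
  expect_equal(r$reason_down, "recombination")
  expect_true(is.na(r$nc))
  expect_error(ncStatistic(p, 99), "not in panel")
})

test_that("singleton indices are rejected under the default filter", {
  m <- rbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L))
  p <- makePanel(m)
  expect_error(ncStatistic(p, 1), "MAC >= 2")
  expect_silent(ncStatistic(p, 1, includeSingletons = TRUE))
})

test_that("nc_statistic matches a brute-force oracle on random panels", {
  set.seed(4711)
  for (rep in 1:200) {
    p <- randomPanel(sample(6:20, 1), sample(5:50, 1))
    m <- hapMatrix(p)
    pos <- variantInfo(p)$pos
    mac <- variantInfo(p)$mac
    idx <- which(mac >= 2)
    if (!length(idx)) next
    got <- ncPanel(p, indexMac = 2:max(mac))
    expect_equal(nrow(got), length(idx))
    want <- do.call(rbind, lapply(idx, function(i)
      as.data.frame(bruteNc(m, pos, i))))
    expect_equal(got[, colnames(want)], want, ignore_attr = TRUE)
  }
})

test_that("permuting haplotype order leaves NC results unchanged", {
  set.seed(99)
  p <- randomPanel(12, 30)
  perm <- sample(ncol(p))
  q <- HaplotypePanel(hapMatrix(p)[, perm], chrom = "chr1",
                      pos = variantInfo(p)$pos,
                      ref = variantInfo(p)$ref, alt = variantInfo(p)$alt)
  a <- ncPanel(p); b <- ncPanel(q)
  expect_equal(a, b)
})

test_that("variants beyond the stops are irrelevant; nearer subsets shrink NC", {
  m <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 1L, 1L, 0L))
  p <- makePanel(m, pos = c(900L, 1000L, 1100L))
  base <- ncStatistic(p, 2)
  expect_equal(base$nc, log10(200))
  # a variant farther than both stop points changes nothing
  m2 <- rbind(m, c(0L, 0L, 1L, 1L, 1L, 0L))
  p2 <- makePanel(m2, pos = c(900L, 1000L, 1100L, 5000L))
  expect_equal(ncStatistic(p2, 2)[, c("d_up", "d_down", "nc")],
               base[, c("d_up", "d_down", "nc")])
  # a strict-subset variant closer than the current stop can only shrink NC
  m3 <- rbind(m[1, ], c(1L, 1L, 0L, 0L, 0L, 0L), m[2:3, ])
  p3 <- makePanel(m3, pos = c(900L, 950L, 1000L, 1100L))
  expect_lte(ncStatistic(p3, 3)$nc, base$nc)
})

test_that("derived mode follows polarity and rejects unpolarized variants", {
  m <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(0L, 1L, 1L, 0L, 0L, 0L))
  p <- makePanel(m, pos = c(100L, 200L))
  anc <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                    ancestral_allele = c("G", "N"))  # ALT ancestral; unknown
  p <- polarize(p, anc)
  expect_equal(variantInfo(p)$polarity, c("ancestral", "unpolarized"))
  # the minor (ALT) allele is ancestral, so the derived carriers are the
  # REF haplotypes
  expect_equal(carrierSet(p, 1, mode = "derived"), 3:6)
  expect_equal(carrierSet(p, 1, mode = "minor"), 1:2)
  expect_error(carrierSet(p, 2, mode = "derived"), "unpolarized")
})

test_that("NC decreases with true allele age at fixed sample MAC", {
  nc <- sharedTruthNc()
  ok <- !is.na(nc$nc)
  rhos <- vapply(2:6, function(k) {
    sub <- nc[ok & nc$mac == k, ]
    suppressWarnings(stats::cor(sub$nc, sub$trueAge, method = "spearman"))
  }, 0)
  expect_true(all(rhos < 0))
})

test_that("ancestral minor alleles have lower NC than derived ones", {
  nc <- sharedTruthNc()
  ok <- !is.na(nc$nc) & nc$mac %in% 2:6
  anc <- nc$nc[ok & nc$polarity == "ancestral"]
  der <- nc$nc[ok & nc$polarity == "derived"]
  expect_gt(length(anc), 5)
  expect_lt(mean(anc), mean(der))
})
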