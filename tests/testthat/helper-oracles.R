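# Independent oracles and small fixture builders used across test files.

# Kimura/Ohta closed form: mean age of a neutral new mutation currently at
# frequency x, in units of 2N generations
neutralAgeOracle <- function(x) -2 * (x / (1 - x)) * log(x)

# quick panel from a variant-by-haplotype 0/1 matrix
makePanel <- function(m, pos = NULL, chrom = "chr1") {
  m <- as.matrix(m)
  if (is.null(pos)) pos <- seq_len(nrow(m)) * 100L
  HaplotypePanel(m, chrom = chrom, pos = pos,
                 ref = rep("A", nrow(m)), alt = rep("G", nrow(m)))
}

# random segregating panel for property tests
randomPanel <- function(nHap, nVar, maxPos = 5000L) {
  repeat {
    m <- matrix(0L, nVar, nHap)
    for (i in seq_len(nVar)) {
      k <- sample(1:(nHap - 1), 1)
      m[i, sample(nHap, k)] <- 1L
    }
    seg <- rowSums(m) > 0 & rowSums(m) < nHap
    m <- m[seg, , drop = FALSE]
    if (nrow(m) >= 2) break
  }
  pos <- sort(sample(maxPos, nrow(m)))
  makePanel(m, pos = pos)
}

# Brute-force NC oracle: re-derives carrier sets, the four-gamete table and
# the strict-subset rule from the raw matrix, testing every candidate in
# sorted order.  Deliberately independent of the package implementation.
bruteNc <- function(m, pos, index, minMac = 2L) {
  nHap <- ncol(m)
  focalVal <- function(i) if (sum(m[i, ]) <= nHap - sum(m[i, ])) 1L else 0L
  carriers <- function(i) which(m[i, ] == focalVal(i))
  mac <- function(i) min(sum(m[i, ]), nHap - sum(m[i, ]))
  cands <- setdiff(which(vapply(seq_len(nrow(m)), mac, 0L) >= minMac), index)
  ci <- carriers(index)
  scan <- function(dir) {
    sel <- if (dir < 0) cands[pos[cands] < pos[index]] else
      cands[pos[cands] > pos[index]]
    sel <- sel[order(abs(pos[sel] - pos[index]))]
    for (j in sel) {
      cj <- carriers(j)
      if (length(cj) > 0 && all(cj %in% ci) && length(cj) < length(ci))
        return(list(d = abs(pos[j] - pos[index]), reason = "linked_rarer"))
      tab <- table(factor(m[index, ], levels = 0:1),
                   factor(m[j, ], levels = 0:1))
      if (all(tab > 0))
        return(list(d = abs(pos[j] - pos[index]), reason = "recombination"))
    }
    list(d = NA_integer_, reason = "censored")
  }
  up <- scan(-1); down <- scan(+1)
  nc <- if (up$reason != "censored" && down$reason != "censored")
    log10(up$d + down$d) else NA_real_
  list(d_up = up$d, reason_up = up$reason, d_down = down$d,
       reason_down = down$reason, nc = nc)
}

# shared synthetic panel pool with truth (built lazily once per test run)
.fixtureEnv <- new.env(parent = emptyenv())
sharedTruthPanel <- function() {
  if (is.null(.fixtureEnv$pool)) {
    cfg <- syntheticConfig(replicates = 2, seed = 20260901)
    .fixtureEnv$pool <- generatePanel(cfg)
  }
  .fixtureEnv$pool
}
sharedTruthNc <- function() {
  if (is.null(.fixtureEnv$nc))
    .fixtureEnv$nc <- ncPanel(sharedTruthPanel()$panel)
  .fixtureEnv$nc
}
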