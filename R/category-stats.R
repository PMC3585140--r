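## Downstream statistics on NC values and frequency spectra by functional
## category: spectra, deleterious-fraction estimation against the synonymous
## neutral baseline, rank-based comparisons with bootstrap CIs, weighted
## Z-score meta-analysis, correlation with damage scores, and
## population-private fractions.

#' Site-frequency spectrum by functional category
#'
#' Exact counts of variants per (MAC, category) cell; categories with no
#' variants are present with zero counts, and per-category totals are
#' attached as an attribute.
#'
#' @param variants data.frame with columns \code{mac} and \code{category}
#'   (e.g. [variantInfo()] of a panel, or an [ncPanel()] result).
#' @param macRange MAC values to tabulate (default \code{2:20}).
#' @param categories category levels; defaults to those observed.
#' @return data.frame with one row per MAC and one column per category,
#'   plus attribute \code{"totals"} (per-category totals over all MACs, not
#'   just \code{macRange}).
#' @export
sfsByCategory <- function(variants, macRange = 2:20, categories = NULL) {
  stopifnot(all(c("mac", "category") %in% colnames(variants)))
  if (is.null(categories)) categories <- sort(unique(variants$category))
  if (!length(categories)) categories <- character(0)
  tab <- matrix(0L, nrow = length(macRange), ncol = length(categories),
                dimnames = list(NULL, categories))
  for (ci in seq_along(categories)) {
    sub <- variants$mac[variants$category == categories[ci]]
    tab[, ci] <- vapply(macRange, function(k) sum(sub == k), 0L)
  }
  out <- data.frame(mac = macRange, tab, check.names = FALSE)
  attr(out, "totals") <- vapply(categories, function(cc)
    sum(variants$category == cc), 0L)
  out
}

#' Deleterious fraction of a category at a given minor allele count
#'
#' Treats the synonymous frequency spectrum as the neutral expectation: the
#' expected number of category variants at this MAC, were they neutral, is
#' \code{totalCat * nSynAtMac / totalSyn}; the excess of the observed count
#' over that expectation, divided by the observed count, estimates the
#' fraction of the category's alleles at this MAC that are deleterious.
#' The value may be negative (a deficit) and is reported as-is.
#'
#' @param nCatAtMac observed category variants at the MAC of interest.
#' @param totalCat total category variants (all MACs).
#' @param nSynAtMac synonymous variants at the same MAC.
#' @param totalSyn total synonymous variants.
#' @return fraction in (-Inf, 1].
#' @examples
#' deleteriousFraction(4335, 46946, 3102, 39454)  # ~0.149
#' @export
deleteriousFraction <- function(nCatAtMac, totalCat, nSynAtMac, totalSyn) {
  stopifnot(nCatAtMac > 0, totalCat > 0, nSynAtMac > 0, totalSyn > 0,
            nCatAtMac <= totalCat, nSynAtMac <= totalSyn)
  (nCatAtMac - totalCat * nSynAtMac / totalSyn) / nCatAtMac
}

# one-sided Mann-Whitney p-value for values > baseline; normal approximation
# with tie correction, exact only for small untied samples
.mannWhitneyGreater <- function(values, baseline) {
  exact <- length(values) < 20 && length(baseline) < 20 &&
    !anyDuplicated(c(values, baseline))
  suppressWarnings(stats::wilcox.test(values, baseline,
                                      alternative = "greater",
                                      exact = exact, correct = TRUE)$p.value)
}

#' Compare NC distributions of categories against a baseline at one MAC
#'
#' For each category at the given minor allele count, computes the variant
#' count, mean NC, effect size in baseline standard deviations
#' (\code{(mean_cat - mean_baseline) / sd_baseline}, the baseline being
#' synonymous variants at the same MAC), a 95\% percentile-bootstrap CI for
#' the effect size, and a one-sided Mann-Whitney p-value for the
#' alternative that the category's NC values are larger (younger alleles).
#' Censored NC values (NA) are excluded and counted.
#'
#' @param nc data.frame with columns \code{nc}, \code{mac} and
#'   \code{category} (an [ncPanel()] result, possibly with a relabelled
#'   \code{category} column).
#' @param mac the minor allele count to analyse.
#' @param baseline the baseline category (default \code{"synonymous"}).
#' @param categories categories to compare; defaults to all non-baseline
#'   categories present at this MAC.  Categories with fewer than 2 usable
#'   variants are omitted with a warning.
#' @param nBoot bootstrap replicates for the CI (default 1000).
#' @param seed optional seed for the bootstrap.
#' @return data.frame: \code{mac}, \code{category}, \code{n},
#'   \code{mean_nc}, \code{effect_size}, \code{ci_low}, \code{ci_high},
#'   \code{p}; the first row is the baseline (effect size 0, no CI/p).
#' @export
compareNC <- function(nc, mac, baseline = "synonymous", categories = NULL,
                      nBoot = 1000, seed = NULL) {
  stopifnot(all(c("nc", "mac", "category") %in% colnames(nc)))
  usable <- nc[!is.na(nc$nc) & nc$mac == mac, ]
  base <- usable$nc[usable$category == baseline]
  if (length(base) < 2)
    stop("fewer than 2 usable baseline ('", baseline, "') variants at MAC ",
         mac)
  if (is.null(categories))
    categories <- setdiff(sort(unique(usable$category)), baseline)
  if (!is.null(seed)) set.seed(seed)
  rows <- list(data.frame(
    mac = mac, category = baseline, n = length(base), mean_nc = mean(base),
    effect_size = 0, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_))
  sdBase <- stats::sd(base)
  for (cc in categories) {
    v <- usable$nc[usable$category == cc]
    if (length(v) < 2) {
      warning("category '", cc, "' has fewer than 2 usable variants at MAC ",
              mac, "; omitted")
      next
    }
    ci <- bootstrapCI(v, base, nBoot = nBoot)
    rows[[length(rows) + 1L]] <- data.frame(
      mac = mac, category = cc, n = length(v), mean_nc = mean(v),
      effect_size = (mean(v) - mean(base)) / sdBase,
      ci_low = ci[1], ci_high = ci[2],
      p = .mannWhitneyGreater(v, base))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile-bootstrap CI for the normalized mean difference
#'
#' Resamples variants with replacement within each group and recomputes the
#' effect size \code{(mean(cat) - mean(baseline)) / sd(baseline)} on each of
#' \code{nBoot} replicates; returns the 2.5th and 97.5th percentiles.
#'
#' @param valuesCat,valuesBaseline numeric vectors of NC values.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed optional seed.
#' @return length-2 numeric vector \code{c(ci_low, ci_high)}.
#' @export
bootstrapCI <- function(valuesCat, valuesBaseline, nBoot = 1000,
                        seed = NULL) {
  stopifnot(length(valuesCat) >= 1, length(valuesBaseline) >= 1)
  if (!is.null(seed)) set.seed(seed)
  n1 <- length(valuesCat); n2 <- length(valuesBaseline)
  i1 <- matrix(sample.int(n1, n1 * nBoot, replace = TRUE), nrow = nBoot)
  i2 <- matrix(sample.int(n2, n2 * nBoot, replace = TRUE), nrow = nBoot)
  m1 <- rowMeans(matrix(valuesCat[i1], nrow = nBoot))
  m2 <- rowMeans(matrix(valuesBaseline[i2], nrow = nBoot))
  s2 <- apply(matrix(valuesBaseline[i2], nrow = nBoot), 1, stats::sd)
  eff <- (m1 - m2) / s2
  eff[!is.finite(eff)] <- 0  # degenerate resample of a constant baseline
  unname(stats::quantile(eff, c(0.025, 0.975)))
}

#' Combine one-sided p-values by the weighted Z-score (Stouffer) method
#'
#' \code{Z = sum(w_i z_i) / sqrt(sum(w_i^2))} with \code{z_i =
#' qnorm(1 - p_i)} and sample-size weights \code{w_i = sqrt(n_i)}; returns
#' the one-sided p-value of Z.  p-values of exactly 0 or 1 are clipped with
#' a warning.
#'
#' @param pValues one-sided p-values in (0,1).
#' @param sampleSizes positive per-study sample sizes (same length).
#' @return combined one-sided p-value.
#' @examples
#' metaCombine(c(0.05, 0.05), c(100, 100))  # ~0.010
#' @export
metaCombine <- function(pValues, sampleSizes) {
  stopifnot(length(pValues) == length(sampleSizes), all(sampleSizes > 0))
  if (any(pValues <= 0 | pValues >= 1)) {
    warning("p-values clipped to (1e-300, 1 - 1e-16)")
    pValues <- pmin(pmax(pValues, 1e-300), 1 - 1e-16)
  }
  z <- stats::qnorm(pValues, lower.tail = FALSE)
  w <- sqrt(sampleSizes)
  Z <- sum(w * z) / sqrt(sum(w^2))
  stats::pnorm(Z, lower.tail = FALSE)
}

#' Spearman correlation of NC values with damage scores
#'
#' One-sided test of positive rank correlation between NC values and a
#' continuous damage probability (alternative: more damaging alleles are
#' younger, hence larger NC).
#'
#' @param ncValues,damageScores paired numeric vectors, length >= 3.
#' @return list with \code{rho} and one-sided \code{p}; both NA (flagged
#'   with a warning) if either vector has zero variance.
#' @export
spearmanVsScore <- function(ncValues, damageScores) {
  ok <- !is.na(ncValues) & !is.na(damageScores)
  ncValues <- ncValues[ok]; damageScores <- damageScores[ok]
  if (length(ncValues) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(ncValues) == 0 || stats::sd(damageScores) == 0) {
    warning("zero variance; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(ncValues, damageScores,
                                         method = "spearman",
                                         alternative = "greater",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Proportion of population-private alleles per category
#'
#' A variant is population-private when its allele is observed in exactly
#' one of the sampled populations.  Variants are stratified by category and
#' by a frequency class (e.g. MAC or a frequency bin label).
#'
#' @param variants data.frame with columns \code{category}, a frequency
#'   class column named by \code{classColumn}, and \code{populations}: a
#'   list-column (or comma-separated character column) of the populations in
#'   which each variant's allele is observed; empty sets are an error.
#' @param classColumn name of the frequency-class column (default
#'   \code{"mac"}).
#' @return data.frame: class, \code{category}, \code{n},
#'   \code{n_private}, \code{prop_private}.
#' @export
privateFraction <- function(variants, classColumn = "mac") {
  stopifnot(all(c("category", "populations", classColumn) %in%
                  colnames(variants)))
  pops <- variants$populations
  if (!is.list(pops)) pops <- strsplit(as.character(pops), ",", fixed = TRUE)
  npop <- lengths(lapply(pops, unique))
  if (any(npop == 0)) stop("variant with empty population presence set")
  private <- npop == 1
  cls <- variants[[classColumn]]
  agg <- stats::aggregate(
    cbind(n = rep(1L, nrow(variants)), n_private = as.integer(private)),
    by = list(class = cls, category = variants$category), FUN = sum)
  names(agg)[1] <- classColumn
  agg$prop_private <- agg$n_private / agg$n
  agg[order(agg[[classColumn]], agg$category), ]
}

#' Full category-comparison table across a MAC range
#'
#' Runs [compareNC()] at each MAC in \code{macRange} and appends a combined
#' block in which per-MAC one-sided p-values for each category are merged by
#' [metaCombine()], weighted by the per-MAC category variant counts.
#'
#' @inheritParams compareNC
#' @param macRange MACs to analyse (default \code{2:6}).
#' @return data.frame as in [compareNC()], with additional rows at
#'   \code{mac = NA} holding the combined p-values per category.
#' @export
compareNCTable <- function(nc, macRange = 2:6, baseline = "synonymous",
                           nBoot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perMac <- lapply(macRange, function(k)
    compareNC(nc, mac = k, baseline = baseline, nBoot = nBoot))
  tab <- do.call(rbind, perMac)
  combined <- do.call(rbind, lapply(
    setdiff(unique(tab$category), baseline), function(cc) {
      sub <- tab[tab$category == cc & !is.na(tab$p), ]
      if (!nrow(sub)) return(NULL)
      data.frame(mac = NA_integer_, category = cc, n = sum(sub$n),
                 mean_nc = NA_real_, effect_size = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 p = metaCombine(sub$p, sub$n))
    }))
  rbind(tab, combined)
}
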