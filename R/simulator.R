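## Forward Wright-Fisher simulation with true-age tracking.
##
## Two complementary engines share one configuration:
##  * simulateTrajectories(): single-locus allele-frequency trajectories at
##    unlinked sites (vectorised binomial sampling), used to compare ages
##    against diffusion theory and across demographic scenarios;
##  * simulatePopulation(): individual-based multi-locus simulation with
##    recombination (compiled code), which yields phased haplotype panels
##    with known truth ages via samplePanel().

#' Wright-Fisher simulation configuration
#'
#' @param N initial diploid population size.
#' @param burnIn burn-in generations before the recorded run (individual-based
#'   simulations only); default \code{10 * N}.
#' @param runLength recorded generations after burn-in; default
#'   \code{round(2.05 * N)}.
#' @param theta scaled mutation rate per site, \code{4 N mu}.
#' @param rho scaled recombination rate per site, \code{4 N r}.
#' @param regionLength region length in bp.
#' @param fractionSelected proportion of new mutations under selection.
#' @param gamma scaled selection coefficient (\code{2 N s}) of selected
#'   mutations; negative means deleterious.
#' @param demography \code{"constant"}, \code{"expansion"} (100-fold
#'   exponential growth over the final \code{0.05 N} generations, starting
#'   \code{2 N} generations after burn-in), or \code{"bottleneck"}
#'   (instantaneous 50\% reduction at \code{2 N} generations after burn-in,
#'   followed by the same exponential growth).
#' @param seed integer seed; stochastic simulations refuse to run without one.
#' @return a list of validated parameters with class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(N = 1000, burnIn = 10 * N,
                             runLength = round(2.05 * N),
                             theta = 1e-4, rho = 1e-4, regionLength = 1e5,
                             fractionSelected = 0.7, gamma = -10,
                             demography = c("constant", "expansion",
                                            "bottleneck"),
                             seed = NULL) {
  demography <- match.arg(demography)
  stopifnot(N >= 2, burnIn >= 0, runLength >= 1,
            theta >= 0, rho >= 0, regionLength >= 1,
            fractionSelected >= 0, fractionSelected <= 1,
            is.finite(gamma))
  structure(list(N = as.integer(N), burnIn = as.integer(burnIn),
                 runLength = as.integer(runLength), theta = theta, rho = rho,
                 regionLength = regionLength,
                 fractionSelected = fractionSelected, gamma = gamma,
                 demography = demography, seed = seed),
            class = "SimulationConfig")
}

.requireSeed <- function(config) {
  if (is.null(config$seed))
    stop("a seed is required for stochastic simulation; set simulationConfig(seed = ...)")
  set.seed(config$seed)
}

#' Diploid population size per recorded generation
#'
#' Expands the demography preset of a [simulationConfig()] into one diploid
#' size per generation of the recorded run (after burn-in).
#'
#' @param config a \code{SimulationConfig}.
#' @return integer vector of length \code{config$runLength}.
#' @export
popSizeSchedule <- function(config) {
  N <- config$N
  G <- config$runLength
  g <- seq_len(G)
  # demographic events sit at the end of the run: with the default
  # runLength of 2.05N the event falls 2N generations after burn-in and the
  # growth phase covers the final 0.05N generations
  dur <- max(round(0.05 * N), 2L)
  event <- max(G - dur, 1L)
  rate <- log(100) / (dur - 1)
  grow <- pmax(g - event - 1L, 0)
  sizes <- switch(config$demography,
    constant = rep(N, G),
    expansion = ifelse(g <= event, N, N * exp(rate * grow)),
    bottleneck = ifelse(g <= event, N, 0.5 * N * exp(rate * grow)))
  sizes <- as.integer(round(sizes))
  if (any(sizes < 2)) stop("population size fell below 2")
  sizes
}

# deterministic marginal allele-frequency change under genic selection
# (fitnesses 1, 1+s, 1+2s at HWE)
.selectionUpdate <- function(p, s) {
  p * (1 + s * (1 + p)) / (1 + 2 * s * p)
}

#' Simulate allele-frequency trajectories at unlinked sites
#'
#' Forward Wright-Fisher binomial sampling of independent biallelic sites,
#' each mutation entering at count 1 and carrying its own selection
#' coefficient; every allele's origin generation is recorded so true age
#' conditional on current frequency is observable.  Two modes:
#' \code{"schedule"} introduces mutations throughout the recorded run under
#' the configured demography and reports the state at the final (sampling)
#' generation; \code{"absorption"} introduces all mutations at generation 0
#' in a constant-size population and follows each to loss or fixation, which
#' is the natural input for occupancy-based age-by-frequency estimates.
#'
#' @param config a [simulationConfig()]; a seed is mandatory.
#' @param nMutations total number of mutations to introduce.  Default
#'   \code{NULL} draws Poisson numbers per generation from \code{theta}
#'   (schedule mode); absorption mode requires an explicit count.
#' @param recordOccupancy if TRUE, record an (allele, age, frequency) row for
#'   every generation an allele segregates.  Memory grows with the total
#'   number of allele-generations; leave FALSE when only sampling-time state
#'   is needed.
#' @param mode \code{"schedule"} or \code{"absorption"}.
#' @param maxGenerations absorption-mode cap; trajectories still segregating
#'   are flagged \code{"truncated"} with a warning.
#' @param keepAbsorbed if FALSE, alleles lost or fixed before the sampling
#'   generation are only counted (\code{nLost}, \code{nFixed}), not kept in
#'   the sites table; saves memory in large endpoint-sampling runs.
#' @return an object of class \code{"AlleleTrajectories"}: list with
#'   \code{sites} (per-allele table: origin generation, gamma, fate, final
#'   count/frequency), \code{occupancy} (long table or NULL), \code{sizes},
#'   \code{generations} and \code{config}.
#' @export
simulateTrajectories <- function(config, nMutations = NULL,
                                 recordOccupancy = FALSE,
                                 mode = c("schedule", "absorption"),
                                 maxGenerations = NULL,
                                 keepAbsorbed = TRUE) {
  mode <- match.arg(mode)
  .requireSeed(config)
  N <- config$N
  s <- config$gamma / (2 * N)

  if (mode == "schedule") {
    sizes <- popSizeSchedule(config)
    G <- config$runLength
    if (is.null(nMutations)) {
      lambda <- config$theta * config$regionLength * sizes / (2 * N)
      newPerGen <- stats::rpois(G, lambda)
    } else {
      newPerGen <- as.integer(stats::rmultinom(1, nMutations,
                                               prob = sizes)[, 1])
    }
  } else {
    if (is.null(nMutations))
      stop("absorption mode requires nMutations")
    if (is.null(maxGenerations)) maxGenerations <- 100L * N
    G <- as.integer(maxGenerations)
    sizes <- rep(N, G)
    newPerGen <- c(as.integer(nMutations), rep(0L, G - 1L))
  }

  cnt <- integer(0); org <- integer(0); sel <- logical(0); ids <- integer(0)
  nextId <- 1L
  nIntro <- 0L
  nLost <- 0L; nFix <- 0L
  dn <- list(id = list(), org = list(), sel = list(), fixed = list(),
             cnt = list(), freq = list(), gen = list())
  nd <- 0L
  occId <- list(); occAge <- list(); occFreq <- list(); no <- 0L
  prevSize <- sizes[1]
  lastGen <- G

  for (g in seq_len(G)) {
    n2 <- 2L * sizes[g]
    if (length(cnt)) {
      p <- cnt / (2 * prevSize)
      if (s != 0) {
        psel <- ifelse(sel, .selectionUpdate(p, s), p)
      } else psel <- p
      cnt <- stats::rbinom(length(cnt), n2, psel)
      gone <- cnt == 0L | cnt == n2
      if (any(gone)) {
        nLost <- nLost + sum(cnt[gone] == 0L)
        nFix <- nFix + sum(cnt[gone] == n2)
        if (keepAbsorbed) {
          nd <- nd + 1L
          dn$id[[nd]] <- ids[gone]; dn$org[[nd]] <- org[gone]
          dn$sel[[nd]] <- sel[gone]; dn$fixed[[nd]] <- cnt[gone] == n2
          dn$cnt[[nd]] <- cnt[gone]; dn$freq[[nd]] <- cnt[gone] / n2
          dn$gen[[nd]] <- rep(g, sum(gone))
        }
        keep <- !gone
        cnt <- cnt[keep]; org <- org[keep]; sel <- sel[keep]
        ids <- ids[keep]
      }
    }
    k <- newPerGen[g]
    if (k > 0L) {
      newIds <- seq.int(nextId, length.out = k)
      nextId <- nextId + k
      cnt <- c(cnt, rep(1L, k))
      org <- c(org, rep(g, k))
      sel <- c(sel, stats::runif(k) < config$fractionSelected)
      ids <- c(ids, newIds)
      nIntro <- nIntro + k
    }
    if (recordOccupancy && length(cnt)) {
      no <- no + 1L
      occId[[no]] <- ids
      occAge[[no]] <- g - org
      occFreq[[no]] <- cnt / n2
    }
    prevSize <- sizes[g]
    lastGen <- g
    if (mode == "absorption" && !length(cnt) && g > 1L) break
  }

  segFate <- if (mode == "absorption") "truncated" else "segregating"
  if (mode == "absorption" && length(cnt))
    warning(length(cnt), " trajectories still segregating at maxGenerations; ",
            "flagged 'truncated'")
  doneIds <- unlist(dn$id); doneFixed <- unlist(dn$fixed)
  doneSel <- unlist(dn$sel)
  sites <- data.frame(
    id = c(doneIds, ids),
    origin_generation = c(unlist(dn$org), org),
    gamma = c(ifelse(doneSel, config$gamma, 0),
              ifelse(sel, config$gamma, 0)),
    fate = c(ifelse(doneFixed, "fixation", "loss"),
             rep(segFate, length(ids))),
    final_count = c(unlist(dn$cnt), cnt),
    final_freq = c(unlist(dn$freq), cnt / (2 * prevSize)),
    end_generation = c(unlist(dn$gen), rep(lastGen, length(ids))))
  if (!nrow(sites))
    sites <- data.frame(id = integer(0), origin_generation = integer(0),
                        gamma = numeric(0), fate = character(0),
                        final_count = integer(0), final_freq = numeric(0),
                        end_generation = integer(0))
  sites <- sites[order(sites$id), , drop = FALSE]
  rownames(sites) <- NULL
  occupancy <- NULL
  if (recordOccupancy)
    occupancy <- data.frame(id = unlist(occId), age = unlist(occAge),
                            freq = unlist(occFreq))
  structure(list(sites = sites, occupancy = occupancy, sizes = sizes,
                 generations = lastGen, nIntroduced = nIntro,
                 nLost = nLost, nFixed = nFix, config = config),
            class = "AlleleTrajectories")
}

#' @export
print.AlleleTrajectories <- function(x, ...) {
  cat("AlleleTrajectories:", x$nIntroduced, "mutations introduced,",
      sum(x$sites$fate %in% c("segregating", "truncated")),
      "segregating at sampling\n")
  cat("  fates:", paste(names(table(x$sites$fate)), table(x$sites$fate),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Mean allele age per frequency bin and selection class
#'
#' Tallies true ages of simulated alleles into frequency bins (default 1\%
#' width), separately per selection class (distinct \code{gamma}).  With
#' \code{at = "sampling"} only alleles segregating at the sampling generation
#' contribute, each once, at its final frequency.  With
#' \code{at = "occupancy"} every generation an allele spent in a bin
#' contributes one observation at the allele's age in that generation; this
#' is the sampling-time ensemble under stationary mutation influx, and
#' standard errors are then clustered by allele.  Empty bins are emitted with
#' \code{n = 0} and \code{mean_age = NA}, not dropped.
#'
#' @param traj an \code{AlleleTrajectories} object.
#' @param bins frequency bin edges; default \code{seq(0, 1, 0.01)}.
#' @param at \code{"sampling"} or \code{"occupancy"}.
#' @return data.frame: \code{bin_low}, \code{bin_high}, \code{gamma},
#'   \code{n}, \code{mean_age}, \code{se} (ages in generations; \code{se} is
#'   NA where undefined, i.e. \code{n < 2}).
#' @export
ageByFrequency <- function(traj, bins = seq(0, 1, by = 0.01),
                           at = c("sampling", "occupancy")) {
  at <- match.arg(at)
  stopifnot(inherits(traj, "AlleleTrajectories"))
  if (!nrow(traj$sites)) stop("no trajectories to summarise")
  if (at == "sampling") {
    seg <- traj$sites[traj$sites$fate %in% c("segregating", "truncated"), ]
    dat <- data.frame(id = seg$id,
                      age = seg$end_generation - seg$origin_generation,
                      freq = seg$final_freq,
                      gamma = seg$gamma)
  } else {
    if (is.null(traj$occupancy))
      stop("occupancy mode needs simulateTrajectories(recordOccupancy = TRUE)")
    occ <- traj$occupancy
    gam <- traj$sites$gamma[match(occ$id, traj$sites$id)]
    dat <- data.frame(id = occ$id, age = occ$age, freq = occ$freq,
                      gamma = gam)
  }
  classes <- sort(unique(traj$sites$gamma))
  nb <- length(bins) - 1L
  binIdx <- findInterval(dat$freq, bins, rightmost.closed = TRUE,
                         all.inside = FALSE)
  out <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    res <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                      gamma = classes[ci], n = 0L, mean_age = NA_real_,
                      se = NA_real_)
    sub <- dat[dat$gamma == classes[ci] & binIdx >= 1 & binIdx <= nb, ]
    bi <- binIdx[dat$gamma == classes[ci] & binIdx >= 1 & binIdx <= nb]
    if (nrow(sub)) {
      res$n <- as.integer(tabulate(bi, nbins = nb))
      sums <- vapply(seq_len(nb), function(b) sum(sub$age[bi == b]), 0)
      res$mean_age <- ifelse(res$n > 0, sums / res$n, NA_real_)
      for (b in which(res$n > 1)) {
        rows <- bi == b
        if (at == "sampling") {
          res$se[b] <- stats::sd(sub$age[rows]) / sqrt(res$n[b])
        } else {
          # ratio-estimator SE clustered by allele id
          ai <- vapply(split(sub$age[rows], sub$id[rows]), sum, 0)
          mi <- vapply(split(sub$age[rows], sub$id[rows]), length, 0L)
          ccount <- length(ai)
          if (ccount > 1) {
            rhat <- sum(ai) / sum(mi)
            res$se[b] <- sqrt(sum((ai - rhat * mi)^2) * ccount /
                                (ccount - 1)) / sum(mi)
          }
        }
      }
    }
    out[[ci]] <- res
  }
  do.call(rbind, out)
}

#' Individual-based Wright-Fisher simulation of a recombining region
#'
#' Forward simulation of diploid individuals carrying haplotypes of the
#' configured region, with infinite-sites mutation at continuous positions,
#' crossover recombination, and genic selection (fitness multiplicative
#' across sites, additive within a locus).  Every mutation's origin
#' generation and selection coefficient are recorded; fixed mutations are
#' absorbed into the background and counted.  All randomness flows through
#' R's RNG, so results are reproducible from the config seed.
#'
#' @param config a [simulationConfig()]; a seed is mandatory.
#' @param thinInterval generations between purges of fixed/lost mutations.
#' @return object of class \code{"WFPopulation"}: \code{genotypes}
#'   (variant-by-haplotype 0/1 matrix over mutations segregating in the final
#'   population, ordered by position), \code{variants} (position in bp scale
#'   \code{[0, regionLength)}, origin generation, gamma, population count),
#'   \code{nHaplotypes}, \code{generations}, and introduction/fixation
#'   counters.
#' @export
simulatePopulation <- function(config, thinInterval = 25L) {
  .requireSeed(config)
  N <- config$N
  sizes <- c(rep(N, config$burnIn), popSizeSchedule(config))
  res <- wf_simulate_cpp(hapSizes = 2L * sizes,
                         muPerGamete = config$theta * config$regionLength /
                           (4 * N),
                         xoverPerMeiosis = config$rho * config$regionLength /
                           (4 * N),
                         regionLength = config$regionLength,
                         fracSelected = config$fractionSelected,
                         sSelected = config$gamma / (2 * N),
                         thinInterval = as.integer(thinInterval))
  variants <- data.frame(pos = res$pos,
                         origin_generation = res$origin,
                         gamma = res$s * 2 * N,
                         pop_count = res$count)
  structure(list(genotypes = res$genotypes, variants = variants,
                 nHaplotypes = ncol(res$genotypes),
                 generations = res$generations,
                 nIntroduced = res$nIntroduced, nFixed = res$nFixed,
                 config = config),
            class = "WFPopulation")
}

#' @export
print.WFPopulation <- function(x, ...) {
  cat("WFPopulation:", nrow(x$variants), "segregating variants in",
      x$nHaplotypes, "haplotypes after", x$generations, "generations\n")
  cat("  mutations introduced:", x$nIntroduced, "; fixed:", x$nFixed, "\n")
  invisible(x)
}

#' Sample a phased panel with truth ages from a simulated population
#'
#' Draws \code{nHaplotypes} haplotypes without replacement from the final
#' generation of an individual-based simulation and packages the variants
#' still segregating in the sample as a \linkS4class{HaplotypePanel}.  The
#' ancestral allele of every simulated variant is the non-mutant (REF)
#' allele.  Truth columns \code{originGeneration}, \code{trueAge} (in
#' generations before sampling), \code{gammaTruth}, \code{selected},
#' \code{popCount} and \code{popFreq} are carried in the variant table.
#' Continuous mutation positions are mapped to 1-based bp; in the rare event
#' of a collision the later variant is dropped (counted in
#' \code{metadata()$exclusions}).
#'
#' @param population a \code{"WFPopulation"}.
#' @param nHaplotypes number of haplotypes to sample (e.g. 188 for a panel of
#'   94 diploid individuals).
#' @param seed optional seed for the sampling step.
#' @param chrom contig name for the panel.
#' @return a \linkS4class{HaplotypePanel}.
#' @export
samplePanel <- function(population, nHaplotypes, seed = NULL, chrom = "sim") {
  stopifnot(inherits(population, "WFPopulation"))
  nh <- population$nHaplotypes
  if (nHaplotypes > nh)
    stop("nHaplotypes (", nHaplotypes, ") exceeds population haplotypes (",
         nh, ")")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nh, nHaplotypes)
  m <- population$genotypes[, idx, drop = FALSE]
  v <- population$variants
  bp <- as.integer(floor(v$pos)) + 1L
  dup <- duplicated(bp)
  ac <- rowSums(m)
  mono <- ac == 0 | ac == nHaplotypes
  keep <- !dup & !mono
  panel <- HaplotypePanel(
    m[keep, , drop = FALSE], chrom = chrom, pos = bp[keep],
    ref = rep("A", sum(keep)), alt = rep("C", sum(keep)),
    variantData = data.frame(
      originGeneration = v$origin_generation[keep],
      trueAge = population$generations - v$origin_generation[keep],
      gammaTruth = v$gamma[keep],
      selected = v$gamma[keep] != 0,
      popCount = v$pop_count[keep],
      popFreq = v$pop_count[keep] / nh))
  S4Vectors::metadata(panel)$exclusions <-
    list(position_collision = sum(dup), sample_monomorphic = sum(mono & !dup))
  panel
}
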