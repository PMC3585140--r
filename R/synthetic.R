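## Synthetic phased panels with known truth (ages, selection class,
## category labels), emulating the scale of a trio-phased population panel:
## 188 haplotypes (94 unrelated parents), contiguous regions with mutation
## and recombination, a mix of neutral and negatively selected variants,
## and PolyPhen-2-style category labels whose damage score increases with
## the strength of selection.

#' Configuration for synthetic panel generation
#'
#' @param nHaplotypes haplotypes to sample per region (default 188,
#'   matching 94 unrelated diploid parents).
#' @param N diploid population size of the underlying simulation (default
#'   200, a desk-scale size; gamma is defined relative to this N).
#' @param regionLength,theta,rho,fractionSelected,gamma as in
#'   [simulationConfig()].
#' @param replicates number of independent regions to simulate and pool
#'   (each becomes its own contig in the panel).
#' @param categoryProbabilities list with elements \code{neutral} and
#'   \code{selected}, each a named probability vector over category labels
#'   (must sum to 1 within each class).
#' @param ancestralErrorRate fraction of sites whose ancestral-map entry is
#'   deliberately flipped to the wrong allele (default 0; the simulated
#'   ancestral allele is the non-mutant allele, so polarization is exact by
#'   construction).
#' @param seed integer seed (mandatory for generation).
#' @return list of validated parameters with class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nHaplotypes = 188, N = 200, regionLength = 1e6,
                            theta = 1e-3, rho = 1e-3,
                            fractionSelected = 0.7, gamma = -10,
                            replicates = 1,
                            categoryProbabilities = list(
                              neutral = c(synonymous = 0.6, benign = 0.4),
                              selected = c(possibly_damaging = 0.4,
                                           probably_damaging = 0.6)),
                            ancestralErrorRate = 0, seed = NULL) {
  stopifnot(nHaplotypes >= 4, replicates >= 1,
            ancestralErrorRate >= 0, ancestralErrorRate <= 1)
  for (cls in c("neutral", "selected")) {
    p <- categoryProbabilities[[cls]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8)
      stop("categoryProbabilities$", cls, " must sum to 1")
  }
  structure(list(nHaplotypes = as.integer(nHaplotypes), N = as.integer(N),
                 regionLength = regionLength, theta = theta, rho = rho,
                 fractionSelected = fractionSelected, gamma = gamma,
                 replicates = as.integer(replicates),
                 categoryProbabilities = categoryProbabilities,
                 ancestralErrorRate = ancestralErrorRate, seed = seed),
            class = "SyntheticConfig")
}

#' Assign functional category labels and damage scores from truth classes
#'
#' Neutral variants are labelled from the neutral probability vector
#' (synonymous/benign by default), selected variants from the selected one
#' (possibly/probably damaging by default).  The continuous damage score is
#' drawn on the logit scale with location increasing in \code{|gamma|}, so
#' it rank-correlates positively with the strength of selection.
#'
#' @param panel a \linkS4class{HaplotypePanel} carrying the truth column
#'   \code{gammaTruth} (from [samplePanel()]).
#' @param config a [syntheticConfig()].
#' @return annotation data.frame: \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{category}, \code{damage_score}.
#' @export
assignCategories <- function(panel, config) {
  vi <- variantInfo(panel)
  if (!"gammaTruth" %in% colnames(vi))
    stop("panel carries no truth classes (gammaTruth)")
  n <- nrow(vi)
  category <- character(n)
  for (cls in c("neutral", "selected")) {
    idx <- if (cls == "neutral") which(vi$gammaTruth == 0) else
      which(vi$gammaTruth != 0)
    p <- config$categoryProbabilities[[cls]]
    if (length(idx))
      category[idx] <- sample(names(p), length(idx), replace = TRUE,
                              prob = p)
  }
  score <- stats::plogis(-1.5 + 0.3 * abs(vi$gammaTruth) +
                           stats::rnorm(n, 0, 0.8))
  data.frame(chrom = vi$chrom, pos = vi$pos, ref = vi$ref, alt = vi$alt,
             category = category, damage_score = score)
}

# stack panels over the same haplotypes as separate contigs of one panel
.combinePanels <- function(panels) {
  m <- do.call(rbind, lapply(panels, hapMatrix))
  vis <- lapply(panels, variantInfo)
  col <- function(name) unlist(lapply(vis, function(v) v[[name]]),
                               use.names = FALSE)
  extra <- setdiff(colnames(vis[[1]]),
                   c("chrom", "pos", "ref", "alt", "altCount", "mac",
                     "focal", "polarity", "derivedCount", "category",
                     "damageScore"))
  vd <- if (length(extra))
    as.data.frame(lapply(stats::setNames(extra, extra), col)) else NULL
  HaplotypePanel(m, chrom = col("chrom"), pos = col("pos"),
                 ref = col("ref"), alt = col("alt"),
                 haplotypeIds = colnames(hapMatrix(panels[[1]])),
                 variantData = vd)
}

#' Generate a synthetic phased panel with truth tables
#'
#' Runs the individual-based simulator for each replicate region, samples
#' \code{nHaplotypes} haplotypes, pools the regions as separate contigs of
#' one \linkS4class{HaplotypePanel}, assigns category labels and damage
#' scores, builds the ancestral-allele map (the simulated ancestral allele
#' is REF; optionally corrupted at \code{ancestralErrorRate}), and
#' polarizes the panel.  Deterministic given \code{config$seed}.
#'
#' @param config a [syntheticConfig()]; the seed is mandatory.
#' @param dir if non-NULL, write \code{<prefix>.vcf},
#'   \code{<prefix>.truth.tsv}, \code{<prefix>.annotations.tsv} and
#'   \code{<prefix>.ancestral.tsv} into this directory.
#' @param prefix file-name prefix for \code{dir} output.
#' @return list with \code{panel} (annotated, polarized), \code{truth},
#'   \code{annotations}, \code{ancestral} data.frames, and \code{files}
#'   (paths, when written).
#' @export
generatePanel <- function(config, dir = NULL, prefix = "panel") {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(config$seed))
    stop("a seed is required; set syntheticConfig(seed = ...)")
  set.seed(config$seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  panels <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    sc <- simulationConfig(N = config$N, theta = config$theta,
                           rho = config$rho,
                           regionLength = config$regionLength,
                           fractionSelected = config$fractionSelected,
                           gamma = config$gamma, demography = "constant",
                           seed = repSeeds[r])
    pop <- simulatePopulation(sc)
    panels[[r]] <- samplePanel(pop, config$nHaplotypes,
                               chrom = sprintf("region%d", r))
  }
  panel <- if (length(panels) == 1) panels[[1]] else .combinePanels(panels)

  annotations <- assignCategories(panel, config)
  vi <- variantInfo(panel)
  ancAllele <- vi$ref
  if (config$ancestralErrorRate > 0) {
    flip <- stats::runif(nrow(vi)) < config$ancestralErrorRate
    ancAllele[flip] <- vi$alt[flip]
  }
  ancestral <- data.frame(chrom = vi$chrom, pos = vi$pos,
                          ancestral_allele = ancAllele)
  panel <- attachAnnotations(panel, annotations)
  panel <- polarize(panel, ancestral)
  truth <- data.frame(chrom = vi$chrom, pos = vi$pos,
                      origin_generation = vi$originGeneration,
                      true_age = vi$trueAge, gamma = vi$gammaTruth,
                      class = ifelse(vi$selected, "selected", "neutral"))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, paste0(prefix, c(".vcf", ".truth.tsv",
                                             ".annotations.tsv",
                                             ".ancestral.tsv")))
    writePhasedVcf(panel, files[1])
    utils::write.table(truth, files[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(annotations, files[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ancestral, files[4], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(panel = panel, truth = truth, annotations = annotations,
       ancestral = ancestral, files = files)
}
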