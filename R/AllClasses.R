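#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData "rowData<-" rowRanges
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom stats rbinom rpois runif
#' @useDynLib alleleClock, .registration = TRUE
NULL

#' SojournProfile: gridded sojourn-time density conditional on frequency
#'
#' Mean sojourn time per unit frequency (units of 2N generations) spent at
#' each past frequency \code{y} by an allele currently at frequency \code{x},
#' under genic selection \code{gamma}, starting from \code{p0} (0 denotes the
#' new-mutation limit).  Created by [sojournProfile()].
#'
#' @slot x current population frequency.
#' @slot gamma scaled selection coefficient (2Ns).
#' @slot p0 initial frequency (0 = new-mutation limit).
#' @slot y frequency grid, strictly increasing in (0,1).
#' @slot density non-negative densities on \code{y}.
#' @slot meanAge adaptive-quadrature integral of the density over (0,1).
#' @export
setClass("SojournProfile",
  representation(x = "numeric", gamma = "numeric", p0 = "numeric",
                 y = "numeric", density = "numeric", meanAge = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@x) != 1 || object@x <= 0 || object@x >= 1)
      msg <- c(msg, "x must be a single frequency in (0,1)")
    if (length(object@y) != length(object@density))
      msg <- c(msg, "y and density lengths differ")
    if (any(object@density < 0))
      msg <- c(msg, "density must be non-negative")
    if (is.unsorted(object@y, strictly = TRUE))
      msg <- c(msg, "y must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SojournProfile", function(object) {
  cat("SojournProfile: x =", object@x, ", gamma =", object@gamma,
      if (object@p0 > 0) paste(", p0 =", object@p0) else ", p0 -> 0 (new mutation)",
      "\n  grid of", length(object@y), "frequencies;",
      "mean age", format(object@meanAge, digits = 4), "(2N generations)\n")
})

#' HaplotypePanel: phased haplotype-by-variant matrix with annotations
#'
#' A \linkS4class{RangedSummarizedExperiment} whose single assay
#' \code{"haplotypes"} is an integer variant-by-haplotype matrix of 0 (REF)
#' and 1 (ALT), with per-variant metadata in \code{rowData}: \code{ref},
#' \code{alt}, \code{mac} (minor allele count), \code{focal} (which allele,
#' \code{"ref"} or \code{"alt"}, is the minor one; exact 50/50 ties go to
#' ALT), \code{polarity} (\code{derived}/\code{ancestral}/\code{unpolarized},
#' describing the minor allele once [polarize()] has been applied),
#' \code{derivedCount}, \code{category} and \code{damageScore}.  Columns are
#' individual phased haplotypes, two per diploid sample.
#'
#' @export
setClass("HaplotypePanel", contains = "RangedSummarizedExperiment")

.validHaplotypePanel <- function(object) {
  msg <- NULL
  if (!"haplotypes" %in% SummarizedExperiment::assayNames(object))
    return("assay 'haplotypes' is missing")
  m <- SummarizedExperiment::assay(object, "haplotypes")
  if (!all(m %in% c(0L, 1L)))
    msg <- c(msg, "assay entries must be 0 or 1")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("ref", "alt", "mac", "focal")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  altCount <- as.integer(rowSums(m))
  macExp <- pmin(altCount, ncol(m) - altCount)
  if (nrow(m) && any(rd$mac != macExp))
    msg <- c(msg, "mac inconsistent with assay column sums")
  gr <- SummarizedExperiment::rowRanges(object)
  pos <- GenomicRanges::start(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (nrow(m) && any(unlist(lapply(split(pos, chr), function(p)
    is.unsorted(p, strictly = TRUE)))))
    msg <- c(msg, "positions must be strictly increasing within each contig")
  if (is.null(msg)) TRUE else msg
}

setValidity("HaplotypePanel", .validHaplotypePanel)

#' Construct a HaplotypePanel
#'
#' @param genotypes integer matrix, variants in rows, haplotypes in columns;
#'   entries 0 (REF allele) or 1 (ALT allele), fully phased, no missing data.
#' @param chrom,pos contig names and 1-based positions per variant; variants
#'   are reordered by (chrom, pos) and must have unique positions per contig.
#' @param ref,alt allele strings per variant.
#' @param haplotypeIds optional column names; defaults to \code{hap1..hapN}.
#' @param variantData optional data.frame of extra per-variant columns (for
#'   example truth ages from the simulator).
#' @return a \linkS4class{HaplotypePanel}.
#' @examples
#' m <- matrix(c(0L,1L,1L,0L, 0L,0L,1L,1L), nrow = 2, byrow = TRUE)
#' HaplotypePanel(m, chrom = "1", pos = c(100L, 200L),
#'                ref = c("A","C"), alt = c("G","T"))
#' @export
HaplotypePanel <- function(genotypes, chrom, pos, ref, alt,
                           haplotypeIds = NULL, variantData = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  nv <- nrow(genotypes)
  chrom <- rep_len(as.character(chrom), nv)
  pos <- as.integer(pos)
  stopifnot(length(pos) == nv, length(ref) == nv, length(alt) == nv)
  ord <- order(chrom, pos)
  genotypes <- genotypes[ord, , drop = FALSE]
  chrom <- chrom[ord]; pos <- pos[ord]
  ref <- as.character(ref)[ord]; alt <- as.character(alt)[ord]
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicate (chrom, pos) entries are not allowed in a panel")
  if (is.null(haplotypeIds))
    haplotypeIds <- paste0("hap", seq_len(ncol(genotypes)))
  colnames(genotypes) <- haplotypeIds
  altCount <- as.integer(rowSums(genotypes))
  n <- ncol(genotypes)
  mac <- pmin(altCount, n - altCount)
  focal <- ifelse(altCount <= n - altCount, "alt", "ref")
  rd <- S4Vectors::DataFrame(
    ref = ref, alt = alt, altCount = altCount, mac = mac, focal = focal,
    polarity = rep("unpolarized", nv), derivedCount = rep(NA_integer_, nv),
    category = rep("none", nv), damageScore = rep(NA_real_, nv))
  if (!is.null(variantData)) {
    variantData <- S4Vectors::DataFrame(variantData)[ord, , drop = FALSE]
    for (cn in colnames(variantData)) rd[[cn]] <- variantData[[cn]]
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(haplotypes = genotypes), rowRanges = gr)
  SummarizedExperiment::rowData(se) <- rd
  new("HaplotypePanel", se)
}

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object), "variants x", ncol(object),
      "haplotypes\n")
  rd <- SummarizedExperiment::rowData(object)
  if (nrow(object)) {
    cat("  MAC range:", paste(range(rd$mac), collapse = "-"),
        "| polarized:", sum(rd$polarity != "unpolarized"),
        "| annotated:", sum(rd$category != "none"), "\n")
  }
  ex <- S4Vectors::metadata(object)$exclusions
  if (!is.null(ex))
    cat("  exclusions on import:",
        paste(names(ex), unlist(ex), sep = "=", collapse = ", "), "\n")
})

#' @describeIn HaplotypePanel the variant-by-haplotype 0/1 matrix.
#' @param x a HaplotypePanel.
#' @export
hapMatrix <- function(x) SummarizedExperiment::assay(x, "haplotypes")

#' @describeIn HaplotypePanel per-variant table (chrom, pos and rowData).
#' @export
variantInfo <- function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  cbind(S4Vectors::DataFrame(chrom = as.character(GenomicRanges::seqnames(gr)),
                             pos = GenomicRanges::start(gr)),
        SummarizedExperiment::rowData(x))
}

#' @describeIn HaplotypePanel number of haplotypes (columns).
#' @export
nHaplotypes <- function(x) ncol(x)
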