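## The Neighborhood-based Clock (NC) statistic.
##
## For an index variant, scan outward in each direction along the contig to
## the closest variant that either shows evidence of recombination with the
## index (four-gamete test) or is fully linked but rarer (its carriers are a
## strict subset of the index carriers, i.e. it arose later on the index
## haplotype).  NC is the base-10 logarithm of the sum of the two physical
## distances; larger values indicate younger alleles.

# logical carrier mask for variant i: haplotypes carrying the focal allele
.carrierMask <- function(m, focalAlt, i) {
  if (focalAlt[i]) m[i, ] == 1L else m[i, ] == 0L
}

#' Carrier haplotypes of a variant's focal allele
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param variant row index of the variant.
#' @param mode \code{"minor"} (default) uses the minor allele as focal;
#'   \code{"derived"} uses the derived allele and requires the variant to be
#'   polarized.
#' @return integer vector of haplotype (column) indices; its length equals
#'   the variant's MAC in minor mode.
#' @export
carrierSet <- function(panel, variant, mode = c("minor", "derived")) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "HaplotypePanel"),
            variant >= 1, variant <= nrow(panel))
  m <- hapMatrix(panel)
  rd <- SummarizedExperiment::rowData(panel)
  focalAlt <- .focalAltFlags(rd, mode)
  if (is.na(focalAlt[variant]))
    stop("variant ", variant, " is unpolarized; cannot use derived mode")
  unname(which(.carrierMask(m, focalAlt, variant)))
}

# per-variant flag: TRUE if the focal allele is ALT, FALSE if REF,
# NA if undefined (derived mode on unpolarized variants)
.focalAltFlags <- function(rd, mode) {
  if (mode == "minor") {
    rd$focal == "alt"
  } else {
    # derived allele: ALT when the minor allele is ALT and derived, or the
    # minor allele is REF and ancestral; i.e. polarity resolves which physical
    # allele is derived
    minorIsAlt <- rd$focal == "alt"
    ifelse(rd$polarity == "unpolarized", NA,
           ifelse(rd$polarity == "derived", minorIsAlt, !minorIsAlt))
  }
}

#' Four-gamete test between two panel variants
#'
#' TRUE when all four two-locus haplotypes (0-0, 0-1, 1-0, 1-1) are observed
#' in the panel, which under infinite sites indicates a recombination (or
#' recurrent mutation) event between the two sites.  The result does not
#' depend on which allele is labelled focal at either site.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param i,j distinct row indices of segregating variants.
#' @return logical.
#' @export
fourGamete <- function(panel, i, j) {
  stopifnot(i != j)
  m <- hapMatrix(panel)
  a <- m[i, ] == 1L
  b <- m[j, ] == 1L
  any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b)
}

#' Is a candidate fully linked and rarer than the index variant?
#'
#' TRUE when the candidate's carrier set is a strict, non-empty subset of
#' the index variant's carrier set: the candidate mutation arose later on
#' the haplotype background already carrying the index allele.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param index,cand row indices of segregating variants.
#' @param mode focal-allele convention, as in [carrierSet()].
#' @return logical.
#' @export
fullyLinkedRarer <- function(panel, index, cand, mode = c("minor", "derived")) {
  mode <- match.arg(mode)
  m <- hapMatrix(panel)
  rd <- SummarizedExperiment::rowData(panel)
  focalAlt <- .focalAltFlags(rd, mode)
  a <- .carrierMask(m, focalAlt, index)
  b <- .carrierMask(m, focalAlt, cand)
  !any(b & !a) && any(a & !b) && any(b)
}

# car: variants x haplotypes logical carrier matrix; candIdx must be sorted
# by position; index is scanned against candidates outward in each direction
.ncOne <- function(car, pos, index, candIdx) {
  a <- car[index, ]
  scan <- function(cands) {
    for (j in cands) {
      b <- car[j, ]
      onlyA <- any(a & !b)
      if (!any(b & !a)) {
        if (onlyA)   # strict, non-empty subset of the index carriers
          return(list(d = abs(pos[j] - pos[index]), reason = "linked_rarer"))
      } else if (onlyA && any(a & b) && any(!a & !b)) {
        return(list(d = abs(pos[j] - pos[index]), reason = "recombination"))
      }
    }
    list(d = NA_integer_, reason = "censored")
  }
  below <- candIdx[pos[candIdx] < pos[index]]
  up <- scan(rev(below))
  down <- scan(candIdx[pos[candIdx] > pos[index]])
  nc <- if (up$reason != "censored" && down$reason != "censored")
    log10(up$d + down$d) else NA_real_
  list(d_up = up$d, reason_up = up$reason,
       d_down = down$d, reason_down = down$reason, nc = nc)
}

#' NC statistic for a single index variant
#'
#' Scans outward from the index position in both directions over candidate
#' variants on the same contig, stopping in each direction at the first
#' candidate that passes the four-gamete test against the index or whose
#' carriers are a strict subset of the index carriers.  The distance in each
#' direction is the absolute 1-based position difference to the stopping
#' variant; NC is \code{log10(d_up + d_down)}.  A direction with no
#' qualifying candidate before the end of the contig is censored and NC is
#' then undefined.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param index row index of the index variant; must be segregating with
#'   MAC >= 2 unless \code{includeSingletons}.
#' @param mode focal-allele convention, as in [carrierSet()].
#' @param includeSingletons if TRUE, singleton variants are admitted both as
#'   candidates and as index variants (default FALSE, matching the analysis
#'   convention of using non-singleton variants only).
#' @return one-row data.frame: \code{d_up}, \code{reason_up}, \code{d_down},
#'   \code{reason_down}, \code{nc}.
#' @export
ncStatistic <- function(panel, index, mode = c("minor", "derived"),
                        includeSingletons = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "HaplotypePanel"))
  if (index < 1 || index > nrow(panel)) stop("index variant not in panel")
  rd <- SummarizedExperiment::rowData(panel)
  minMac <- if (includeSingletons) 1L else 2L
  if (rd$mac[index] < minMac)
    stop("index variant must be segregating with MAC >= ", minMac)
  m <- hapMatrix(panel)
  focalAlt <- .focalAltFlags(rd, mode)
  if (is.na(focalAlt[index]))
    stop("index variant is unpolarized; cannot use derived mode")
  gr <- SummarizedExperiment::rowRanges(panel)
  pos <- GenomicRanges::start(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  candIdx <- which(rd$mac >= minMac & chr == chr[index] & !is.na(focalAlt))
  candIdx <- setdiff(candIdx, index)
  car <- (m == 1L) == focalAlt   # row i is TRUE where the focal allele sits
  res <- .ncOne(car, pos, index, candIdx)
  as.data.frame(res)
}

#' NC statistics for all index variants of a panel
#'
#' Computes [ncStatistic()] for every variant whose MAC falls in
#' \code{indexMac} (and, in derived mode, which is polarized), returning one
#' row per index variant together with its annotation columns.  Censored
#' results carry \code{nc = NA} and are reported, not dropped; downstream
#' statistics exclude them.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param indexMac integer vector of admissible index MAC values
#'   (default \code{2:6}).
#' @param mode focal-allele convention, as in [carrierSet()].
#' @param includeSingletons admit singleton candidates (default FALSE).
#' @return data.frame: \code{chrom}, \code{pos}, \code{mac},
#'   \code{polarity}, \code{category}, \code{damage_score}, \code{d_up},
#'   \code{reason_up}, \code{d_down}, \code{reason_down}, \code{nc}, plus
#'   any truth columns present in the panel (\code{trueAge},
#'   \code{gammaTruth}).
#' @export
ncPanel <- function(panel, indexMac = 2:6, mode = c("minor", "derived"),
                    includeSingletons = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "HaplotypePanel"))
  rd <- SummarizedExperiment::rowData(panel)
  m <- hapMatrix(panel)
  focalAlt <- .focalAltFlags(rd, mode)
  gr <- SummarizedExperiment::rowRanges(panel)
  pos <- GenomicRanges::start(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  minMac <- if (includeSingletons) 1L else 2L
  indices <- which(rd$mac %in% indexMac & !is.na(focalAlt))
  car <- (m == 1L) == focalAlt
  candAll <- which(rd$mac >= minMac & !is.na(focalAlt))
  candByChr <- split(candAll, chr[candAll])
  out <- vector("list", length(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    candIdx <- candByChr[[chr[i]]]
    candIdx <- candIdx[candIdx != i]
    out[[k]] <- .ncOne(car, pos, i, candIdx)
  }
  res <- data.frame(
    chrom = chr[indices], pos = pos[indices], mac = rd$mac[indices],
    polarity = rd$polarity[indices], category = rd$category[indices],
    damage_score = rd$damageScore[indices],
    d_up = vapply(out, `[[`, 1, "d_up"),
    reason_up = vapply(out, `[[`, "", "reason_up"),
    d_down = vapply(out, `[[`, 1, "d_down"),
    reason_down = vapply(out, `[[`, "", "reason_down"),
    nc = vapply(out, `[[`, 1, "nc"))
  for (extra in c("trueAge", "gammaTruth", "selected"))
    if (extra %in% colnames(rd)) res[[extra]] <- rd[[extra]][indices]
  res
}
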