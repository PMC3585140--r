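## Reading and writing phased haplotype panels and their annotations.

#' Read a phased VCF into a HaplotypePanel
#'
#' Parses a VCF 4.x file (plain or gzipped) of phased diploid genotypes into
#' a \linkS4class{HaplotypePanel}.  Only biallelic SNVs with fully phased,
#' non-missing GT fields (\code{a|b}) are retained; multiallelic records,
#' non-SNVs, records with any unphased or missing genotype, and duplicated
#' (chrom, pos) records are excluded and counted in
#' \code{metadata(panel)$exclusions}.
#'
#' @param path path to the VCF file.
#' @return a \linkS4class{HaplotypePanel} with two haplotype columns per
#'   sample, named \code{<sample>_1} and \code{<sample>_2}.
#' @seealso [writePhasedVcf()]
#' @export
readPhasedVcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  gtOnly <- vcfR::extract.gt(vcf, element = "GT", as.numeric = FALSE)
  if (is.null(dim(gtOnly)))
    gtOnly <- matrix(gtOnly, nrow = nrow(fix),
                     dimnames = list(NULL, samples))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & !multi
  phasedOk <- matrix(grepl("^[01]\\|[01]$", gtOnly), nrow = nrow(gtOnly))
  allPhased <- rowSums(phasedOk) == ncol(gtOnly)
  keep <- snv & allPhased & !multi
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  dup <- duplicated(key) & keep
  keep <- keep & !dup
  exclusions <- list(multiallelic = sum(multi),
                     non_snv = sum(!multi & !snv),
                     unphased_or_missing = sum(snv & !allPhased),
                     duplicate_position = sum(dup))

  idx <- which(keep)
  nHap <- 2L * length(samples)
  m <- matrix(0L, nrow = length(idx), ncol = nHap)
  if (length(idx)) {
    g <- gtOnly[idx, , drop = FALSE]
    a1 <- substr(g, 1, 1) == "1"
    a2 <- substr(g, 3, 3) == "1"
    m[, seq(1, nHap, by = 2)] <- a1 * 1L
    m[, seq(2, nHap, by = 2)] <- a2 * 1L
  }
  panel <- HaplotypePanel(
    m, chrom = fix[idx, "CHROM"], pos = as.integer(fix[idx, "POS"]),
    ref = ref[idx], alt = alt[idx],
    haplotypeIds = paste0(rep(samples, each = 2), "_", c(1, 2)))
  S4Vectors::metadata(panel)$exclusions <- exclusions
  panel
}

#' Write a HaplotypePanel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with one diploid sample per pair of consecutive
#' haplotype columns and phased GT fields.  \code{readPhasedVcf()} of the
#' result reproduces the genotype matrix, positions and alleles exactly.
#'
#' @param panel a \linkS4class{HaplotypePanel} with an even number of
#'   haplotype columns.
#' @param path output path (plain text; use no .gz suffix).
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
  stopifnot(is(panel, "HaplotypePanel"))
  nh <- ncol(panel)
  if (nh %% 2 != 0)
    stop("an even number of haplotypes is required to form diploid samples")
  vi <- variantInfo(panel)
  m <- hapMatrix(panel)
  sampleNames <- paste0("sample", seq_len(nh / 2))
  gtcols <- vapply(seq_len(nh / 2), function(i)
    paste0(m[, 2 * i - 1], "|", m[, 2 * i]), character(nrow(m)))
  if (nrow(m) == 1) gtcols <- matrix(gtcols, nrow = 1)
  header <- c("##fileformat=VCFv4.2",
              "##source=alleleClock",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleNames), collapse = "\t"))
  body <- character(nrow(m))
  if (nrow(m)) {
    left <- paste(vi$chrom, vi$pos, ".", vi$ref, vi$alt, ".", "PASS", ".",
                  "GT", sep = "\t")
    body <- paste(left, apply(matrix(gtcols, nrow = nrow(m)), 1, paste,
                              collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Polarize panel variants as derived or ancestral
#'
#' Given a per-site ancestral-allele map, sets for each variant the derived
#' allele count and the polarity of the minor (focal) allele:
#' \code{"derived"} if the minor allele differs from the ancestral allele,
#' \code{"ancestral"} if it equals it (the common situation for a
#' near-fixed derived allele), \code{"unpolarized"} when the site is absent
#' from the map or the mapped allele matches neither REF nor ALT.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param ancestralMap data.frame with columns \code{chrom}, \code{pos},
#'   \code{ancestral_allele} (see [readAncestralMap()]).
#' @return the panel with \code{polarity} and \code{derivedCount} filled in.
#' @export
polarize <- function(panel, ancestralMap) {
  stopifnot(is(panel, "HaplotypePanel"),
            all(c("chrom", "pos", "ancestral_allele") %in%
                  colnames(ancestralMap)))
  vi <- variantInfo(panel)
  key <- paste(vi$chrom, vi$pos)
  anc <- toupper(ancestralMap$ancestral_allele[
    match(key, paste(ancestralMap$chrom, ancestralMap$pos))])
  rd <- SummarizedExperiment::rowData(panel)
  n <- ncol(panel)
  isRef <- !is.na(anc) & anc == vi$ref
  isAlt <- !is.na(anc) & anc == vi$alt
  rd$derivedCount <- ifelse(isRef, rd$altCount,
                            ifelse(isAlt, n - rd$altCount, NA_integer_))
  minorAllele <- ifelse(rd$focal == "alt", vi$alt, vi$ref)
  rd$polarity <- ifelse(!isRef & !isAlt, "unpolarized",
                        ifelse(minorAllele == anc, "ancestral", "derived"))
  SummarizedExperiment::rowData(panel) <- rd
  validObject(panel)
  panel
}

#' Attach functional annotations to a panel
#'
#' Joins an annotation table keyed by (chrom, pos, alt) onto the panel's
#' variants, filling \code{category} and \code{damageScore}.  Coding
#' variants absent from the table keep \code{category = "none"}.  Duplicate
#' keys in the table are an error; rows with a damage score outside [0,1]
#' are rejected with a warning.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param table data.frame with columns \code{chrom}, \code{pos},
#'   \code{alt}, \code{category} and optionally \code{damage_score}
#'   (see [readAnnotationTable()]).
#' @return the annotated panel; match counts are stored in
#'   \code{metadata(panel)$annotation_matches}.
#' @export
attachAnnotations <- function(panel, table) {
  stopifnot(is(panel, "HaplotypePanel"),
            all(c("chrom", "pos", "alt", "category") %in% colnames(table)))
  keys <- paste(table$chrom, table$pos, table$alt)
  if (anyDuplicated(keys))
    stop("duplicate annotation keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  if (!is.null(table$damage_score)) {
    bad <- !is.na(table$damage_score) &
      (table$damage_score < 0 | table$damage_score > 1)
    if (any(bad)) {
      warning(sum(bad), " annotation row(s) with damage_score outside [0,1] rejected")
      table <- table[!bad, , drop = FALSE]
      keys <- keys[!bad]
    }
  }
  vi <- variantInfo(panel)
  hit <- match(paste(vi$chrom, vi$pos, vi$alt), keys)
  rd <- SummarizedExperiment::rowData(panel)
  rd$category <- ifelse(is.na(hit), "none", table$category[hit])
  if (!is.null(table$damage_score))
    rd$damageScore <- ifelse(is.na(hit), NA_real_, table$damage_score[hit])
  SummarizedExperiment::rowData(panel) <- rd
  S4Vectors::metadata(panel)$annotation_matches <-
    list(matched = sum(!is.na(hit)), unmatched = sum(is.na(hit)))
  validObject(panel)
  panel
}

#' Read an annotation table
#'
#' TSV with header \code{chrom, pos, ref, alt, category, damage_score};
#' categories follow PolyPhen-2 naming (\code{synonymous}, \code{benign},
#' \code{possibly_damaging}, \code{probably_damaging}, \code{other},
#' \code{none}) and \code{damage_score} is a probability in [0,1] or NA.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read an ancestral-allele map
#'
#' TSV with header \code{chrom, pos, ancestral_allele}; the allele is an
#' upper-case base, or any other symbol (e.g. \code{N}) for unknown.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readAncestralMap <- function(path) {
  if (!file.exists(path)) stop("ancestral map not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
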