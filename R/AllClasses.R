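#' ExonIndex: exon intervals per gene symbol
#'
#' Holds, for every annotated gene symbol, its chromosome, strand and the
#' union of its exon intervals (overlapping exons are merged so a SNP in
#' two exons of one gene is counted once). Built by [readAnnotation()].
#'
#' @slot exons a named [GenomicRanges::GRangesList], one element per gene
#'   symbol, holding the reduced (merged) exon intervals of that gene.
#' @slot geneStrand named character vector, `"+"`, `"-"` or `"*"` per gene.
#' @aliases ExonIndex
#' @exportClass ExonIndex
setClass("ExonIndex",
  slots = c(exons = "GRangesList", geneStrand = "character"))

setValidity("ExonIndex", function(object) {
  nm <- names(object@exons)
  if (is.null(nm) || anyDuplicated(nm))
    return("exons must be named by unique gene symbols")
  if (!identical(nm, names(object@geneStrand)))
    return("geneStrand names must match exons names")
  nchr <- vapply(object@exons, function(gr)
    length(unique(as.character(seqnames(gr)))), integer(1))
  if (any(nchr != 1L))
    return(sprintf("gene(s) with exons on multiple chromosomes: %s",
                   paste(nm[nchr != 1L], collapse = ", ")))
  if (any(unlist(width(object@exons)) < 1L))
    return("all exon intervals must have positive width")
  TRUE
})

#' GenotypePanel: a multi-sample diploid genotype matrix over SNP records
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are SNP
#' records (one per alternative allele of each site: a site with k ALT
#' alleles contributes k rows sharing chromosome/position/REF) and whose
#' columns are panel individuals. The single assay `"geno"` holds integer
#' codes: 0 = no copy of this alternative allele, 1 = exactly one copy
#' (heterozygous for this allele), 2 = two copies, `NA` = missing call.
#' Row metadata carries `snpId` (`chrom:pos:ref:alt`), `ref`, `alt` and
#' `siteKey` (`chrom:pos:ref`, shared by sibling ALT records). Optional
#' sample metadata (`sex` in M/F, `ancestry` in EUR/AFR/AMR/EAS/SAS) lives
#' in `colData`.
#'
#' @aliases GenotypePanel
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    return("assay 'geno' is required")
  g <- SummarizedExperiment::assay(object, "geno")
  bad <- !(g %in% c(0L, 1L, 2L)) & !is.na(g)
  if (any(bad))
    return("genotype codes must be 0, 1, 2 or NA")
  mc <- mcols(rowRanges(object))
  need <- c("snpId", "ref", "alt", "siteKey")
  if (!all(need %in% colnames(mc)))
    return(sprintf("row metadata must contain %s", paste(need, collapse = ", ")))
  if (anyDuplicated(mc$snpId))
    return("snpId must be unique within a panel")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample ids must be unique and non-empty")
  ## per sample and site, copies of all alternative alleles cannot exceed
  ## the diploid count of 2
  if (nrow(object) > 0L && ncol(object) > 0L) {
    persite <- rowsum(ifelse(is.na(g), 0L, g), mc$siteKey)
    if (any(persite > 2L))
      return("alt-allele copies at one site exceed 2 for some sample")
  }
  TRUE
})

#' AseGeneList: one individual's list of ASE gene symbols
#'
#' The (possibly anonymous) list of gene symbols reported as
#' allele-specific expressed in one individual, optionally together with
#' known sex and ancestry of the list's owner. Gene symbols are unique;
#' matching against the annotation is by exact case-sensitive symbol.
#'
#' @slot label individual label (a sample id or an anonymous placeholder).
#' @slot genes character vector of unique gene symbols, in input order.
#' @slot sex `"M"`, `"F"` or `NA`.
#' @slot ancestry one of EUR/AFR/AMR/EAS/SAS, or `NA`.
#' @slot removed gene symbols dropped by [sanitizeList()] (provenance).
#' @aliases AseGeneList
#' @exportClass AseGeneList
setClass("AseGeneList",
  slots = c(label = "character", genes = "character",
            sex = "character", ancestry = "character",
            removed = "character"))

setValidity("AseGeneList", function(object) {
  if (length(object@label) != 1L) return("label must be a single string")
  if (anyDuplicated(object@genes)) return("gene symbols must be unique")
  if (!is.na(object@sex) && !object@sex %in% c("M", "F"))
    return("sex must be 'M', 'F' or NA")
  if (!is.na(object@ancestry) && !object@ancestry %in% ANCESTRIES)
    return(sprintf("ancestry must be one of %s or NA",
                   paste(ANCESTRIES, collapse = "/")))
  TRUE
})

ANCESTRIES <- c("EUR", "AFR", "AMR", "EAS", "SAS")

#' Construct an AseGeneList
#'
#' @param genes character vector of gene symbols (must be unique).
#' @param label individual label; defaults to `"anonymous"`.
#' @param sex,ancestry optional auxiliary features of the list's owner.
#' @return an [AseGeneList-class] object.
#' @export
AseGeneList <- function(genes, label = "anonymous",
                        sex = NA_character_, ancestry = NA_character_) {
  new("AseGeneList", label = as.character(label),
      genes = as.character(genes),
      sex = as.character(sex), ancestry = as.character(ancestry),
      removed = character(0))
}

#' CandidateSet: inferred heterozygous-SNP set for one gene list
#'
#' The set of SNP records inferred to be heterozygous in the list's owner:
#' every panel SNP falling in an exon of a listed gene that survives the
#' heterozygous-genotyping-frequency filter. Carries per-SNP provenance
#' (which listed genes contributed it), the panel het frequency of each
#' candidate, the filter settings used, and optional auxiliary features.
#'
#' @slot snpIds candidate SNP identifiers (`chrom:pos:ref:alt`).
#' @slot freq named numeric, panel heterozygous genotyping frequency per
#'   candidate.
#' @slot sourceGenes named list mapping each snpId to the contributing
#'   gene symbol(s).
#' @slot sex,ancestry auxiliary features to be matched alongside SNPs
#'   (`NA` = absent).
#' @slot bounds numeric length-2 filter bounds used (lower, upper).
#' @slot filterMode `"exclude-range"` or `"keep-range"`.
#' @slot label the gene list's label, for bookkeeping.
#' @aliases CandidateSet
#' @exportClass CandidateSet
setClass("CandidateSet",
  slots = c(snpIds = "character", freq = "numeric", sourceGenes = "list",
            sex = "character", ancestry = "character",
            bounds = "numeric", filterMode = "character",
            label = "character"))

setValidity("CandidateSet", function(object) {
  n <- length(object@snpIds)
  if (anyDuplicated(object@snpIds)) return("snpIds must be unique")
  if (length(object@freq) != n || !identical(names(object@freq), object@snpIds))
    return("freq must be named by snpIds")
  if (length(object@sourceGenes) != n)
    return("sourceGenes must have one entry per snpId")
  if (length(object@bounds) != 2L || object@bounds[1] >= object@bounds[2])
    return("bounds must be (lower, upper) with lower < upper")
  TRUE
})

#' LinkResult: scores, ranking and confidence for one linking run
#'
#' Per panel individual (scenario 1) or per anonymized gene list
#' (scenario 2): the linking score L in bits, the rank (1 = best match,
#' ties broken lexicographically), the number of matched candidate items,
#' and the entropy-based matching probability. Run-level fields hold the
#' gap statistic max/max2, its empirical p-value when a permutation null
#' has been run, and the best match.
#'
#' @slot table a [S4Vectors::DataFrame] with columns `id`, `score`,
#'   `nMatched`, `rank`, `pi`, ordered by rank.
#' @slot gap ratio of best to second-best score (`Inf` if the runner-up
#'   scored 0 while the best did not; 1 if the best score is 0).
#' @slot pGap empirical p-value of the gap (`NA` until
#'   [gapSignificance()] is run).
#' @slot bestMatch id of the rank-1 individual/list.
#' @slot uninformative `TRUE` when all scores are 0.
#' @slot params list of run parameters (bounds, seed, axis, ...).
#' @aliases LinkResult
#' @exportClass LinkResult
setClass("LinkResult",
  slots = c(table = "DFrame", gap = "numeric", pGap = "numeric",
            bestMatch = "character", uninformative = "logical",
            params = "list"))

setValidity("LinkResult", function(object) {
  tb <- object@table
  need <- c("id", "score", "nMatched", "rank", "pi")
  if (!all(need %in% colnames(tb)))
    return(sprintf("table must contain columns %s", paste(need, collapse = ", ")))
  if (nrow(tb) && !identical(sort(tb$rank), seq_len(nrow(tb))))
    return("ranks must be a permutation of 1..N")
  if (nrow(tb) && abs(sum(tb$pi) - 1) > 1e-9)
    return("matching probabilities must sum to 1")
  TRUE
})
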