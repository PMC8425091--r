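## Accessors and show() methods for the core classes. Slot access from user
## code should go through these.

#' Gene symbols held by an ExonIndex
#' @param x an `ExonIndex`.
#' @return character vector of gene symbols.
#' @export
setMethod("geneNames", "ExonIndex", function(x) names(x@exons))

#' Merged exon intervals of one gene
#'
#' Fails loudly for symbols absent from the index.
#' @param x an `ExonIndex`.
#' @param gene a single gene symbol.
#' @return a `GRanges` of merged exon intervals.
#' @export
setMethod("exonsOf", "ExonIndex", function(x, gene) {
  stopifnot(length(gene) == 1L)
  if (!gene %in% names(x@exons))
    stop(sprintf("gene '%s' is not in the annotation index", gene), call. = FALSE)
  x@exons[[gene]]
})

#' Genomic span of genes (bp)
#'
#' The span of the exon-union envelope: last exon end minus first exon
#' start plus one. Used for length-weighted gene counts.
#' @param x an `ExonIndex`.
#' @param genes gene symbols; defaults to all genes in the index.
#' @return named numeric vector of spans in bp.
#' @export
setMethod("geneSpan", "ExonIndex", function(x, genes) {
  if (missing(genes)) genes <- geneNames(x)
  miss <- setdiff(genes, geneNames(x))
  if (length(miss))
    stop(sprintf("gene(s) not in the annotation index: %s",
                 paste(head(miss, 5), collapse = ", ")), call. = FALSE)
  vapply(genes, function(g) {
    gr <- x@exons[[g]]
    max(end(gr)) - min(start(gr)) + 1
  }, numeric(1))
})

setMethod("length", "ExonIndex", function(x) length(x@exons))

setMethod("show", "ExonIndex", function(object) {
  cat(sprintf("ExonIndex with %d gene(s) on %d chromosome(s)\n",
              length(object),
              length(unique(unlist(lapply(object@exons, function(g)
                as.character(seqnames(g))[1]))))))
  nex <- sum(lengths(object@exons))
  cat(sprintf("  %d merged exon interval(s)\n", nex))
})

#' SNP record identifiers of a panel
#' @param x a `GenotypePanel`.
#' @return character vector `chrom:pos:ref:alt`, one per record.
#' @export
setMethod("snpIds", "GenotypePanel", function(x) mcols(rowRanges(x))$snpId)

#' Sample identifiers of a panel
#' @param x a `GenotypePanel`.
#' @return character vector of sample ids.
#' @export
setMethod("sampleIds", "GenotypePanel", function(x) colnames(x))

#' Genotype code matrix of a panel
#' @param x a `GenotypePanel`.
#' @return integer matrix (SNP records x samples) of codes 0/1/2/NA,
#'   rownames = snpIds.
#' @export
setMethod("genoMatrix", "GenotypePanel", function(x) {
  g <- SummarizedExperiment::assay(x, "geno")
  rownames(g) <- snpIds(x)
  colnames(g) <- colnames(x)
  g
})

#' Does a panel carry sex/ancestry sample metadata?
#' @param panel a `GenotypePanel`.
#' @param what `"sex"`, `"ancestry"` or both.
#' @return logical.
#' @export
hasSampleInfo <- function(panel, what = c("sex", "ancestry")) {
  all(what %in% colnames(colData(panel)))
}

setMethod("show", "GenotypePanel", function(object) {
  nsite <- length(unique(mcols(rowRanges(object))$siteKey))
  cat(sprintf("GenotypePanel: %d SNP record(s) at %d site(s) x %d sample(s)\n",
              nrow(object), nsite, ncol(object)))
  meta <- intersect(c("sex", "ancestry"), colnames(colData(object)))
  cat(sprintf("  sample metadata: %s\n",
              if (length(meta)) paste(meta, collapse = ", ") else "none"))
})

#' Gene symbols of an ASE list
#' @param x an `AseGeneList`.
#' @return character vector of gene symbols in list order.
#' @export
setMethod("geneSymbols", "AseGeneList", function(x) x@genes)

setMethod("length", "AseGeneList", function(x) length(x@genes))

setMethod("show", "AseGeneList", function(object) {
  cat(sprintf("AseGeneList '%s': %d gene(s)", object@label, length(object)))
  aux <- c(if (!is.na(object@sex)) paste0("sex=", object@sex),
           if (!is.na(object@ancestry)) paste0("ancestry=", object@ancestry))
  if (length(aux)) cat(" [", paste(aux, collapse = ", "), "]", sep = "")
  cat("\n")
  if (length(object@removed))
    cat(sprintf("  %d gene(s) removed by sanitization\n", length(object@removed)))
})

#' Label of an ASE gene list
#' @param x an `AseGeneList`.
#' @return the label string.
#' @export
listLabel <- function(x) x@label

#' Candidate SNP ids of a CandidateSet
#' @param x a `CandidateSet`.
#' @return character vector of snpIds.
#' @export
setMethod("snpIds", "CandidateSet", function(x) x@snpIds)

#' Panel heterozygous genotyping frequency per candidate
#' @param x a `CandidateSet`.
#' @return named numeric vector.
#' @export
candidateFreq <- function(x) {
  stopifnot(is(x, "CandidateSet"))
  x@freq
}

#' Contributing genes per candidate SNP
#' @param x a `CandidateSet`.
#' @return named list mapping snpId to gene symbol(s).
#' @export
sourceGenes <- function(x) {
  stopifnot(is(x, "CandidateSet"))
  x@sourceGenes
}

setMethod("length", "CandidateSet", function(x) length(x@snpIds))

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet '%s': %d candidate SNP(s) from %d gene(s)\n",
              object@label, length(object),
              length(unique(unlist(object@sourceGenes)))))
  cat(sprintf("  filter: %s f in (%g, %g), f = 0 dropped\n",
              if (object@filterMode == "exclude-range") "exclude" else "keep",
              object@bounds[1], object@bounds[2]))
  aux <- c(if (!is.na(object@sex)) paste0("sex=", object@sex),
           if (!is.na(object@ancestry)) paste0("ancestry=", object@ancestry))
  if (length(aux)) cat("  auxiliary:", paste(aux, collapse = ", "), "\n")
})

#' Per-individual linking table
#' @param x a `LinkResult`.
#' @return a `DataFrame` with columns id, score, nMatched, rank, pi,
#'   ordered by rank.
#' @export
setMethod("linkTable", "LinkResult", function(x) x@table)

#' Best-matching id of a linking run
#' @param x a `LinkResult`.
#' @return the id ranked first.
#' @export
setMethod("bestMatch", "LinkResult", function(x) x@bestMatch)

#' Gap statistic (best / second-best score)
#' @param x a `LinkResult`.
#' @return the gap ratio.
#' @export
setMethod("gapStat", "LinkResult", function(x) x@gap)

#' Empirical p-value of the gap statistic
#' @param x a `LinkResult`.
#' @return p-value in (0, 1], or `NA` if no permutation null was run.
#' @export
setMethod("pGap", "LinkResult", function(x) x@pGap)

setMethod("show", "LinkResult", function(object) {
  axis <- if (!is.null(object@params$axis)) object@params$axis else "individuals"
  cat(sprintf("LinkResult over %d %s\n", nrow(object@table), axis))
  cat(sprintf("  best match: %s (L = %.3f bits, gap = %s, p_gap = %s)\n",
              object@bestMatch, object@table$score[1],
              format(object@gap, digits = 4),
              if (is.na(object@pGap)) "not assessed"
              else format(object@pGap, digits = 4)))
  if (object@uninformative)
    cat("  WARNING: uninformative run (all scores zero)\n")
})
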