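#' Heterozygous genotyping frequency of every panel SNP record
#'
#' For each SNP record (one per alternative allele), the fraction of panel
#' individuals carrying exactly one copy of that allele:
#' f = #individuals with code 1 / total #individuals. Missing calls count
#' in the denominator (they can never contribute evidence of
#' heterozygosity) but not in the numerator.
#'
#' @param panel a [GenotypePanel-class] with at least one sample.
#' @return named numeric vector of frequencies in \[0, 1\], names = snpIds.
#' @export
hetFrequencies <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  if (ncol(panel) == 0L) stop("panel has no samples", call. = FALSE)
  g <- genoMatrix(panel)
  rowSums(g == 1L, na.rm = TRUE) / ncol(g)
}

#' Frequency filter for candidate SNPs
#'
#' In the default `"exclude-range"` mode, SNPs whose heterozygous
#' genotyping frequency lies strictly inside `(lower, upper)` are removed
#' and the rest retained, so both rare (f <= lower) and very common
#' (f >= upper) heterozygous SNPs are kept; boundary values survive the
#' strict inequalities. SNPs with f = 0 are always removed: they can never
#' match any panel individual and their information weight is undefined.
#' `"keep-range"` inverts the rule and retains the interval instead.
#'
#' @param f named numeric vector of het frequencies (see
#'   [hetFrequencies()]).
#' @param lower,upper filter bounds, `0 <= lower < upper <= 1`.
#' @param mode `"exclude-range"` (default) or `"keep-range"`.
#' @return names of admissible SNPs (possibly empty, with a warning).
#' @export
frequencyFilter <- function(f, lower = 0.1, upper = 0.5,
                            mode = c("exclude-range", "keep-range")) {
  mode <- match.arg(mode)
  stopifnot(lower >= 0, upper <= 1, lower < upper)
  keep <- if (mode == "exclude-range")
    f > 0 & (f <= lower | f >= upper)
  else
    f > lower & f < upper
  out <- names(f)[keep]
  if (length(out) == 0L)
    warning("no SNPs are admissible under the current filter bounds")
  out
}

#' Compile the candidate heterozygous-SNP set for an ASE gene list
#'
#' For every listed gene found in the annotation index, collects all panel
#' SNP records whose position falls in any (merged) exon of the gene —
#' every alternative allele of a site is a separate candidate — then
#' applies the heterozygous-genotyping-frequency filter. The result is the
#' union over genes, deduplicated, with per-SNP provenance recording which
#' listed genes contributed it. Symbols absent from the index are dropped
#' with a warning; if none remain, or if filtering empties the set, the
#' call fails.
#'
#' @param geneList an [AseGeneList-class].
#' @param index an [ExonIndex-class].
#' @param panel a [GenotypePanel-class].
#' @param lower,upper,mode filter settings, see [frequencyFilter()].
#' @param freq optional precomputed [hetFrequencies()] of `panel`, to
#'   avoid recomputation across many lists.
#' @return a [CandidateSet-class]. Auxiliary features (sex/ancestry) known
#'   for the list's owner are carried over.
#' @export
compileCandidates <- function(geneList, index, panel,
                              lower = 0.1, upper = 0.5,
                              mode = c("exclude-range", "keep-range"),
                              freq = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(geneList, "AseGeneList"), is(index, "ExonIndex"),
            is(panel, "GenotypePanel"))
  genes <- geneSymbols(geneList)
  found <- genes[genes %in% geneNames(index)]
  absent <- setdiff(genes, found)
  if (length(absent))
    warning(length(absent), " gene symbol(s) not in the annotation; dropped: ",
            paste(head(absent, 5), collapse = ", "))
  if (length(found) == 0L)
    stop("no gene of the list is present in the annotation index",
         call. = FALSE)
  if (is.null(freq)) freq <- hetFrequencies(panel)
  exons <- index@exons[found]
  flat <- unlist(exons, use.names = FALSE)
  geneOf <- rep(names(exons), lengths(exons))
  hits <- findOverlaps(rowRanges(panel), flat, ignore.strand = TRUE)
  if (length(hits)) {
    hitSnp <- snpIds(panel)[S4Vectors::queryHits(hits)]
    hitGene <- geneOf[S4Vectors::subjectHits(hits)]
    srcAll <- lapply(split(hitGene, hitSnp), unique)
    ids <- names(srcAll)
  } else {
    srcAll <- list()
    ids <- character(0)
  }
  admissible <- frequencyFilter(freq[ids], lower = lower, upper = upper,
                                mode = mode)
  if (length(admissible) == 0L)
    stop("candidate set is empty after the frequency filter; ",
         "consider relaxing the bounds (lower=", lower, ", upper=", upper,
         ")", call. = FALSE)
  ## keep panel row order for reproducible output
  admissible <- admissible[order(match(admissible, snpIds(panel)))]
  new("CandidateSet",
      snpIds = admissible,
      freq = freq[admissible],
      sourceGenes = srcAll[admissible],
      sex = geneList@sex, ancestry = geneList@ancestry,
      bounds = c(lower, upper), filterMode = mode,
      label = listLabel(geneList))
}
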