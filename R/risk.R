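#' Gene prevalence and self-information across a cohort of ASE lists
#'
#' For every gene observed in any list: the number of lists containing it,
#' its prevalence p = n_lists / N_lists, its self-information -log2(p) in
#' bits (rarely-ASE genes are the most identifying), and its genomic span
#' when an annotation index is supplied (NA for genes absent from the
#' index).
#'
#' @param lists a non-empty list of [AseGeneList-class] objects.
#' @param index optional [ExonIndex-class] for gene lengths.
#' @return a [S4Vectors::DataFrame] with columns `gene`, `nLists`,
#'   `prevalence`, `selfInformation`, `geneLength`, sorted by decreasing
#'   `nLists` (ties by symbol).
#' @export
genePrevalence <- function(lists, index = NULL) {
  stopifnot(length(lists) >= 1L)
  allGenes <- unlist(lapply(lists, geneSymbols), use.names = FALSE)
  counts <- table(allGenes)
  gene <- names(counts)
  n <- as.integer(counts)
  p <- n / length(lists)
  len <- rep(NA_real_, length(gene))
  if (!is.null(index)) {
    known <- gene %in% geneNames(index)
    if (any(known)) len[known] <- geneSpan(index, gene[known])
  }
  ord <- order(-n, gene)
  DataFrame(gene = gene[ord], nLists = n[ord], prevalence = p[ord],
            selfInformation = -log2(p[ord]), geneLength = len[ord])
}

#' The k most widely shared ASE genes
#'
#' @param prev output of [genePrevalence()].
#' @param k number of genes (default 20, the conventional sanitization
#'   set size); if fewer genes are observed, all are returned with a
#'   warning.
#' @return character vector of gene symbols, most shared first, ties
#'   broken by symbol.
#' @export
topCommonGenes <- function(prev, k = 20) {
  stopifnot(k >= 1)
  if (nrow(prev) < k) {
    warning("only ", nrow(prev), " gene(s) observed; returning all")
    k <- nrow(prev)
  }
  ## prev is already sorted by decreasing nLists, ties by symbol
  head(prev$gene, k)
}

#' Sanitize an ASE gene list
#'
#' Removes either an explicit gene set or, in HLA mode, every symbol with
#' the `HLA-` prefix (the highly polymorphic HLA genes are ASE in most
#' individuals and carry little identifying information, so removing them
#' is the canonical first sanitization step). Removed symbols are retained
#' in the result's provenance. Emptying the list completely is an error —
#' there would be nothing left to link or to share.
#'
#' @param geneList an [AseGeneList-class].
#' @param remove character vector of symbols to drop (ignored in HLA
#'   mode).
#' @param mode `"set"` (drop `remove`) or `"hla"` (drop `HLA-*`).
#' @return the sanitized [AseGeneList-class], with dropped symbols
#'   appended to its `removed` provenance slot.
#' @export
sanitizeList <- function(geneList, remove = character(0),
                         mode = c("set", "hla")) {
  mode <- match.arg(mode)
  stopifnot(is(geneList, "AseGeneList"))
  genes <- geneSymbols(geneList)
  drop <- if (mode == "hla") startsWith(genes, "HLA-") else genes %in% remove
  if (all(drop))
    stop("sanitization would empty the gene list of '",
         listLabel(geneList), "'", call. = FALSE)
  out <- geneList
  out@genes <- genes[!drop]
  out@removed <- c(geneList@removed, genes[drop])
  validObject(out)
  out
}

#' Evaluate linking accuracy over a cohort with known identities
#'
#' Runs the scenario-1 attack for every gene list (whose label is taken as
#' its owner's true sample id), and summarizes: rank-1 accuracy; the top-k
#' accuracy curve (fraction of individuals whose true identity ranks in
#' the top k); when a permutation null is run, precision and
#' false-positive rate gated on gap significance (precision = correct
#' links among links with p_gap < alpha; FPR = significant incorrect links
#' among all incorrect links — both are approximations of
#' significance-gated error rates and are labelled as such); and
#' per-individual diagnostics (number of genes, length-weighted gene
#' count, number of candidate SNPs, rank of the true identity).
#'
#' @param lists list of [AseGeneList-class] objects; labels must be panel
#'   sample ids.
#' @param panel a [GenotypePanel-class].
#' @param index an [ExonIndex-class].
#' @param lower,upper,mode filter settings.
#' @param kMax largest k of the top-k curve (default 20, capped at panel
#'   size).
#' @param nPerm permutations per list for gap significance (0 = skip
#'   precision/FPR).
#' @param seed integer; per-list seeds are derived from it.
#' @param alpha significance threshold on p_gap (default 0.05).
#' @return list with elements `rank1Accuracy`, `topK` (data.frame k,
#'   accuracy), `precision`, `falsePositiveRate`, `alpha`,
#'   `diagnostics` (data.frame per individual), `nLists`.
#' @export
evaluateCohort <- function(lists, panel, index,
                           lower = 0.1, upper = 0.5,
                           mode = c("exclude-range", "keep-range"),
                           kMax = 20, nPerm = 0, seed = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  labels <- vapply(lists, listLabel, character(1))
  missing_ <- setdiff(labels, sampleIds(panel))
  if (length(missing_))
    stop("true identity absent from panel: ",
         paste(head(missing_, 5), collapse = ", "), call. = FALSE)
  kMax <- min(kMax, ncol(panel))
  freq <- hetFrequencies(panel)
  n <- length(lists)
  rankTrue <- integer(n); nCand <- integer(n); pG <- rep(NA_real_, n)
  nGenes <- integer(n); lenW <- numeric(n); gaps <- numeric(n)
  for (i in seq_len(n)) {
    can <- compileCandidates(lists[[i]], index, panel, lower = lower,
                             upper = upper, mode = mode, freq = freq)
    res <- rankIndividuals(can, panel, freq = freq)
    tb <- linkTable(res)
    rankTrue[i] <- tb$rank[tb$id == labels[i]]
    nCand[i] <- length(can)
    gaps[i] <- gapStat(res)
    gl <- geneSymbols(lists[[i]])
    nGenes[i] <- length(gl)
    known <- gl[gl %in% geneNames(index)]
    lenW[i] <- if (length(known)) sum(geneSpan(index, known)) else 0
    if (nPerm > 0) {
      s <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
      pG[i] <- gapSignificance(can, panel, nPerm = nPerm, seed = s,
                               freq = freq)$pGap
    }
  }
  correct <- rankTrue == 1L
  topK <- data.frame(k = seq_len(kMax),
                     accuracy = vapply(seq_len(kMax),
                                       function(k) mean(rankTrue <= k),
                                       numeric(1)))
  precision <- fpr <- NA_real_
  if (nPerm > 0) {
    sig <- pG < alpha
    precision <- if (any(sig)) mean(correct[sig]) else NA_real_
    fpr <- if (any(!correct)) mean(sig[!correct]) else NA_real_
  }
  list(rank1Accuracy = mean(correct),
       topK = topK,
       precision = precision,             # SI-approximation
       falsePositiveRate = fpr,           # SI-approximation
       alpha = alpha,
       diagnostics = data.frame(label = labels, nGenes = nGenes,
                                lengthWeightedGenes = lenW,
                                nCandidates = nCand, rankTrue = rankTrue,
                                gap = gaps, pGap = pG, correct = correct),
       nLists = n)
}
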