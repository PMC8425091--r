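#' Self-information weight of a SNP (bits)
#'
#' The information carried by observing a heterozygous match at a SNP with
#' panel heterozygous genotyping frequency f is its self-information
#' \eqn{-\log_2 f}: rare heterozygous SNPs are strongly identifying, a SNP
#' heterozygous in everyone (f = 1) carries no information. Frequencies of
#' zero have no defined weight (such SNPs are removed upstream by
#' [frequencyFilter()]).
#'
#' @param f numeric vector of frequencies in (0, 1\].
#' @return numeric vector of non-negative weights in bits.
#' @export
snpWeight <- function(f) {
  if (any(f <= 0 | f > 1))
    stop("frequencies must lie in (0, 1]", call. = FALSE)
  -log2(f)
}

## Core scorer: bits matched by every panel individual against a candidate
## set, including auxiliary features. Returns list(score, nMatched).
.scoreAll <- function(can, panel, freq = NULL) {
  idx <- match(snpIds(can), snpIds(panel))
  if (anyNA(idx))
    stop("candidate SNP(s) absent from the panel: ",
         paste(head(snpIds(can)[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  f <- if (is.null(freq)) candidateFreq(can) else freq[snpIds(can)]
  w <- snpWeight(f)
  het <- genoMatrix(panel)[idx, , drop = FALSE] == 1L
  het[is.na(het)] <- FALSE          # missing calls never match
  score <- as.vector(crossprod(het, w))
  nMatched <- as.vector(colSums(het))
  names(score) <- names(nMatched) <- sampleIds(panel)
  for (feat in c("sex", "ancestry")) {
    val <- slot(can, feat)
    if (is.na(val)) next
    if (!hasSampleInfo(panel, feat))
      stop("candidate set carries ", feat,
           " but the panel has no such metadata", call. = FALSE)
    cats <- colData(panel)[[feat]]
    fcat <- mean(cats == val)
    match_ <- cats == val
    if (fcat > 0) {
      score[match_] <- score[match_] + snpWeight(fcat)
      nMatched[match_] <- nMatched[match_] + 1L
    }
  }
  list(score = score, nMatched = nMatched)
}

#' Linking score of one panel individual against a candidate set
#'
#' L(i, can) is the sum, over the candidate SNPs at which individual i is
#' heterozygous for the candidate allele (code 1), of the SNPs'
#' self-information weights; candidates where the individual codes 0, 2 or
#' missing contribute nothing. Auxiliary features attached to the
#' candidate set contribute the self-information of their panel category
#' frequency when they match.
#'
#' @param can a [CandidateSet-class].
#' @param panel a [GenotypePanel-class].
#' @param sample one sample id (default: all samples).
#' @return named numeric vector of scores in bits.
#' @export
linkingScore <- function(can, panel, sample = NULL) {
  sc <- .scoreAll(can, panel)$score
  if (is.null(sample)) sc else {
    if (!all(sample %in% names(sc)))
      stop("unknown sample id(s): ",
           paste(setdiff(sample, names(sc)), collapse = ", "), call. = FALSE)
    sc[sample]
  }
}

## gap = best / second-best of a score vector
.gapOf <- function(score) {
  top <- sort(score, decreasing = TRUE)[1:2]
  if (top[1] == 0) 1
  else if (top[2] == 0) Inf
  else unname(top[1] / top[2])
}

#' Gap statistic of a linking run
#'
#' The ratio between the best and second-best linking scores. A large gap
#' means the best match stands out from the panel. Conventions: all-zero
#' scores give gap 1 (nothing stands out); a positive best score over a
#' zero runner-up gives `Inf`; tied leaders give 1.
#'
#' @param x a [LinkResult-class] or a numeric score vector of length >= 2.
#' @return the gap ratio (>= 1 whenever scores are non-negative).
#' @export
gapStatistic <- function(x) {
  score <- if (is(x, "LinkResult")) linkTable(x)$score else x
  if (length(score) < 2L)
    stop("gap requires at least two scored individuals", call. = FALSE)
  .gapOf(score)
}

#' Entropy-based matching probabilities
#'
#' Converts linking scores into a probability distribution over the panel:
#' \eqn{\pi(i) = c\,e^{L_i/\sigma}} with c normalizing to
#' \eqn{\sum_i \pi(i) = 1} and \eqn{\sigma} the (population) standard
#' deviation of the scores. Computed with max-shifted exponentials for
#' overflow safety; if all scores are equal (\eqn{\sigma = 0}) the
#' distribution is uniform. Ordering by \eqn{\pi} always equals ordering
#' by L, and \eqn{\pi} is invariant to shifting all scores by a constant.
#'
#' @param x a [LinkResult-class] or a numeric score vector of length >= 2.
#' @return numeric vector of probabilities summing to 1.
#' @export
entropyProbabilities <- function(x) {
  score <- if (is(x, "LinkResult")) {
    tb <- linkTable(x)
    setNames(tb$score, tb$id)
  } else x
  if (length(score) < 2L)
    stop("need at least two individuals", call. = FALSE)
  sigma <- sqrt(mean((score - mean(score))^2))
  if (sigma == 0) return(setNames(rep(1 / length(score), length(score)),
                                  names(score)))
  z <- score / sigma
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## assemble a LinkResult from a named score vector
.makeLinkResult <- function(score, nMatched, params = list()) {
  ids <- names(score)
  ord <- order(-score, ids)               # lexicographic tie-break
  pi <- entropyProbabilities(score)
  tb <- DataFrame(id = ids[ord],
                  score = unname(score[ord]),
                  nMatched = unname(nMatched[ord]),
                  rank = seq_along(ord),
                  pi = unname(pi[ord]))
  uninf <- all(score == 0)
  if (uninf)
    warning("uninformative linking run: all scores are zero")
  new("LinkResult", table = tb, gap = .gapOf(score), pGap = NA_real_,
      bestMatch = ids[ord][1], uninformative = uninf, params = params)
}

#' Rank panel individuals against a candidate set (scenario 1)
#'
#' Scores every genome in the panel with [linkingScore()], ranks in
#' decreasing order (ties broken by lexicographic sample id, so results
#' are deterministic), computes the gap statistic and the entropy-based
#' matching probabilities. The rank-1 individual is the inferred identity
#' of the gene list's owner.
#'
#' @param can a [CandidateSet-class].
#' @param panel a [GenotypePanel-class] with >= 2 samples.
#' @param freq optional precomputed [hetFrequencies()] of `panel`.
#' @return a [LinkResult-class].
#' @export
rankIndividuals <- function(can, panel, freq = NULL) {
  stopifnot(is(can, "CandidateSet"), is(panel, "GenotypePanel"))
  if (ncol(panel) < 2L)
    stop("ranking requires a panel of at least two individuals",
         call. = FALSE)
  sc <- .scoreAll(can, panel, freq)
  .makeLinkResult(sc$score, sc$nMatched,
                  params = list(axis = "individuals",
                                label = can@label,
                                nCandidates = length(can),
                                bounds = can@bounds,
                                filterMode = can@filterMode))
}

#' Permutation significance of the gap statistic
#'
#' Draws `nPerm` random candidate sets of the same size as the observed
#' one, uniformly without replacement from the filter-admissible panel
#' SNPs (genome-wide by default, or restricted to exonic SNPs with
#' `pool = "exonic"`), recomputes the gap for each, and reports the
#' add-one empirical p-value
#' \eqn{p = (1 + \#\{gap_{null} \ge gap_{obs}\}) / (1 + nPerm)}.
#' Auxiliary features of the observed set, if any, are attached unchanged
#' to every null set so that the null matches the observed scoring rule.
#'
#' @param can the observed [CandidateSet-class].
#' @param panel a [GenotypePanel-class].
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for reproducibility.
#' @param pool `"genome-wide"` (default) or `"exonic"`.
#' @param index an [ExonIndex-class], required for `pool = "exonic"`.
#' @param freq optional precomputed [hetFrequencies()].
#' @return list with elements `pGap`, `observedGap`, `nullGaps`, `nPerm`,
#'   `seed`.
#' @export
gapSignificance <- function(can, panel, nPerm = 1000, seed = NULL,
                            pool = c("genome-wide", "exonic"),
                            index = NULL, freq = NULL) {
  pool <- match.arg(pool)
  stopifnot(nPerm >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freq)) freq <- hetFrequencies(panel)
  admissible <- frequencyFilter(freq, lower = can@bounds[1],
                                upper = can@bounds[2], mode = can@filterMode)
  if (pool == "exonic") {
    if (is.null(index))
      stop("pool = 'exonic' requires an annotation index", call. = FALSE)
    flat <- unlist(index@exons, use.names = FALSE)
    hits <- findOverlaps(rowRanges(panel), flat, ignore.strand = TRUE)
    exonic <- unique(snpIds(panel)[S4Vectors::queryHits(hits)])
    admissible <- intersect(admissible, exonic)
  }
  k <- length(can)
  if (length(admissible) < k)
    stop("admissible SNP pool (", length(admissible),
         ") is smaller than the candidate set (", k, ")", call. = FALSE)
  obsGap <- .gapOf(.scoreAll(can, panel, freq)$score)
  ## precompute het matrix and weights over the pool once
  idx <- match(admissible, snpIds(panel))
  het <- genoMatrix(panel)[idx, , drop = FALSE] == 1L
  het[is.na(het)] <- FALSE
  w <- snpWeight(freq[admissible])
  auxScore <- numeric(ncol(panel))
  for (feat in c("sex", "ancestry")) {
    val <- slot(can, feat)
    if (is.na(val)) next
    cats <- colData(panel)[[feat]]
    fcat <- mean(cats == val)
    if (fcat > 0) auxScore[cats == val] <- auxScore[cats == val] + snpWeight(fcat)
  }
  nullGaps <- vapply(seq_len(nPerm), function(b) {
    draw <- sample.int(length(admissible), k)
    .gapOf(as.vector(crossprod(het[draw, , drop = FALSE], w[draw])) + auxScore)
  }, numeric(1))
  p <- (1 + sum(nullGaps >= obsGap)) / (1 + nPerm)
  list(pGap = p, observedGap = obsGap, nullGaps = nullGaps,
       nPerm = nPerm, seed = seed)
}

#' Attach a permutation p-value to a LinkResult
#'
#' Convenience wrapper running [gapSignificance()] and storing its
#' p-value in the result object.
#'
#' @inheritParams gapSignificance
#' @param result the [LinkResult-class] produced from `can` and `panel`.
#' @return the updated [LinkResult-class].
#' @export
addGapSignificance <- function(result, can, panel, nPerm = 1000, seed = NULL,
                               pool = c("genome-wide", "exonic"),
                               index = NULL, freq = NULL) {
  gs <- gapSignificance(can, panel, nPerm = nPerm, seed = seed,
                        pool = pool, index = index, freq = freq)
  result@pGap <- gs$pGap
  result@params$nPerm <- nPerm
  result@params$seed <- seed
  validObject(result)
  result
}

#' Add auxiliary sex/ancestry features to a candidate set
#'
#' Each feature becomes one extra matchable item: a panel individual whose
#' metadata matches gains the self-information of the category's panel
#' frequency (e.g. 1 bit for a sex present in half the panel), a mismatch
#' contributes nothing. The panel must carry the corresponding metadata at
#' scoring time.
#'
#' @param can a [CandidateSet-class].
#' @param sex `"M"`, `"F"` or `NA` to leave unset.
#' @param ancestry one of EUR/AFR/AMR/EAS/SAS, or `NA`.
#' @param panel optional [GenotypePanel-class]; when supplied, the
#'   presence of the needed metadata is checked immediately.
#' @return the updated [CandidateSet-class].
#' @export
augmentAuxiliary <- function(can, sex = NA_character_,
                             ancestry = NA_character_, panel = NULL) {
  stopifnot(is(can, "CandidateSet"))
  if (!is.na(sex)) {
    if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'", call. = FALSE)
    can@sex <- sex
  }
  if (!is.na(ancestry)) {
    if (!ancestry %in% ANCESTRIES)
      stop("ancestry must be one of ", paste(ANCESTRIES, collapse = "/"),
           call. = FALSE)
    can@ancestry <- ancestry
  }
  if (!is.null(panel)) {
    for (feat in c("sex", "ancestry"))
      if (!is.na(slot(can, feat)) && !hasSampleInfo(panel, feat))
        stop("panel carries no ", feat, " metadata", call. = FALSE)
  }
  validObject(can)
  can
}

#' Link a known genome to anonymized ASE gene lists (scenario 2)
#'
#' The mirror attack: given the genotypes of a known individual and a
#' collection of anonymized gene lists (each possibly attached to a
#' private phenotype via its label), compile every list into a candidate
#' set, score the known genome against each, and rank the lists. The
#' rank-1 list's label is the inferred (phenotype-bearing) record of the
#' known individual. The score of a (genome, list) pair is identical to
#' the scenario-1 score of that pair. Lists that fail to compile (no gene
#' in the annotation, or empty after filtering) score 0 with a warning.
#' Gap significance, when requested, permutes random candidate sets of
#' each list's size over the list axis.
#'
#' @param sample the known individual's sample id in `panel`.
#' @param lists a list of [AseGeneList-class] objects (>= 2), labels
#'   unique.
#' @param index an [ExonIndex-class].
#' @param panel the [GenotypePanel-class] holding the known genome.
#' @param lower,upper,mode filter settings, see [frequencyFilter()].
#' @param nPerm permutations for gap significance (0 = skip).
#' @param seed integer seed for the permutation null.
#' @return a [LinkResult-class] over lists (ids = list labels).
#' @export
linkGenomeToLists <- function(sample, lists, index, panel,
                              lower = 0.1, upper = 0.5,
                              mode = c("exclude-range", "keep-range"),
                              nPerm = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (length(lists) < 2L)
    stop("need at least two anonymized lists", call. = FALSE)
  if (!sample %in% sampleIds(panel))
    stop("sample '", sample, "' is not in the panel", call. = FALSE)
  labels <- vapply(lists, listLabel, character(1))
  if (anyDuplicated(labels))
    stop("list labels must be unique", call. = FALSE)
  freq <- hetFrequencies(panel)
  cans <- vector("list", length(lists))
  score <- nMatched <- setNames(numeric(length(lists)), labels)
  for (i in seq_along(lists)) {
    cans[i] <- list(tryCatch(
      compileCandidates(lists[[i]], index, panel, lower = lower,
                        upper = upper, mode = mode, freq = freq),
      error = function(e) {
        warning("list '", labels[i], "' could not be compiled (scored 0): ",
                conditionMessage(e))
        NULL
      }))
    if (!is.null(cans[[i]])) {
      sc <- .scoreAll(cans[[i]], panel, freq)
      score[i] <- sc$score[sample]
      nMatched[i] <- sc$nMatched[sample]
    }
  }
  res <- .makeLinkResult(score, nMatched,
                         params = list(axis = "lists", sample = sample,
                                       bounds = c(lower, upper),
                                       filterMode = mode))
  if (nPerm > 0) {
    if (!is.null(seed)) set.seed(seed)
    admissible <- frequencyFilter(freq, lower, upper, mode)
    idx <- match(admissible, snpIds(panel))
    hetRow <- genoMatrix(panel)[idx, sample] == 1L
    hetRow[is.na(hetRow)] <- FALSE
    w <- snpWeight(freq[admissible])
    sizes <- vapply(cans, function(x) if (is.null(x)) 0L else length(x),
                    integer(1))
    if (max(sizes) > length(admissible))
      stop("admissible pool smaller than the largest candidate set",
           call. = FALSE)
    obsGap <- .gapOf(score)
    nullGaps <- vapply(seq_len(nPerm), function(b) {
      nullScore <- vapply(sizes, function(k) {
        if (k == 0L) return(0)
        draw <- sample.int(length(admissible), k)
        sum(w[draw][hetRow[draw]])
      }, numeric(1))
      .gapOf(nullScore)
    }, numeric(1))
    res@pGap <- (1 + sum(nullGaps >= obsGap)) / (1 + nPerm)
    res@params$nPerm <- nPerm
    res@params$seed <- seed
  }
  res
}
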