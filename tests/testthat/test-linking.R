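test_that("SNP weights are self-information in bits", {
  expect_equal(snpWeight(0.5), 1.0)
  expect_equal(snpWeight(1.0), 0.0)
  expect_equal(snpWeight(0.25), 2.0)
  expect_error(snpWeight(0), "\\(0, 1]")
  expect_error(snpWeight(-0.1))
})

test_that("linking scores sum matched weights and ignore 0/2/missing", {
  ## candidates: A (f = 0.5 -> 1 bit), B (f = 0.25 -> 2 bits)
  geno <- rbind(c(1L, 1L, 0L, 2L),
                c(1L, 0L, NA, 1L))
  panel <- makeTestPanel(geno)
  freq <- setNames(c(0.5, 0.25), snpIds(panel))
  can <- makeCandidateSet(snpIds(panel), freq)
  L <- linkingScore(can, panel)
  expect_equal(unname(L), c(3, 1, 0, 2))
  expect_equal(unname(linkingScore(can, panel, "S03")), 0)
})

test_that("scores equal an independent per-SNP loop oracle", {
  co <- smallCohort()
  freq <- hetFrequencies(co$panel)
  can <- compileCandidates(co$lists[[3]], co$index, co$panel, freq = freq)
  L <- linkingScore(can, co$panel)
  g <- genoMatrix(co$panel)
  for (id in sample(sampleIds(co$panel), 8)) {
    acc <- 0
    for (s in snpIds(can))
      if (!is.na(g[s, id]) && g[s, id] == 1L) acc <- acc - log2(freq[[s]])
    expect_equal(unname(L[id]), acc, tolerance = 1e-12)
  }
})

test_that("score is additive over any partition of the candidate set", {
  co <- smallCohort()
  freq <- hetFrequencies(co$panel)
  can <- compileCandidates(co$lists[[7]], co$index, co$panel, freq = freq)
  ids <- snpIds(can)
  cut <- sample(length(ids), 1)
  part1 <- makeCandidateSet(ids[seq_len(cut)], freq)
  part2 <- if (cut < length(ids))
    makeCandidateSet(ids[(cut + 1):length(ids)], freq) else NULL
  total <- linkingScore(can, co$panel)
  split_ <- linkingScore(part1, co$panel) +
    if (is.null(part2)) 0 else linkingScore(part2, co$panel)
  expect_equal(unname(total), unname(split_), tolerance = 1e-12)
})

test_that("ranking is decreasing with lexicographic tie-breaks", {
  geno <- rbind(c(1L, 1L, 1L),
                c(1L, 0L, 0L))
  colnames(geno) <- c("S1", "S3", "S2")
  panel <- makeTestPanel(geno)
  can <- makeCandidateSet(snpIds(panel),
                          setNames(c(0.5, 0.5), snpIds(panel)))
  res <- rankIndividuals(can, panel)
  tb <- linkTable(res)
  expect_equal(tb$id, c("S1", "S2", "S3"))  # S2/S3 tie at 1 bit
  expect_equal(tb$rank, 1:3)
  expect_equal(bestMatch(res), "S1")
})

test_that("a single discriminating SNP ranks its carrier first", {
  geno <- matrix(c(0L, 1L, 0L, 0L), 1, 4)
  panel <- makeTestPanel(geno)
  can <- makeCandidateSet(snpIds(panel), setNames(0.25, snpIds(panel)))
  expect_equal(bestMatch(rankIndividuals(can, panel)), "S02")
})

test_that("all-zero scores flag the run as uninformative", {
  geno <- matrix(c(0L, 0L, 2L, 0L), 1, 4)
  panel <- makeTestPanel(geno)
  can <- makeCandidateSet(snpIds(panel), setNames(0.25, snpIds(panel)))
  expect_warning(res <- rankIndividuals(can, panel), "uninformative")
  expect_true(res@uninformative)
  expect_equal(gapStat(res), 1)
})

test_that("gap statistic handles ties, zeros and dominance", {
  expect_equal(gapStatistic(c(6, 3, 1)), 2.0)
  expect_equal(gapStatistic(c(4, 4, 1)), 1.0)
  expect_equal(gapStatistic(c(5, 0, 0)), Inf)
  expect_equal(gapStatistic(c(0, 0, 0)), 1)
  expect_error(gapStatistic(3), "at least two")
})

test_that("entropy probabilities normalize, preserve order, and shift-invariance holds", {
  ## closed form: scores (2, 0), population sd = 1
  pi <- entropyProbabilities(c(a = 2, b = 0))
  expect_equal(unname(pi), c(exp(2) / (exp(2) + 1), 1 / (exp(2) + 1)),
               tolerance = 1e-12)
  ## equal scores -> uniform
  expect_equal(unname(entropyProbabilities(c(3, 3, 3))), rep(1 / 3, 3))
  set.seed(55)
  for (rep in 1:20) {
    L <- runif(sample(3:50, 1), 0, 40)
    pi <- entropyProbabilities(L)
    expect_equal(sum(pi), 1, tolerance = 1e-9)
    expect_equal(which.max(pi), which.max(L))
    expect_equal(order(pi), order(L))
    expect_equal(entropyProbabilities(L + 7.3), pi, tolerance = 1e-9)
  }
  ## overflow safety for huge scores
  expect_equal(sum(entropyProbabilities(c(1e6, 0, 12))), 1)
})

test_that("LinkResult pi column matches entropy probabilities of the scores", {
  co <- smallCohort()
  can <- compileCandidates(co$lists[[2]], co$index, co$panel)
  res <- rankIndividuals(can, co$panel)
  tb <- linkTable(res)
  expect_equal(sum(tb$pi), 1, tolerance = 1e-9)
  expect_equal(tb$id[which.max(tb$pi)], tb$id[which.max(tb$score)])
  expect_true(all(diff(tb$pi) <= 1e-12))  # ordered by rank => non-increasing
})

test_that("permutation p honours the add-one estimator bounds", {
  co <- smallCohort()
  can <- compileCandidates(co$lists[[4]], co$index, co$panel)
  gs <- gapSignificance(can, co$panel, nPerm = 50, seed = 9)
  expect_gte(gs$pGap, 1 / 51)
  expect_lte(gs$pGap, 1)
  ## reproducibility under the same seed
  gs2 <- gapSignificance(can, co$panel, nPerm = 50, seed = 9)
  expect_identical(gs$nullGaps, gs2$nullGaps)
  ## nPerm = 1 with a null gap at least as large gives p = 1
  fake <- makeCandidateSet(snpIds(can)[1], hetFrequencies(co$panel))
  one <- gapSignificance(fake, co$panel, nPerm = 1, seed = 2)
  expect_true(one$pGap %in% c(0.5, 1.0))
  if (one$nullGaps >= one$observedGap) expect_equal(one$pGap, 1.0)
})

test_that("the pool must be at least as large as the candidate set", {
  geno <- matrix(c(1L, 0L, 1L, 1L), 2, 2,
                 dimnames = list(NULL, c("S1", "S2")))
  panel <- makeTestPanel(geno)
  f <- hetFrequencies(panel)
  can <- makeCandidateSet(snpIds(panel), f, lower = 1e-6, upper = 0.5)
  ## with bounds (1e-6, 0.5): f = 0.5 and 1.0 both retained, but shrink the
  ## pool by keep-range so it is smaller than the 2-SNP candidate set
  can@filterMode <- "keep-range"
  expect_error(suppressWarnings(
    gapSignificance(can, panel, nPerm = 5, seed = 1)),
    "smaller than the candidate set")
})

test_that("matching auxiliary features add category self-information", {
  geno <- matrix(c(1L, 1L, 1L, 1L), 1, 4,
                 dimnames = list(NULL, sprintf("S%d", 1:4)))
  md <- data.frame(sample = sprintf("S%d", 1:4),
                   sex = c("F", "F", "M", "M"),
                   ancestry = c("EUR", "AFR", "AFR", "AFR"))
  panel <- makeTestPanel(geno, metadata = md)
  base <- makeCandidateSet(snpIds(panel), setNames(1.0, snpIds(panel)))
  L0 <- linkingScore(base, panel)
  ## sex = F in a half-female panel: matching females gain exactly 1 bit
  canF <- augmentAuxiliary(base, sex = "F", panel = panel)
  LF <- linkingScore(canF, panel)
  expect_equal(unname(LF - L0), c(1, 1, 0, 0))
  ## ancestry covering 25% of the panel gains -log2(0.25) = 2 bits
  canE <- augmentAuxiliary(base, ancestry = "EUR", panel = panel)
  LE <- linkingScore(canE, panel)
  expect_equal(unname(LE - L0), c(2, 0, 0, 0))
  ## both at once stack additively
  canB <- augmentAuxiliary(base, sex = "F", ancestry = "EUR", panel = panel)
  expect_equal(unname(linkingScore(canB, panel) - L0), c(3, 1, 0, 0))
  ## no auxiliary features: identity
  expect_identical(linkingScore(base, panel), L0)
  ## panel without metadata is a hard error
  bare <- makeTestPanel(geno)
  expect_error(linkingScore(canF, bare), "no such metadata")
  expect_error(augmentAuxiliary(base, sex = "X"), "sex")
  expect_error(augmentAuxiliary(base, ancestry = "OCE"), "ancestry")
})

test_that("matching auxiliary never lowers, mismatching never changes scores", {
  co <- smallCohort()
  can <- compileCandidates(co$lists[[6]], co$index, co$panel)
  L0 <- linkingScore(can, co$panel)
  for (sx in c("M", "F")) {
    L1 <- linkingScore(augmentAuxiliary(can, sex = sx), co$panel)
    match_ <- colData(co$panel)$sex == sx
    expect_true(all(L1[match_] >= L0[match_]))
    expect_equal(L1[!match_], L0[!match_])
  }
})

test_that("a known genome links back to its own anonymized list (scenario 2)", {
  co <- smallCohort()
  target <- "IND010"
  pool <- co$lists[5:15]
  res <- linkGenomeToLists(target, pool, co$index, co$panel,
                           nPerm = 30, seed = 2)
  expect_equal(bestMatch(res), target)
  expect_false(is.na(pGap(res)))
  ## scenario-2 scores equal scenario-1 scores for the same (genome, list)
  freq <- hetFrequencies(co$panel)
  tb <- linkTable(res)
  for (l in pool[1:4]) {
    can <- compileCandidates(l, co$index, co$panel, freq = freq)
    expect_equal(tb$score[tb$id == listLabel(l)],
                 unname(linkingScore(can, co$panel, target)),
                 tolerance = 1e-12)
  }
})

test_that("scenario 2 scores uncompilable lists as zero with a warning", {
  co <- smallCohort()
  bogus <- AseGeneList(c("NOT_A_GENE"), label = "bogus")
  withCallingHandlers(
    expect_warning(
      res <- linkGenomeToLists("IND001", c(co$lists[1:3], list(bogus)),
                               co$index, co$panel),
      "could not be compiled"),
    warning = function(w) {
      if (grepl("not in the annotation", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tb <- linkTable(res)
  expect_equal(tb$score[tb$id == "bogus"], 0)
})
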