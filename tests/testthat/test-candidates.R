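test_that("het frequency counts heterozygotes over all individuals", {
  geno <- rbind(c(1L, 0L, 1L, 2L),
                c(0L, 0L, 0L, 0L),
                c(1L, NA, 1L, 1L))
  panel <- makeTestPanel(geno)
  f <- hetFrequencies(panel)
  expect_equal(unname(f), c(0.5, 0, 0.75))  # NA stays in the denominator
})

test_that("het frequencies equal a brute-force recount on a cohort", {
  co <- smallCohort()
  f <- hetFrequencies(co$panel)
  g <- genoMatrix(co$panel)
  for (i in sample(nrow(g), 50)) {
    count <- 0L
    for (j in seq_len(ncol(g)))
      if (!is.na(g[i, j]) && g[i, j] == 1L) count <- count + 1L
    expect_equal(unname(f[i]), count / ncol(g))
  }
})

test_that("the frequency filter excludes the open mid-range and always drops f = 0", {
  f <- setNames(c(0, 0.05, 0.1, 0.3, 0.5, 0.9),
                paste0("s", 1:6))
  expect_setequal(frequencyFilter(f), c("s2", "s3", "s5", "s6"))
  ## boundaries survive the strict inequalities
  expect_true("s3" %in% frequencyFilter(f))       # f = 0.1 retained
  expect_false("s4" %in% frequencyFilter(f))      # f = 0.3 removed
  ## inverted mode keeps the interval but still drops f = 0
  expect_setequal(frequencyFilter(f, mode = "keep-range"), "s4")
  expect_warning(frequencyFilter(setNames(0.3, "x")), "no SNPs")
  expect_error(frequencyFilter(f, lower = 0.5, upper = 0.1))
})

test_that("candidates are exonic, filtered, and carry gene provenance", {
  ## gene exon [100,200]; SNPs at 150 (rare) and 160 (mid-range) and 500 (outside)
  geno <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),   # f = 0.05... n=10 -> 0.1
                c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),   # f = 0.3
                c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))   # f = 0.5, not exonic
  panel <- makeTestPanel(geno, pos = c(150L, 160L, 500L))
  idx <- makeTestIndex("G1", 100, 200)
  can <- compileCandidates(AseGeneList("G1"), idx, panel)
  expect_equal(snpIds(can), "chrT:150:A:G")
  expect_equal(sourceGenes(can)[["chrT:150:A:G"]], "G1")
  expect_equal(unname(candidateFreq(can)), 0.1)
})

test_that("a SNP shared by two genes appears once with both sources", {
  geno <- matrix(c(1L, 1L, 0L, 0L), 1, 4)
  panel <- makeTestPanel(geno, pos = 150L)
  idx <- makeTestIndex(c("G1", "G2"), c(100, 140), c(200, 260))
  can <- compileCandidates(AseGeneList(c("G1", "G2")), idx, panel)
  expect_length(can, 1)
  expect_setequal(sourceGenes(can)[[1]], c("G1", "G2"))
})

test_that("unknown symbols warn and a fully unknown list errors", {
  panel <- makeTestPanel(matrix(c(1L, 1L, 0L, 0L), 1, 4), pos = 150L)
  idx <- makeTestIndex("G1", 100, 200)
  expect_warning(
    can <- compileCandidates(AseGeneList(c("G1", "NOPE")), idx, panel),
    "not in the annotation")
  expect_length(can, 1)
  expect_error(
    suppressWarnings(compileCandidates(AseGeneList("NOPE"), idx, panel)),
    "no gene of the list")
})

test_that("an all-filtered list fails with a bounds suggestion", {
  geno <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 1, 10)  # f = 0.3
  panel <- makeTestPanel(geno, pos = 150L)
  idx <- makeTestIndex("G1", 100, 200)
  expect_error(suppressWarnings(compileCandidates(AseGeneList("G1"), idx,
                                                  panel)),
               "relaxing the bounds")
})

test_that("adding a gene never shrinks the candidate set (monotonicity)", {
  co <- smallCohort()
  freq <- hetFrequencies(co$panel)
  genes <- geneSymbols(co$lists[[1]])
  prev <- character(0)
  for (k in c(2, 5, 10)) {
    can <- compileCandidates(AseGeneList(genes[seq_len(k)]), co$index,
                             co$panel, freq = freq)
    expect_true(all(prev %in% snpIds(can)))
    prev <- snpIds(can)
  }
})

test_that("indexed overlap+filter equals the double-loop oracle on random instances", {
  set.seed(88)
  for (rep in 1:10) {
    nG <- sample(3:8, 1); nS <- sample(20:60, 1); nI <- sample(4:10, 1)
    starts <- sort(sample.int(5000, nG)) * 2
    idx <- makeTestIndex(sprintf("G%d", seq_len(nG)),
                         starts, starts + sample(50:300, nG, replace = TRUE))
    geno <- matrix(sample(c(0L, 1L, 2L, NA), nS * nI, replace = TRUE,
                          prob = c(0.5, 0.3, 0.1, 0.1)), nS, nI)
    panel <- makeTestPanel(geno, pos = sort(sample.int(11000, nS)))
    genes <- sprintf("G%d", sample(nG, sample(2:nG, 1)))
    expected <- oracleCandidates(genes, idx, panel)
    got <- tryCatch(
      sort(snpIds(suppressWarnings(
        compileCandidates(AseGeneList(genes), idx, panel)))),
      error = function(e) character(0))
    expect_identical(got, expected)
  }
})

test_that("every compiled candidate satisfies the retained-region predicate", {
  co <- smallCohort()
  freq <- hetFrequencies(co$panel)
  for (j in 1:5) {
    can <- compileCandidates(co$lists[[j]], co$index, co$panel, freq = freq)
    f <- candidateFreq(can)
    expect_true(all(f > 0 & (f <= 0.1 | f >= 0.5)))
  }
})
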