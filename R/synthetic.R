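#' Configuration for a synthetic ASE cohort
#'
#' Describes a self-contained cohort — diploid genotype panel, gene
#' annotation, sample metadata and per-individual ASE gene lists — built
#' around the structural property the linkage attack exploits: every gene
#' on an individual's ASE list carries at least one exonic SNP at which
#' that individual is heterozygous.
#'
#' The default allele-frequency spectrum draws each SNP's heterozygosity
#' probability from a mixture of a rare component (`0.1 * Beta(2, 3)`,
#' support \[0, 0.1\]) and a common component (`0.5 + 0.5 * Beta(2, 2)`,
#' support \[0.5, 1\]), so the default frequency filter (exclude
#' 0.1 < f < 0.5) retains almost all SNPs. The rare component dominates
#' (95%) so that gene eligibility — carrying at least one exonic het SNP —
#' is a genuinely individual-specific event rather than a property shared
#' by the whole panel; see the package vignette for the design rationale.
#'
#' @param nIndividuals panel size (default 200).
#' @param nGenes number of genes (default 300).
#' @param nSnps number of SNP sites (default 5000), placed uniformly
#'   inside and outside exons.
#' @param genesPerList ASE list size per individual (default 30).
#' @param exonsPerGene exons per gene (default 3).
#' @param exonLengthRange,intronLengthRange,intergenicRange bp ranges for
#'   the gene geometry (uniform draws).
#' @param rareWeight mixture weight of the rare frequency component
#'   (default 0.95).
#' @param rareShape,commonShape Beta shape parameters of the two
#'   components.
#' @param multiAllelicFrac fraction of sites emitted with two alternative
#'   alleles, to exercise ALT expansion (default 0.03).
#' @param homAltFactor hom-alt probability is `homAltFactor * f^2`
#'   (roughly Hardy-Weinberg for small f), capped at `1 - f`.
#' @param sexRatio fraction of males; counts are deterministic
#'   (`floor(n * sexRatio)` males), assignment shuffled.
#' @param ancestryProps named proportions over EUR/AFR/AMR/EAS/SAS,
#'   summing to 1.
#' @param chromosome chromosome name (default `"chrS"`).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param maxRetries per-individual genotype resampling attempts when an
#'   individual has fewer eligible genes than `genesPerList`.
#' @return a `CohortConfig` (validated list).
#' @export
cohortConfig <- function(nIndividuals = 200, nGenes = 300, nSnps = 5000,
                         genesPerList = 30, exonsPerGene = 3,
                         exonLengthRange = c(150, 400),
                         intronLengthRange = c(500, 1500),
                         intergenicRange = c(1000, 3000),
                         rareWeight = 0.95,
                         rareShape = c(2, 3), commonShape = c(2, 2),
                         multiAllelicFrac = 0.03, homAltFactor = 0.25,
                         sexRatio = 0.5,
                         ancestryProps = c(EUR = 0.5, AFR = 0.15, AMR = 0.1,
                                           EAS = 0.15, SAS = 0.1),
                         chromosome = "chrS", seed = 7, maxRetries = 20) {
  cfg <- list(nIndividuals = nIndividuals, nGenes = nGenes, nSnps = nSnps,
              genesPerList = genesPerList, exonsPerGene = exonsPerGene,
              exonLengthRange = exonLengthRange,
              intronLengthRange = intronLengthRange,
              intergenicRange = intergenicRange,
              rareWeight = rareWeight, rareShape = rareShape,
              commonShape = commonShape,
              multiAllelicFrac = multiAllelicFrac,
              homAltFactor = homAltFactor, sexRatio = sexRatio,
              ancestryProps = ancestryProps, chromosome = chromosome,
              seed = seed, maxRetries = maxRetries)
  with(cfg, {
    stopifnot(nIndividuals >= 2, nGenes >= 1, nSnps >= 1, genesPerList >= 1,
              exonsPerGene >= 1, rareWeight >= 0, rareWeight <= 1,
              multiAllelicFrac >= 0, multiAllelicFrac < 1,
              sexRatio >= 0, sexRatio <= 1,
              genesPerList <= nGenes)
    if (!setequal(names(ancestryProps), ANCESTRIES) ||
        abs(sum(ancestryProps) - 1) > 1e-8)
      stop("ancestryProps must be named EUR/AFR/AMR/EAS/SAS and sum to 1",
           call. = FALSE)
  })
  structure(cfg, class = "CohortConfig")
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf(paste0("CohortConfig: %d individuals, %d genes, %d SNP sites, ",
                     "%d genes/list, seed %d\n"),
              x$nIndividuals, x$nGenes, x$nSnps, x$genesPerList, x$seed))
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

## deterministic category assignment: exact counts, shuffled order
.assignCategories <- function(n, props) {
  counts <- floor(n * props)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * props - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(props), counts))
}

#' Generate a synthetic ASE cohort
#'
#' Builds gene models on one synthetic chromosome, places SNP sites
#' uniformly along it, draws per-SNP heterozygosity probabilities from the
#' configured spectrum, samples diploid genotypes independently across
#' SNPs and individuals (no linkage disequilibrium), and constructs each
#' individual's ASE gene list by sampling uniformly from that individual's
#' *eligible* genes — those containing at least one exonic SNP at which
#' the individual is heterozygous. This is the structural constraint the
#' linkage attack exploits. A configured fraction of sites carries two
#' alternative alleles (both from the rare component, genotypes drawn per
#' haplotype so alt copies sum to at most 2).
#'
#' If an individual has fewer eligible genes than `genesPerList`, its
#' genotypes are resampled up to `maxRetries` times before failing.
#'
#' @param config a [cohortConfig()].
#' @param dir optional output directory; when supplied, writes
#'   `cohort.vcf`, `genes.gtf`, `metadata.tsv`, one gene list per
#'   individual under `lists/`, and `truth.json`.
#' @return (invisibly when `dir` is given) a list with elements `panel`
#'   ([GenotypePanel-class], metadata attached), `index`
#'   ([ExonIndex-class]), `lists` (list of [AseGeneList-class], labelled
#'   by owner sample id), `truth` (owners, per-individual eligible genes
#'   and het SNP ids, per-gene exonic SNP ids, config) and `files` (paths,
#'   or NULL).
#' @export
generateCohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$nIndividuals
  ## --- gene models on one chromosome ---------------------------------
  geneNamesV <- sprintf("GENE%04d", seq_len(config$nGenes))
  exonStart <- exonEnd <- vector("list", config$nGenes)
  cursor <- 1
  for (g in seq_len(config$nGenes)) {
    s <- e <- integer(config$exonsPerGene)
    for (k in seq_len(config$exonsPerGene)) {
      len <- round(runif(1, config$exonLengthRange[1],
                         config$exonLengthRange[2]))
      s[k] <- cursor; e[k] <- cursor + len - 1
      cursor <- e[k] + 1 +
        round(runif(1, config$intronLengthRange[1],
                    config$intronLengthRange[2]))
    }
    exonStart[[g]] <- s; exonEnd[[g]] <- e
    cursor <- cursor +
      round(runif(1, config$intergenicRange[1], config$intergenicRange[2]))
  }
  chromLen <- cursor
  geneStrand <- setNames(rep(c("+", "-"), length.out = config$nGenes),
                         geneNamesV)
  exonsGRL <- GRangesList(lapply(seq_len(config$nGenes), function(g)
    GRanges(config$chromosome,
            IRanges(exonStart[[g]], exonEnd[[g]]))))
  names(exonsGRL) <- geneNamesV
  index <- new("ExonIndex", exons = reduce(exonsGRL),
               geneStrand = geneStrand)
  ## --- SNP sites ------------------------------------------------------
  sitePos <- sort(sample.int(chromLen, config$nSnps))
  siteRef <- sample(.BASES, config$nSnps, replace = TRUE)
  nMulti <- floor(config$multiAllelicFrac * config$nSnps)
  isMulti <- rep(FALSE, config$nSnps)
  if (nMulti > 0) isMulti[sample.int(config$nSnps, nMulti)] <- TRUE
  drawF <- function(m, forceRare = FALSE) {
    rare <- if (forceRare) rep(TRUE, m) else runif(m) < config$rareWeight
    ifelse(rare,
           0.1 * rbeta(m, config$rareShape[1], config$rareShape[2]),
           0.5 + 0.5 * rbeta(m, config$commonShape[1], config$commonShape[2]))
  }
  altOf <- function(refBase, k) sample(setdiff(.BASES, refBase), k)
  ## expanded records: one per (site, alt)
  recSite <- rep(seq_len(config$nSnps), ifelse(isMulti, 2L, 1L))
  nRec <- length(recSite)
  recOfSiteFirst <- match(seq_len(config$nSnps), recSite)
  recAlt <- character(nRec)
  for (s in which(!isMulti))
    recAlt[recOfSiteFirst[s]] <- altOf(siteRef[s], 1)
  for (s in which(isMulti))
    recAlt[recOfSiteFirst[s] + 0:1] <- altOf(siteRef[s], 2)
  recF <- numeric(nRec)
  biRec <- recSite %in% which(!isMulti)
  recF[biRec] <- drawF(sum(biRec))
  recF[!biRec] <- drawF(sum(!biRec), forceRare = TRUE)
  ## --- exonic record indices per gene ---------------------------------
  recGR <- GRanges(config$chromosome, IRanges(sitePos[recSite], width = 1))
  flat <- unlist(index@exons, use.names = FALSE)
  geneOf <- rep(names(index@exons), lengths(index@exons))
  hits <- findOverlaps(recGR, flat)
  geneRecs <- lapply(
    split(S4Vectors::queryHits(hits),
          factor(geneOf[S4Vectors::subjectHits(hits)], levels = geneNamesV)),
    unique)
  ## --- genotypes with the eligibility constraint ----------------------
  multiSites <- which(isMulti)
  sampleGenotypes <- function() {
    codes <- integer(nRec)
    bi <- which(biRec)
    fB <- recF[bi]
    p2 <- pmin(config$homAltFactor * fB^2, 1 - fB)
    u <- runif(length(bi))
    codes[bi] <- ifelse(u < fB, 1L, ifelse(u < fB + p2, 2L, 0L))
    for (s in multiSites) {
      r1 <- recOfSiteFirst[s]; r2 <- r1 + 1L
      q1 <- recF[r1] / 2; q2 <- recF[r2] / 2
      h <- findInterval(runif(2), c(q1, q1 + q2))  # 0 = alt1, 1 = alt2, 2 = ref
      codes[r1] <- sum(h == 0L); codes[r2] <- sum(h == 1L)
    }
    codes
  }
  geno <- matrix(0L, nRec, n)
  sampleIdsV <- sprintf("IND%03d", seq_len(n))
  colnames(geno) <- sampleIdsV
  eligible <- vector("list", n)
  for (j in seq_len(n)) {
    for (try in seq_len(config$maxRetries + 1L)) {
      codes <- sampleGenotypes()
      elig <- names(geneRecs)[vapply(geneRecs, function(r)
        any(codes[r] == 1L), TRUE)]
      if (length(elig) >= config$genesPerList) break
      if (try == config$maxRetries + 1L)
        stop("individual ", sampleIdsV[j], " has only ", length(elig),
             " eligible gene(s) after ", config$maxRetries,
             " resampling attempts; lower genesPerList or enrich the ",
             "frequency spectrum", call. = FALSE)
    }
    geno[, j] <- codes
    eligible[[j]] <- elig
  }
  ## --- metadata --------------------------------------------------------
  nM <- floor(n * config$sexRatio)
  sex <- sample(c(rep("M", nM), rep("F", n - nM)))
  ancestry <- .assignCategories(n, config$ancestryProps)
  metadata <- data.frame(sample = sampleIdsV, sex = sex, ancestry = ancestry)
  panel <- GenotypePanel(geno,
                         chrom = rep(config$chromosome, nRec),
                         pos = sitePos[recSite],
                         ref = siteRef[recSite], alt = recAlt,
                         metadata = metadata)
  ## --- ASE lists -------------------------------------------------------
  lists <- lapply(seq_len(n), function(j)
    AseGeneList(sample(eligible[[j]], config$genesPerList),
                label = sampleIdsV[j]))
  hetSnps <- lapply(seq_len(n),
                    function(j) snpIds(panel)[geno[, j] == 1L])
  names(hetSnps) <- names(eligible) <- sampleIdsV
  geneSnpIds <- lapply(geneRecs, function(r) snpIds(panel)[r])
  truth <- list(owners = setNames(sampleIdsV, sampleIdsV),
                eligibleGenes = eligible, hetSnps = hetSnps,
                geneSnpIds = geneSnpIds,
                hetProb = setNames(recF, snpIds(panel)),
                multiAllelic = setNames(isMulti[recSite], snpIds(panel)),
                config = unclass(config))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "lists"), showWarnings = FALSE)
    vcf <- file.path(dir, "cohort.vcf")
    gtf <- file.path(dir, "genes.gtf")
    meta <- file.path(dir, "metadata.tsv")
    writePanel(panel, vcf)
    .writeGtf(index, gtf)
    writeMetadata(metadata, meta)
    listFiles <- vapply(lists, function(l) {
      p <- file.path(dir, "lists", paste0(listLabel(l), ".txt"))
      writeGeneList(l, p)
      p
    }, character(1))
    truthPath <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(owners = as.list(truth$owners),
           genesPerList = config$genesPerList,
           seed = config$seed,
           listGenes = setNames(lapply(lists, geneSymbols), sampleIdsV)),
      truthPath, auto_unbox = TRUE, digits = NA)
    files <- list(vcf = vcf, gtf = gtf, metadata = meta,
                  lists = listFiles, truth = truthPath)
  }
  out <- list(panel = panel, index = index, lists = lists, truth = truth,
              files = files)
  if (is.null(dir)) out else invisible(out)
}

## GENCODE-dialect GTF (key "value"; gene_name on exon lines)
.writeGtf <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geneNames(index)) {
    gr <- index@exons[[g]]
    st <- index@geneStrand[[g]]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s.1"; gene_name "%s";', g, g, g)
    writeLines(sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(seqnames(gr)), start(gr), end(gr),
                       st, attrs), con)
  }
  invisible(path)
}

#' Shuffle list-owner identities (negative control)
#'
#' Permutes the owner labels across a collection of gene lists, preferring
#' a derangement (no list keeps its own label) so that the shuffled cohort
#' measures chance-level linking. Reproducible given a seed.
#'
#' @param lists list of [AseGeneList-class] objects (>= 2).
#' @param seed integer seed.
#' @return the lists with permuted labels; the permutation used is
#'   attached as attribute `"permutation"`.
#' @export
shuffleIdentities <- function(lists, seed = NULL) {
  n <- length(lists)
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  perm <- seq_len(n)
  for (try in seq_len(100)) {
    perm <- sample(n)
    if (!any(perm == seq_len(n))) break
  }
  labels <- vapply(lists, listLabel, character(1))
  out <- lapply(seq_len(n), function(i) {
    l <- lists[[i]]
    l@label <- labels[perm[i]]
    l
  })
  attr(out, "permutation") <- perm
  out
}
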