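## Fixtures are built in code at test time; nothing binary is stored.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

## write a GTF from a data.frame(gene, chrom, start, end, strand)
writeTestGtf <- function(df, path = tempfile(fileext = ".gtf"),
                         dropGeneName = rep(FALSE, nrow(df))) {
  attrs <- ifelse(dropGeneName,
                  sprintf('gene_id "%s";', df$gene),
                  sprintf('gene_id "%s"; gene_name "%s";', df$gene, df$gene))
  writeLines(sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                     df$chrom, df$start, df$end, df$strand, attrs),
             path)
  path
}

## write a VCF from site rows; `gt` is a character matrix sites x samples
writeTestVcf <- function(chrom, pos, ref, alt, gt,
                         samples = colnames(gt),
                         path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  path
}

## panel straight from a code matrix (rows named chrom:pos:ref:alt optional)
makeTestPanel <- function(geno, chrom = NULL, pos = NULL, ref = NULL,
                          alt = NULL, metadata = NULL) {
  n <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("chrT", n)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%02d", seq_len(ncol(geno)))
  GenotypePanel(geno, chrom = chrom, pos = pos, ref = ref, alt = alt,
                metadata = metadata)
}

## exon index straight from interval vectors (one gene per element)
makeTestIndex <- function(genes, starts, ends, chrom = "chrT") {
  grl <- GRangesList(mapply(function(s, e)
    GRanges(chrom, IRanges(s, e)), starts, ends, SIMPLIFY = FALSE))
  names(grl) <- genes
  new("ExonIndex", exons = reduce(grl),
      geneStrand = setNames(rep("+", length(genes)), genes))
}

## candidate set from raw ids/frequencies (for null-scheme draws)
makeCandidateSet <- function(ids, freq, lower = 0.1, upper = 0.5,
                             mode = "exclude-range", label = "synthetic") {
  new("CandidateSet", snpIds = ids, freq = setNames(freq[ids], ids),
      sourceGenes = setNames(rep(list(character(0)), length(ids)), ids),
      sex = NA_character_, ancestry = NA_character_,
      bounds = c(lower, upper), filterMode = mode, label = label)
}

## small cohort shared across tests (built once per session)
.fixtures <- new.env(parent = emptyenv())
smallCohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generateCohort(
      cohortConfig(nIndividuals = 40, nGenes = 150, nSnps = 2500,
                   genesPerList = 20, seed = 11, maxRetries = 100))
  .fixtures$small
}

## brute-force double-loop candidate oracle: O(genes x snps), 1-based
## inclusive interval test, then the frequency rule, then union
oracleCandidates <- function(genes, index, panel, lower = 0.1, upper = 0.5) {
  freq <- hetFrequencies(panel)
  rr <- rowRanges(panel)
  snpPos <- start(rr)
  snpChrom <- as.character(seqnames(rr))
  ids <- character(0)
  for (g in genes) {
    if (!g %in% geneNames(index)) next
    ex <- exonsOf(index, g)
    for (i in seq_along(rr)) {
      hit <- FALSE
      for (k in seq_along(ex)) {
        if (snpChrom[i] == as.character(seqnames(ex))[k] &&
            snpPos[i] >= start(ex)[k] && snpPos[i] <= end(ex)[k]) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        f <- freq[[snpIds(panel)[i]]]
        if (f > 0 && (f <= lower || f >= upper))
          ids <- c(ids, snpIds(panel)[i])
      }
    }
  }
  sort(unique(ids))
}
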