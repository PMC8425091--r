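#' Construct a GenotypePanel from components
#'
#' Low-level constructor; most users should call [readPanel()] or
#' [generateCohort()]. One row per (site, alternative allele) pair.
#'
#' @param geno integer matrix of codes 0/1/2/NA, SNP records x samples,
#'   with column names giving sample ids.
#' @param chrom,pos,ref,alt parallel vectors describing each SNP record;
#'   `pos` is the 1-based VCF position.
#' @param metadata optional data.frame with columns `sample`, `sex`,
#'   `ancestry` (see [readMetadata()]).
#' @return a [GenotypePanel-class].
#' @export
GenotypePanel <- function(geno, chrom, pos, ref, alt, metadata = NULL) {
  stopifnot(is.matrix(geno), !is.null(colnames(geno)),
            length(chrom) == nrow(geno), length(pos) == nrow(geno),
            length(ref) == nrow(geno), length(alt) == nrow(geno))
  mode(geno) <- "integer"
  rr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(rr) <- DataFrame(
    snpId = paste(chrom, pos, ref, alt, sep = ":"),
    ref = as.character(ref), alt = as.character(alt),
    siteKey = paste(chrom, pos, ref, sep = ":"))
  names(rr) <- mcols(rr)$snpId
  rownames(geno) <- mcols(rr)$snpId
  se <- SummarizedExperiment(assays = list(geno = geno), rowRanges = rr)
  panel <- new("GenotypePanel", se)
  if (!is.null(metadata)) panel <- attachMetadata(panel, metadata)
  panel
}

#' Read a multi-sample VCF into a GenotypePanel
#'
#' Every alternative allele of every site becomes one SNP record, so a
#' multi-allelic site with k ALT alleles yields k records sharing
#' chromosome/position/REF. For each record, a sample's code is the number
#' of copies of that particular alternative allele in its GT call
#' (`1/2` codes 1 for the first ALT record and 1 for the second); phasing
#' separators are ignored, and any call containing `.` (including `./.`)
#' is missing for all of the site's records. Non-diploid GT calls are an
#' error naming the offending record.
#'
#' @param path a VCF 4.x file with GT fields (plain or bgzipped).
#' @return a [GenotypePanel-class].
#' @export
readPanel <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF has no samples / no GT field", call. = FALSE)
  rr <- rowRanges(vcf)
  altCL <- as(VariantAnnotation::alt(vcf), "CharacterList")
  refA <- as.character(VariantAnnotation::ref(vcf))
  nAlt <- lengths(altCL)
  if (any(nAlt == 0L)) {
    keep <- nAlt > 0L
    rr <- rr[keep]; gt <- gt[keep, , drop = FALSE]
    altCL <- altCL[keep]; nAlt <- nAlt[keep]; refA <- refA[keep]
  }
  if (length(rr) == 0L) stop("VCF has no usable variant records", call. = FALSE)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  ## decode each distinct GT string once: copies of each alt index, or missing
  uniq <- unique(as.vector(gt))
  parts <- strsplit(uniq, "[/|]")
  ploidy <- lengths(parts)
  missU <- vapply(parts, function(p) any(p == "."), TRUE)
  badP <- ploidy != 2L & !(missU & ploidy <= 2L)
  if (any(badP)) {
    bad <- uniq[badP][1]
    hit <- which(gt == bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-diploid GT '%s' at record %s:%d (sample %s)",
                 bad, chrom[hit[1]], pos[hit[1]], colnames(gt)[hit[2]]),
         call. = FALSE)
  }
  maxAlt <- max(nAlt)
  lut <- matrix(0L, length(uniq), maxAlt)
  for (u in seq_along(uniq)) {
    if (missU[u]) next
    a <- suppressWarnings(as.integer(parts[[u]]))
    if (anyNA(a)) {
      hit <- which(gt == uniq[u], arr.ind = TRUE)[1, ]
      stop(sprintf("unparseable GT '%s' at record %s:%d", uniq[u],
                   chrom[hit[1]], pos[hit[1]]), call. = FALSE)
    }
    for (k in seq_len(maxAlt)) lut[u, k] <- sum(a == k)
  }
  gtIdx <- match(gt, uniq)
  dim(gtIdx) <- dim(gt)
  rowOf <- rep(seq_along(nAlt), nAlt)   # site of each expanded record
  altIdx <- sequence(nAlt)              # alt index within its site
  gi <- gtIdx[rowOf, , drop = FALSE]
  codes <- lut[cbind(as.vector(gi), rep(altIdx, times = ncol(gt)))]
  codes[missU[as.vector(gi)]] <- NA_integer_
  codes <- matrix(codes, nrow = length(rowOf), ncol = ncol(gt),
                  dimnames = list(NULL, colnames(gt)))
  GenotypePanel(codes,
                chrom = chrom[rowOf], pos = pos[rowOf],
                ref = refA[rowOf],
                alt = unlist(altCL, use.names = FALSE))
}

#' Write a GenotypePanel as VCF 4.2
#'
#' Sibling ALT records of one site are folded back into a single
#' multi-allelic VCF line; genotype codes are rendered as unphased GT
#' calls (`0/1`, `1/2`, ...), with missing codes as `./.`. Sample
#' metadata is not written (use [writeMetadata()]).
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  rr <- rowRanges(panel)
  mc <- mcols(rr)
  g <- genoMatrix(panel)
  sites <- unique(mc$siteKey)
  siteIdx <- split(seq_along(rr), factor(mc$siteKey, levels = sites))
  nAlt <- lengths(siteIdx)
  first <- vapply(siteIdx, `[`, integer(1), 1L)
  chrom <- as.character(seqnames(rr))[first]
  pos <- start(rr)[first]
  refA <- mc$ref[first]
  altStr <- vapply(siteIdx, function(i) paste(mc$alt[i], collapse = ","),
                   character(1))
  gtChar <- matrix("./.", length(sites), ncol(g))
  bi <- which(nAlt == 1L)
  if (length(bi)) {
    codes <- g[first[bi], , drop = FALSE]
    gtChar[bi, ] <- c("0/0", "0/1", "1/1")[codes + 1L]
    gtChar[bi, ][is.na(codes)] <- "./."
  }
  for (s in which(nAlt > 1L)) {
    sub <- g[siteIdx[[s]], , drop = FALSE]
    gtChar[s, ] <- apply(sub, 2, function(codes) {
      if (anyNA(codes)) return("./.")
      alleles <- c(rep(0L, 2L - sum(codes)),
                   rep(seq_along(codes), codes))
      paste(sort(alleles), collapse = "/")
    })
  }
  lines <- do.call(paste, c(list(chrom, pos, ".", refA, altStr, ".", "PASS",
                                 ".", "GT"),
                            as.data.frame(gtChar, stringsAsFactors = FALSE),
                            sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=aselink",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(panel)), collapse = "\t")),
             con)
  writeLines(lines, con)
  invisible(path)
}
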