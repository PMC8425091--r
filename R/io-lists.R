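#' Read an ASE gene list from a text file
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored. Duplicate symbols are dropped (first occurrence kept) and the
#' number of dropped duplicates is reported via a message.
#'
#' @param path text file, UTF-8, one symbol per line.
#' @param label individual label; defaults to the file name without
#'   extension.
#' @param sex,ancestry optional known auxiliary features of the owner.
#' @return an [AseGeneList-class].
#' @export
readGeneList <- function(path, label = NULL,
                         sex = NA_character_, ancestry = NA_character_) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  raw <- trimws(readLines(path, warn = FALSE))
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0L)
    stop("gene list '", path, "' is empty after filtering", call. = FALSE)
  dup <- duplicated(raw)
  if (any(dup))
    message(sum(dup), " duplicate gene symbol(s) dropped from '", path, "'")
  AseGeneList(raw[!dup], label = label, sex = sex, ancestry = ancestry)
}

#' Write an ASE gene list
#' @param x an [AseGeneList-class].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(x, path) {
  stopifnot(is(x, "AseGeneList"))
  writeLines(geneSymbols(x), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header columns `sample`, `sex`, `ancestry`; sex must
#' be M or F, ancestry one of EUR/AFR/AMR/EAS/SAS. Any other category is
#' an error naming the offending row.
#'
#' @param path TSV file.
#' @return data.frame with columns sample, sex, ancestry.
#' @export
readMetadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "sex", "ancestry")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  badSex <- !md$sex %in% c("M", "F")
  if (any(badSex))
    stop(sprintf("invalid sex '%s' in metadata row %d (sample %s)",
                 md$sex[badSex][1], which(badSex)[1],
                 md$sample[badSex][1]), call. = FALSE)
  badAnc <- !md$ancestry %in% ANCESTRIES
  if (any(badAnc))
    stop(sprintf("invalid ancestry '%s' in metadata row %d (sample %s)",
                 md$ancestry[badAnc][1], which(badAnc)[1],
                 md$sample[badAnc][1]), call. = FALSE)
  if (anyDuplicated(md$sample))
    stop("duplicate sample ids in metadata", call. = FALSE)
  md[, need]
}

#' Write a sample metadata table
#' @param metadata data.frame with columns sample, sex, ancestry.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach sex/ancestry metadata to a panel
#'
#' Every metadata row must refer to a sample present in the panel, and
#' every panel sample must be covered.
#'
#' @param panel a [GenotypePanel-class].
#' @param metadata data.frame as returned by [readMetadata()].
#' @return the panel with `sex` and `ancestry` columns in its `colData`.
#' @export
attachMetadata <- function(panel, metadata) {
  stopifnot(is(panel, "GenotypePanel"))
  extra <- setdiff(metadata$sample, sampleIds(panel))
  if (length(extra))
    stop("metadata refers to sample(s) absent from the panel: ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  miss <- setdiff(sampleIds(panel), metadata$sample)
  if (length(miss))
    stop("panel sample(s) missing from metadata: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  idx <- match(sampleIds(panel), metadata$sample)
  colData(panel)$sex <- metadata$sex[idx]
  colData(panel)$ancestry <- metadata$ancestry[idx]
  validObject(panel)
  panel
}

#' Write a candidate set as an audit TSV
#'
#' Columns: snp_id, chrom, pos, ref, alt, f (panel het frequency),
#' source_genes (comma-separated contributing genes).
#'
#' @param can a [CandidateSet-class].
#' @param panel the [GenotypePanel-class] the candidates were compiled
#'   against (for coordinates).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(can, panel, path) {
  idx <- match(snpIds(can), snpIds(panel))
  if (anyNA(idx))
    stop("candidate SNP(s) absent from panel", call. = FALSE)
  rr <- rowRanges(panel)[idx]
  df <- data.frame(
    snp_id = snpIds(can),
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    ref = mcols(rr)$ref,
    alt = mcols(rr)$alt,
    f = unname(candidateFreq(can)),
    source_genes = vapply(sourceGenes(can), paste, character(1),
                          collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a linking result as TSV plus a JSON summary
#'
#' @param result a [LinkResult-class].
#' @param tsvPath per-individual table (id, score, nMatched, rank, pi).
#' @param jsonPath run summary (best match, gap, p_gap, parameters).
#' @return `tsvPath`, invisibly.
#' @export
writeLinkResult <- function(result, tsvPath, jsonPath = NULL) {
  tb <- as.data.frame(linkTable(result))
  write.table(tb, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    summary <- list(
      best_match = bestMatch(result),
      gap = if (is.infinite(gapStat(result))) "Inf" else gapStat(result),
      p_gap = if (is.na(pGap(result))) NULL else pGap(result),
      uninformative = result@uninformative,
      parameters = result@params)
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(tsvPath)
}
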