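#' Read a GENCODE-dialect GTF into an ExonIndex
#'
#' Imports the annotation, keeps features of the requested type (exons by
#' default), groups them by the `gene_name` attribute and merges
#' overlapping exons of each gene, so that downstream overlap counts each
#' SNP at most once per gene. Exon records lacking a `gene_name`
#' attribute are skipped with a warning; a file yielding no usable gene is
#' an error. Genes whose exons span several chromosomes are rejected.
#'
#' @param path a GTF file (plain or gzipped).
#' @param feature the `type` value identifying exon features
#'   (default `"exon"`).
#' @return an [ExonIndex-class].
#' @export
readAnnotation <- function(path, feature = "exon") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == feature]
  if (length(gr) == 0L)
    stop("annotation contains no '", feature, "' features", call. = FALSE)
  if (is.null(gr$gene_name)) {
    warning(length(gr), " exon record(s) lack a gene_name attribute; skipped")
    stop("no usable genes in annotation (no gene_name attributes)",
         call. = FALSE)
  }
  noname <- is.na(gr$gene_name) | gr$gene_name == ""
  if (any(noname)) {
    warning(sum(noname), " exon record(s) lack a gene_name attribute; skipped")
    gr <- gr[!noname]
  }
  if (length(gr) == 0L)
    stop("no usable genes in annotation after skipping unnamed exons",
         call. = FALSE)
  sym <- gr$gene_name
  bychr <- split(as.character(seqnames(gr)), sym)
  multi <- names(bychr)[vapply(bychr, function(v) length(unique(v)) > 1, TRUE)]
  if (length(multi))
    stop("gene(s) with exons on multiple chromosomes: ",
         paste(multi, collapse = ", "), call. = FALSE)
  st <- vapply(split(as.character(strand(gr)), sym), function(v) {
    u <- unique(v)
    if (length(u) == 1L) u else "*"
  }, character(1))
  merged <- reduce(S4Vectors::split(gr, sym), ignore.strand = TRUE)
  new("ExonIndex", exons = merged, geneStrand = st[names(merged)])
}
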