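#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @export
setGeneric("exonsOf", function(x, gene) standardGeneric("exonsOf"))

#' @export
setGeneric("geneSpan", function(x, genes) standardGeneric("geneSpan"))

#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))

#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))

#' @export
setGeneric("bestMatch", function(x) standardGeneric("bestMatch"))

#' @export
setGeneric("gapStat", function(x) standardGeneric("gapStat"))

#' @export
setGeneric("pGap", function(x) standardGeneric("pGap"))
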