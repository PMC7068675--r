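#' Accessors for FFLNetwork and ExpressionBundle objects
#'
#' `ffls()`, `fflEdges()` and `fflNodes()` return the loop, edge and node
#' tables of an [FFLNetwork-class]; `nFFLs()` the loop count.
#' `exprMatrix()` returns one of the three expression matrices of an
#' [ExpressionBundle-class] by layer; `sampleIds()` and `sampleGroups()` the
#' shared sample ordering and the case/control factor.
#'
#' @param x an `FFLNetwork` or `ExpressionBundle`.
#' @param layer for `exprMatrix`, one of `"gene"`, `"miRNA"`, `"lncRNA"`.
#' @return data.frames (network accessors), a numeric matrix
#'   (`exprMatrix`), a character vector (`sampleIds`) or a factor
#'   (`sampleGroups`).
#' @examples
#' net <- enumerateFFLs(data.frame(
#'   source = c("G1", "G1", "M1"), target = c("M1", "L1", "L1"),
#'   layer = c("gene-miRNA", "gene-lncRNA", "miRNA-lncRNA")))
#' ffls(net)
#' nFFLs(net)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ffls", function(x) standardGeneric("ffls"))
#' @rdname accessors
#' @export
setGeneric("fflEdges", function(x) standardGeneric("fflEdges"))
#' @rdname accessors
#' @export
setGeneric("fflNodes", function(x) standardGeneric("fflNodes"))
#' @rdname accessors
#' @export
setGeneric("nFFLs", function(x) standardGeneric("nFFLs"))
#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x, layer = c("gene", "miRNA", "lncRNA"))
  standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
setMethod("ffls", "FFLNetwork", function(x) x@ffls)
#' @rdname accessors
setMethod("fflEdges", "FFLNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("fflNodes", "FFLNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("nFFLs", "FFLNetwork", function(x) nrow(x@ffls))

#' @rdname accessors
setMethod("exprMatrix", "ExpressionBundle", function(x, layer) {
  layer <- match.arg(layer, c("gene", "miRNA", "lncRNA"))
  switch(layer, gene = x@geneExpr, miRNA = x@mirnaExpr, lncRNA = x@lncrnaExpr)
})
#' @rdname accessors
setMethod("sampleIds", "ExpressionBundle", function(x) colnames(x@geneExpr))
#' @rdname accessors
setMethod("sampleGroups", "ExpressionBundle", function(x) x@groups)

#' @rdname degreeDistribution
#' @export
setGeneric("degreeDistribution", function(x) standardGeneric("degreeDistribution"))

#' @rdname keyModule
#' @export
setGeneric("keyModule", function(x) standardGeneric("keyModule"))

#' @rdname coreModules
#' @export
setGeneric("coreModules", function(x, minSize = 4, penalty = 2,
                                   mergeThreshold = 0.8)
  standardGeneric("coreModules"))
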