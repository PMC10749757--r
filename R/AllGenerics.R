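#' Accessors for crossGEx classes
#'
#' Accessor generics: `exprData()` returns the long-format records of an
#' [ExpressionTable-class]; `exprScale()` its declared scale;
#' `provenance()` its provenance text; `orthologData()` the group records
#' of an [OrthologTable-class]; `droppedTaxa()` its count of dropped
#' unsupported-taxon records; `idMapData()` the cross-reference records of
#' an [IdMap-class]; `trendParams()` the `(a0, a1)` of a
#' [DispersionTrend-class]; `medianValues()`, `medianAxis()` and
#' `medianContext()` the matrix, column axis and stratum of a
#' [MedianMatrix-class].
#'
#' @param x An object of the relevant class.
#' @return The slot value described above.
#' @name accessors
#' @examples
#' tab <- ExpressionTable(data.frame(gene_id = "g", species = "human",
#'   tissue = "t", sample_id = "s", value = 1), "counts")
#' exprScale(tab)
#' nrow(exprData(tab))
NULL

#' @rdname accessors
#' @export
setGeneric("exprData", function(x) standardGeneric("exprData"))
#' @rdname accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("orthologData", function(x) standardGeneric("orthologData"))
#' @rdname accessors
#' @export
setGeneric("droppedTaxa", function(x) standardGeneric("droppedTaxa"))
#' @rdname accessors
#' @export
setGeneric("idMapData", function(x) standardGeneric("idMapData"))
#' @rdname accessors
#' @export
setGeneric("trendParams", function(x) standardGeneric("trendParams"))
#' @rdname accessors
#' @export
setGeneric("medianValues", function(x) standardGeneric("medianValues"))
#' @rdname accessors
#' @export
setGeneric("medianAxis", function(x) standardGeneric("medianAxis"))
#' @rdname accessors
#' @export
setGeneric("medianContext", function(x) standardGeneric("medianContext"))

#' @rdname accessors
setMethod("exprData", "ExpressionTable", function(x) x@records)
#' @rdname accessors
setMethod("exprScale", "ExpressionTable", function(x) x@scale)
#' @rdname accessors
setMethod("provenance", "ExpressionTable", function(x) x@provenance)
#' @rdname accessors
setMethod("orthologData", "OrthologTable", function(x) x@groups)
#' @rdname accessors
setMethod("droppedTaxa", "OrthologTable", function(x) x@droppedTaxa)
#' @rdname accessors
setMethod("idMapData", "IdMap", function(x) x@xref)
#' @rdname accessors
setMethod("trendParams", "DispersionTrend",
          function(x) c(a0 = x@a0, a1 = x@a1))
#' @rdname accessors
setMethod("medianValues", "MedianMatrix", function(x) x@values)
#' @rdname accessors
setMethod("medianAxis", "MedianMatrix", function(x) x@axis)
#' @rdname accessors
setMethod("medianContext", "MedianMatrix", function(x) x@context)

#' @rdname dsAnalysis
#' @export
setGeneric("dsAnalysis",
           function(x, spec = SelectionSpec(), mode, ...)
             standardGeneric("dsAnalysis"))
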