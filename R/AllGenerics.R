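# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname GoldStandard-class
#' @param object,x a package object.
#' @export
setGeneric("goldEdges", function(object) standardGeneric("goldEdges"))

#' @rdname GoldStandard-class
#' @export
setGeneric("cutoffs", function(object) standardGeneric("cutoffs"))

#' @rdname GoldStandard-class
#' @export
setGeneric("nTrueEdges", function(object) standardGeneric("nTrueEdges"))

#' @rdname GoldStandard-class
#' @export
setGeneric("nFalseEdges", function(object) standardGeneric("nFalseEdges"))

#' @rdname GoldStandard-class
#' @param gs a [GoldStandard-class].
#' @param expr numeric expression matrix, genes x samples.
#' @export
setGeneric("restrictToDataset",
           function(gs, expr) standardGeneric("restrictToDataset"))

#' @rdname ConfounderDesign-class
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname CoexpressionResult-class
#' @export
setGeneric("coexEdges", function(object) standardGeneric("coexEdges"))

#' @rdname RocResult-class
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname RocResult-class
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("phenoTable", function(object) standardGeneric("phenoTable"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("edgeList", function(object) standardGeneric("edgeList"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("genParams", function(object) standardGeneric("genParams"))
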