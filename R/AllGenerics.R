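#' @rdname StrainPanel-class
#' @param x a \code{StrainPanel}
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname StrainPanel-class
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname StrainPanel-class
#' @export
setGeneric("panelLoci", function(x) standardGeneric("panelLoci"))

#' @rdname StrainPanel-class
#' @param locus locus name
#' @export
setGeneric("locusSequences", function(x, locus) standardGeneric("locusSequences"))

#' @rdname StrainPanel-class
#' @export
setGeneric("referenceStrain", function(x) standardGeneric("referenceStrain"))

#' @rdname AlleleTable-class
#' @param x an \code{AlleleTable}
#' @export
setGeneric("alleleAssignments", function(x) standardGeneric("alleleAssignments"))

#' @rdname AlleleTable-class
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' @rdname AlleleTable-class
#' @export
setGeneric("nTyped", function(x) standardGeneric("nTyped"))

#' @rdname MLSTScheme-class
#' @param x an \code{MLSTScheme}
#' @export
setGeneric("schemeName", function(x) standardGeneric("schemeName"))

#' @rdname MLSTScheme-class
#' @export
setGeneric("geneOrder", function(x) standardGeneric("geneOrder"))
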