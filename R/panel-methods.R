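#' @describeIn StrainPanel-class strain ids in panel order
#' @export
setMethod("strainNames", "StrainPanel", function(x) x@strains$strain_id)

#' @describeIn StrainPanel-class named character vector strain id -> species
#' @export
setMethod("speciesLabels", "StrainPanel",
    function(x) setNames(x@strains$species, x@strains$strain_id))

#' @describeIn StrainPanel-class locus names in panel order
#' @export
setMethod("panelLoci", "StrainPanel", function(x) x@loci)

#' @describeIn StrainPanel-class the \code{DNAStringSet} at one locus
#'   (names are strain ids; strains missing that locus are absent)
#' @export
setMethod("locusSequences", "StrainPanel", function(x, locus) {
    if (!locus %in% x@loci)
        stop(sprintf("unknown locus '%s'", locus))
    ss <- x@sequences[[locus]]
    if (is.null(ss)) DNAStringSet() else ss
})

#' @describeIn StrainPanel-class reference strain id or NA
#' @export
setMethod("referenceStrain", "StrainPanel", function(x) x@referenceStrain)

setMethod("show", "StrainPanel", function(object) {
    sp <- table(object@strains$species)
    cat(sprintf("StrainPanel: %d strains, %d species, %d loci\n",
                nrow(object@strains), length(sp), length(object@loci)))
    for (s in unique(object@strains$species))
        cat(sprintf("  %s: %d strain(s)\n", s, sum(object@strains$species == s)))
    if (length(object@loci))
        cat("loci:", paste(head(object@loci, 10L), collapse = ", "),
            if (length(object@loci) > 10L) "..." else "", "\n")
    if (!is.na(object@referenceStrain))
        cat("reference strain:", object@referenceStrain, "\n")
})

#' @describeIn AlleleTable-class named integer vector strain id -> allele id
#' @export
setMethod("alleleAssignments", "AlleleTable", function(x) x@assignment)

#' @describeIn AlleleTable-class integer vector of per-allele strain counts
#' @export
setMethod("alleleCounts", "AlleleTable", function(x) x@counts)

#' @describeIn AlleleTable-class number of typed strains
#' @export
setMethod("nTyped", "AlleleTable", function(x) x@N)

setMethod("show", "AlleleTable", function(object) {
    cat(sprintf("AlleleTable for locus '%s': %d strains, %d alleles\n",
                object@locus, object@N, length(object@counts)))
    cat("counts:", paste(object@counts, collapse = " "), "\n")
})

#' @describeIn MLSTScheme-class scheme label
#' @export
setMethod("schemeName", "MLSTScheme", function(x) x@name)

#' @describeIn MLSTScheme-class ordered locus names
#' @export
setMethod("geneOrder", "MLSTScheme", function(x) x@geneOrder)

setMethod("show", "MLSTScheme", function(object) {
    cat(sprintf("MLSTScheme %s: %s\n", object@name,
                paste(object@geneOrder, collapse = " -> ")))
})

setMethod("show", "Primer", function(object) {
    cat(sprintf("Primer %s: 5'-%s-3' (%d nt, Tm %.0f C)\n",
                object@name, object@seq, nchar(object@seq), object@tm))
})

setMethod("show", "PrimerPair", function(object) {
    cat("PrimerPair:\n  F: "); show(object@forward)
    cat("  R: "); show(object@reverse)
    if (!is.na(object@expectedSize))
        cat(sprintf("  expected product: %d bp\n", object@expectedSize))
})

setMethod("show", "PCRParams", function(object) {
    cat(sprintf(
        "PCRParams: <=%d mismatches, %d-nt 3' anchor, product %d-%d bp, %s\n",
        object@maxMismatches, object@anchorLen, object@minProduct,
        object@maxProduct,
        if (object@bothStrands) "both strands" else "plus strand only"))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d species (%s strains), %d loci, omega %.2f, seed %d\n",
                length(object@speciesNames),
                paste(object@strainsPerSpecies, collapse = "+"),
                nrow(object@locusSpecs), object@omegaTarget, object@seed))
    if (nrow(object@plantedWindows))
        cat(sprintf("  %d planted window(s) on %s\n",
                    nrow(object@plantedWindows),
                    paste(unique(object@plantedWindows$locus), collapse = ", ")))
})
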