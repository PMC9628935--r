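#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement GENETIC_CODE
#'   readBStringSet writeXStringSet matchPattern width subseq xscat
#' @importFrom IRanges start end
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table combn head
NULL

#' StrainPanel: a species-labelled multi-locus sequence panel
#'
#' The central container of the package: a set of strains, each carrying a
#' species label, with one DNA sequence per (strain, locus) cell.  Cells may
#' be missing (a strain without data at a locus is simply absent from that
#' locus' \code{DNAStringSet}); statistics exclude missing cells per locus
#' rather than dropping the strain panel-wide.
#'
#' @slot strains data.frame with columns \code{strain_id} and \code{species},
#'   in first-appearance order; this order is preserved in every downstream
#'   table and tree.
#' @slot loci character vector of locus names, first-appearance order.
#' @slot sequences named list, one \code{DNAStringSet} per locus, names of
#'   each set being strain ids.
#' @slot referenceStrain single strain id or \code{NA_character_}; used by
#'   reference-based polymorphism reports.
#'
#' @seealso [buildPanel()], [generatePanel()], [summarizeLoci()]
#' @export
setClass("StrainPanel",
    representation(
        strains = "data.frame",
        loci = "character",
        sequences = "list",
        referenceStrain = "character"
    ),
    prototype(
        strains = data.frame(strain_id = character(), species = character(),
                             stringsAsFactors = FALSE),
        loci = character(),
        sequences = list(),
        referenceStrain = NA_character_
    )
)

setValidity("StrainPanel", function(object) {
    msg <- character()
    st <- object@strains
    if (!all(c("strain_id", "species") %in% names(st)))
        msg <- c(msg, "strains must have columns strain_id and species")
    else {
        if (anyDuplicated(st$strain_id))
            msg <- c(msg, "duplicate strain_id in panel")
        if (any(!nzchar(st$species)) || anyNA(st$species))
            msg <- c(msg, "every strain needs a non-empty species label")
    }
    if (anyDuplicated(object@loci))
        msg <- c(msg, "duplicate locus names")
    if (!all(names(object@sequences) %in% object@loci))
        msg <- c(msg, "sequences list names must be panel loci")
    for (loc in names(object@sequences)) {
        ss <- object@sequences[[loc]]
        if (!is(ss, "DNAStringSet")) {
            msg <- c(msg, sprintf("sequences[['%s']] is not a DNAStringSet", loc))
            next
        }
        bad <- setdiff(names(ss), st$strain_id)
        if (length(bad))
            msg <- c(msg, sprintf("locus %s has sequences for unknown strains: %s",
                                  loc, paste(bad, collapse = ", ")))
    }
    if (length(object@referenceStrain) != 1L)
        msg <- c(msg, "referenceStrain must be length 1 (possibly NA)")
    else if (!is.na(object@referenceStrain) &&
             !(object@referenceStrain %in% st$strain_id))
        msg <- c(msg, "referenceStrain is not a member strain")
    if (length(msg)) msg else TRUE
})

#' AlleleTable: exact-match allele assignment at one locus
#'
#' Strains with byte-identical sequences (after uppercasing) share an allele
#' id; ids are 1..k in order of first occurrence.
#'
#' @slot locus locus name.
#' @slot assignment named integer vector, strain id -> allele id.
#' @slot counts integer vector, allele id j -> number of strains carrying j.
#' @slot N number of typed strains.
#'
#' @seealso [callAlleles()], [discriminatoryPower()]
#' @export
setClass("AlleleTable",
    representation(
        locus = "character",
        assignment = "integer",
        counts = "integer",
        N = "integer"
    )
)

setValidity("AlleleTable", function(object) {
    msg <- character()
    k <- length(object@counts)
    if (sum(object@counts) != object@N)
        msg <- c(msg, "allele counts must sum to N")
    if (length(object@assignment) != object@N)
        msg <- c(msg, "assignment length must equal N")
    if (k > 0L && !identical(sort(unique(object@assignment)), seq_len(k)))
        msg <- c(msg, "allele ids must be contiguous 1..k")
    if (length(msg)) msg else TRUE
})

#' MLSTScheme: an ordered gene concatenation scheme
#'
#' @slot name scheme label (e.g. \code{"pubMLST"}).
#' @slot geneOrder ordered character vector of locus names, no duplicates.
#'
#' @seealso [mlstSchemes()], [concatenateScheme()]
#' @export
setClass("MLSTScheme",
    representation(name = "character", geneOrder = "character")
)

setValidity("MLSTScheme", function(object) {
    msg <- character()
    if (length(object@geneOrder) == 0L)
        msg <- c(msg, "geneOrder must be non-empty")
    if (anyDuplicated(object@geneOrder))
        msg <- c(msg, "geneOrder must not contain duplicates")
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(msg)) msg else TRUE
})

#' Primer: a single oligonucleotide
#'
#' @slot name primer name.
#' @slot seq 5'->3' sequence over A/C/G/T, 18-30 nt.
#' @slot tm Wallace-rule melting temperature in degrees C (see [primerTm()]).
#' @export
setClass("Primer",
    representation(name = "character", seq = "character", tm = "numeric")
)

setValidity("Primer", function(object) {
    msg <- character()
    n <- nchar(object@seq)
    if (length(object@seq) != 1L || n < 18L || n > 30L)
        msg <- c(msg, "primer length must be 18-30 nt")
    if (grepl("[^ACGT]", object@seq))
        msg <- c(msg, "primer sequence restricted to A/C/G/T (no degenerate bases)")
    if (length(msg)) msg else TRUE
})

#' PrimerPair: a forward/reverse oligo pair with expected product size
#'
#' @slot forward,reverse [Primer-class] objects, both written 5'->3'.
#' @slot expectedSize expected product length in bp (NA if unknown); when
#'   set it must be at least the sum of the two primer lengths, since the
#'   product includes both primer footprints.
#' @export
setClass("PrimerPair",
    representation(forward = "Primer", reverse = "Primer",
                   expectedSize = "integer")
)

setValidity("PrimerPair", function(object) {
    sz <- object@expectedSize
    if (!is.na(sz) &&
        sz < nchar(object@forward@seq) + nchar(object@reverse@seq))
        return("expectedSize must be >= forward length + reverse length")
    TRUE
})

#' PCRParams: in-silico PCR matching parameters
#'
#' The annealing model is Hamming distance with a 3' anchor: a primer binds
#' where it has at most \code{maxMismatches} mismatches overall and zero
#' mismatches within its \code{anchorLen} 3'-terminal bases.
#'
#' @slot maxMismatches maximum mismatches tolerated per primer site.
#' @slot anchorLen length of the 3'-terminal zero-mismatch anchor.
#' @slot minProduct,maxProduct admissible product length range in bp.
#' @slot bothStrands consider both template orientations.
#' @seealso [pcrParams()], [insilicoPcr()]
#' @export
setClass("PCRParams",
    representation(maxMismatches = "integer", anchorLen = "integer",
                   minProduct = "integer", maxProduct = "integer",
                   bothStrands = "logical")
)

setValidity("PCRParams", function(object) {
    msg <- character()
    if (object@anchorLen < 0L)
        msg <- c(msg, "anchorLen must be >= 0")
    if (object@minProduct >= object@maxProduct)
        msg <- c(msg, "minProduct must be < maxProduct")
    if (object@maxMismatches < 0L)
        msg <- c(msg, "maxMismatches must be >= 0")
    if (length(msg)) msg else TRUE
})

#' SimConfig: configuration of the strain-panel simulator
#'
#' @slot speciesNames species labels, one per simulated species.
#' @slot strainsPerSpecies integer vector parallel to \code{speciesNames}.
#' @slot locusSpecs data.frame with columns \code{name}, \code{length},
#'   \code{coding}; coding lengths must be divisible by 3.
#' @slot pInter named numeric, per-locus target \emph{pairwise} inter-species
#'   substitution proportion (each species ancestor receives
#'   \code{floor(pInter * length / 2)} substitutions from the shared root).
#' @slot pIntra named numeric, per-locus intra-species substitution
#'   proportion (each strain receives \code{floor(pIntra * length)}
#'   substitutions from its species ancestor).
#' @slot omegaTarget desired Nei-Gojobori dN/dS of coding-locus divergence,
#'   in (0, 1].
#' @slot plantedWindows data.frame with columns \code{locus},
#'   \code{targetSpecies}, \code{start}, \code{windowLength}; windows are
#'   kept invariant in the target species and given 4 substitutions (at
#'   least one in the 3'-terminal 3 positions) in every other species
#'   ancestor.
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [generatePanel()]
#' @export
setClass("SimConfig",
    representation(
        speciesNames = "character",
        strainsPerSpecies = "integer",
        locusSpecs = "data.frame",
        pInter = "numeric",
        pIntra = "numeric",
        omegaTarget = "numeric",
        plantedWindows = "data.frame",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    ls <- object@locusSpecs
    if (length(object@strainsPerSpecies) != length(object@speciesNames))
        msg <- c(msg, "strainsPerSpecies must parallel speciesNames")
    if (any(object@strainsPerSpecies < 1L))
        msg <- c(msg, "each species needs at least one strain")
    if (!all(c("name", "length", "coding") %in% names(ls)))
        msg <- c(msg, "locusSpecs needs columns name, length, coding")
    else {
        if (any(ls$coding & ls$length %% 3L != 0L))
            msg <- c(msg, "coding locus lengths must be divisible by 3")
        if (anyDuplicated(ls$name))
            msg <- c(msg, "duplicate locus names in locusSpecs")
    }
    pInter <- object@pInter; pIntra <- object@pIntra
    if (!all(ls$name %in% names(pInter)) || !all(ls$name %in% names(pIntra)))
        msg <- c(msg, "pInter and pIntra must be named for every locus")
    else {
        pi1 <- pIntra[ls$name]; pi2 <- pInter[ls$name]
        if (any(pi1 < 0) || any(pi1 >= pi2) || any(pi2 > 0.75))
            msg <- c(msg, "require 0 <= pIntra < pInter <= 0.75 per locus")
    }
    if (object@omegaTarget <= 0 || object@omegaTarget > 1)
        msg <- c(msg, "omegaTarget must be in (0, 1]")
    pw <- object@plantedWindows
    if (nrow(pw)) {
        if (!all(c("locus", "targetSpecies", "start", "windowLength") %in% names(pw)))
            msg <- c(msg, "plantedWindows needs columns locus, targetSpecies, start, windowLength")
        else {
            if (any(pw$windowLength < 18L | pw$windowLength > 30L))
                msg <- c(msg, "windowLength must be in [18, 30]")
            if (!all(pw$locus %in% ls$name))
                msg <- c(msg, "planted window on unknown locus")
            else {
                len <- setNames(ls$length, ls$name)[pw$locus]
                if (any(pw$start < 1L | pw$start + pw$windowLength - 1L > len))
                    msg <- c(msg, "planted window outside locus bounds")
            }
            if (!all(pw$targetSpecies %in% object@speciesNames))
                msg <- c(msg, "planted window targets unknown species")
            # overlap check within each locus
            for (loc in unique(pw$locus)) {
                w <- pw[pw$locus == loc, , drop = FALSE]
                if (nrow(w) > 1L) {
                    o <- order(w$start)
                    s <- w$start[o]; e <- w$start[o] + w$windowLength[o] - 1L
                    if (any(s[-1L] <= e[-length(e)]))
                        msg <- c(msg, sprintf("overlapping planted windows on locus %s", loc))
                }
            }
        }
    }
    if (length(msg)) msg else TRUE
})
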