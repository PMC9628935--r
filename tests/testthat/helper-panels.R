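## Shared fixtures built in code.

## build a StrainPanel from a list locus -> named character vector of
## sequences, with a named species vector
panelFromList <- function(seqList, species, referenceStrain = NA_character_) {
    strains <- data.frame(strain_id = names(species),
                          species = unname(species),
                          stringsAsFactors = FALSE)
    sequences <- lapply(seqList, function(s) {
        ss <- Biostrings::DNAStringSet(s)
        names(ss) <- names(s)
        ss
    })
    methods::new("StrainPanel", strains = strains, loci = names(seqList),
                 sequences = sequences,
                 referenceStrain = as.character(referenceStrain))
}

## default-configuration simulations are expensive enough to share across
## test blocks within a file; cache per seed
.simCache <- new.env(parent = emptyenv())
cachedSim <- function(seed) {
    key <- as.character(seed)
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- generatePanel(simConfig(seed = seed))
    .simCache[[key]]
}

## a small, fast config: 3 species x 2 strains, two short coding loci and
## one non-coding locus, no planted windows
smallConfig <- function(seed, pIntra = NULL, pInter = NULL) {
    specs <- data.frame(
        name = c("locA", "locB", "nc16"),
        length = c(300L, 450L, 400L),
        coding = c(TRUE, TRUE, FALSE),
        stringsAsFactors = FALSE)
    simConfig(seed = seed,
              speciesNames = c("sp1", "sp2", "sp3"),
              strainsPerSpecies = c(2L, 2L, 2L),
              locusSpecs = specs,
              pInter = pInter, pIntra = pIntra,
              plantedWindows = NULL)
}
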