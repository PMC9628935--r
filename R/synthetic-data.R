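## Multi-species strain-panel simulator: star phylogeny, codon-aware
## substitution with a target dN/dS, planted species-diagnostic windows.

## deterministic 31-bit sub-seed from (seed, key parts); keys the global RNG
## per (locus, species, strain) so adding a strain never perturbs others
.subSeed <- function(seed, ...) {
    key <- paste(c(seed, ...), collapse = "\r")
    h <- 17
    for (v in utf8ToInt(key))
        h <- (h * 31 + v) %% 2147483629
    as.integer(h + 1)
}

#' Default locus table of the simulator
#'
#' The seventeen housekeeping loci of the five Bacillus MLST schemes with
#' their published alignment lengths (mutL shortened from 1892 to 1890 bp so
#' the codon-aware mutator applies), plus one slow-evolving 16S-like
#' non-coding locus.
#'
#' @return data.frame with columns \code{name}, \code{length}, \code{coding}.
#' @export
defaultLocusSpecs <- function() {
    data.frame(
        name = c("adk", "aroE", "ccpA", "glpF", "gmk", "gyrA", "gyrB",
                 "ilvD", "mutL", "pta", "purH", "pycA", "pyrE", "rpoD",
                 "spo0A", "sucC", "tpiA", "rrs"),
        length = c(654L, 843L, 1005L, 828L, 615L, 2466L, 1917L, 1677L,
                   1890L, 972L, 1539L, 3450L, 651L, 1122L, 804L, 1158L,
                   762L, 1550L),
        coding = c(rep(TRUE, 17L), FALSE),
        stringsAsFactors = FALSE)
}

.DEFAULT_SPECIES <- c("B_subtilis", "B_siamensis", "B_velezensis",
                      "B_amyloliquefaciens", "B_atrophaeus")

#' Construct a simulator configuration
#'
#' Defaults emulate the published study design: 5 Bacillus species with
#' 6+3+5+4+3 = 21 strains, the 17 housekeeping loci (plus a 16S-like locus),
#' pairwise inter-species divergence 0.25 for protein loci and 0.008 for the
#' 16S-like locus, intra-species divergence 0.005 / 0.001, coding-locus
#' dN/dS target 0.4, and two planted B. subtilis-diagnostic window pairs on
#' pycA and aroE positioned so the planted primer pairs yield 233 bp and
#' 278 bp products.
#'
#' @param seed integer RNG seed (required).
#' @param speciesNames,strainsPerSpecies species labels and strain counts.
#' @param locusSpecs data.frame (\code{name}, \code{length}, \code{coding}).
#' @param pInter,pIntra per-locus substitution proportions; a scalar is
#'   recycled over loci (the 16S-like \code{rrs} locus keeps its own
#'   defaults unless explicitly named).
#' @param omegaTarget desired coding-locus dN/dS in (0, 1].
#' @param plantedWindows data.frame (\code{locus}, \code{targetSpecies},
#'   \code{start}, \code{windowLength}); \code{NULL} disables planting.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(seed,
                      speciesNames = .DEFAULT_SPECIES,
                      strainsPerSpecies = c(6L, 3L, 5L, 4L, 3L),
                      locusSpecs = defaultLocusSpecs(),
                      pInter = NULL, pIntra = NULL,
                      omegaTarget = 0.4,
                      plantedWindows = defaultPlantedWindows()) {
    mkRates <- function(x, codingDefault, rrsDefault) {
        out <- setNames(ifelse(locusSpecs$coding, codingDefault, rrsDefault),
                        locusSpecs$name)
        if (!is.null(x)) {
            if (is.null(names(x))) out[] <- x
            else out[names(x)] <- x
        }
        out
    }
    if (is.null(plantedWindows))
        plantedWindows <- data.frame(locus = character(),
                                     targetSpecies = character(),
                                     start = integer(),
                                     windowLength = integer(),
                                     stringsAsFactors = FALSE)
    new("SimConfig",
        speciesNames = speciesNames,
        strainsPerSpecies = as.integer(strainsPerSpecies),
        locusSpecs = locusSpecs,
        pInter = mkRates(pInter, 0.25, 0.008),
        pIntra = mkRates(pIntra, 0.005, 0.001),
        omegaTarget = omegaTarget,
        plantedWindows = plantedWindows,
        seed = as.integer(seed))
}

#' Default planted diagnostic windows
#'
#' Two windows per marker locus (a forward window and a downstream window
#' whose reverse complement serves as the reverse primer), spaced so the
#' planted pairs amplify 233 bp (pycA) and 278 bp (aroE) products from the
#' target species.
#'
#' @param targetSpecies species the windows are diagnostic for.
#' @return data.frame usable as \code{plantedWindows} in [simConfig()].
#' @export
defaultPlantedWindows <- function(targetSpecies = "B_subtilis") {
    data.frame(
        locus = c("pycA", "pycA", "aroE", "aroE"),
        targetSpecies = targetSpecies,
        start = c(1001L, 1212L, 301L, 558L),
        windowLength = c(20L, 22L, 20L, 21L),
        stringsAsFactors = FALSE)
}

#' Codon-aware point substitution with a target dN/dS
#'
#' Applies exactly \code{nSub} accepted substitutions.  Each proposal draws
#' a uniform site and a uniform alternative base; a proposal creating a stop
#' codon is always rejected, a synonymous proposal is always accepted, and a
#' nonsynonymous proposal is accepted with probability \code{omegaTarget}.
#' Rejected proposals are redrawn.  Uses the R RNG stream in effect (seed
#' with \code{set.seed()} for determinism).
#'
#' @param seq coding DNA string, length divisible by 3, no stop codons
#'   required (stops in frame are tolerated but never created).
#' @param nSub number of accepted substitutions, \code{< nchar(seq)}.
#' @param omegaTarget acceptance probability of nonsynonymous proposals.
#' @return the mutated DNA string.
#' @export
mutateCodonAware <- function(seq, nSub, omegaTarget) {
    seq <- toupper(as.character(seq))
    L <- nchar(seq)
    if (L %% 3L != 0L) stop("coding sequence length must be divisible by 3")
    if (nSub >= L) stop("nSub must be < sequence length")
    if (nSub == 0L) return(seq)
    ct <- .codonTables()
    b <- match(strsplit(seq, "")[[1]], .BASES)
    if (anyNA(b)) stop("coding sequence must be over A/C/G/T")
    accepted <- 0L
    tries <- 0L
    maxTries <- 1000L * (nSub + 1L)
    while (accepted < nSub) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop("mutateCodonAware: substitution target unreachable")
        i <- sample.int(L, 1L)
        nb <- ((b[i] - 1L + sample.int(3L, 1L)) %% 4L) + 1L
        cpos <- (i - 1L) %/% 3L
        p <- (i - 1L) %% 3L + 1L
        o <- cpos * 3L
        cidx <- .codonIndex(b[o + 1L], b[o + 2L], b[o + 3L])
        if (ct$stopRes[cidx, p, nb]) next
        if (ct$isStop[cidx]) next  # leave in-frame stops untouched
        if (!ct$synChange[cidx, p, nb] && stats::runif(1L) >= omegaTarget)
            next
        b[i] <- nb
        accepted <- accepted + 1L
    }
    paste(.BASES[b], collapse = "")
}

## neutral point substitution for non-coding loci: every proposal accepted
.mutateNeutral <- function(seq, nSub) {
    if (nSub == 0L) return(seq)
    b <- match(strsplit(seq, "")[[1]], .BASES)
    L <- length(b)
    for (k in seq_len(nSub)) {
        i <- sample.int(L, 1L)
        b[i] <- ((b[i] - 1L + sample.int(3L, 1L)) %% 4L) + 1L
    }
    paste(.BASES[b], collapse = "")
}

.randomRootSeq <- function(length, coding) {
    ct <- .codonTables()
    if (coding) {
        sense <- ct$codons[!ct$isStop]
        paste(sample(sense, length %/% 3L, replace = TRUE), collapse = "")
    } else {
        paste(sample(.BASES, length, replace = TRUE), collapse = "")
    }
}

## plant 4 substitutions inside [start, end] of a char-index vector, with at
## least one in the 3'-terminal 3 positions and one in the 5'-terminal 3
.plantWindowDivergence <- function(b, start, end) {
    wpos <- start:end
    tail3 <- wpos[(length(wpos) - 2L):length(wpos)]
    head3 <- wpos[1:3]
    chosen <- c(sample(tail3, 1L), sample(head3, 1L))
    rest <- setdiff(wpos, chosen)
    chosen <- c(chosen, sample(rest, 2L))
    for (i in chosen)
        b[i] <- ((b[i] - 1L + sample.int(3L, 1L)) %% 4L) + 1L
    b
}

#' Generate a synthetic strain panel with ground truth
#'
#' Star phylogeny per locus: one random root sequence, one species ancestor
#' per species at \code{floor(pInter x L / 2)} accepted substitutions from
#' the root (codon-aware for coding loci), and each strain at
#' \code{floor(pIntra x L)} substitutions from its species ancestor.
#' Planted windows are copied invariant into every target-species strain and
#' given 4 substitutions (>=1 in the 3'-terminal and 5'-terminal 3
#' positions) in every non-target species ancestor.
#'
#' @param config a [SimConfig-class].
#' @return list with elements \code{panel} (a [StrainPanel-class]) and
#'   \code{truth} (list: \code{species}, \code{allelePartitions},
#'   \code{windows}, \code{expectedAmplicons}).
#' @export
generatePanel <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    ls <- config@locusSpecs
    species <- rep(config@speciesNames, config@strainsPerSpecies)
    strainIds <- unlist(lapply(seq_along(config@speciesNames), function(k)
        paste0(config@speciesNames[k], "_s",
               seq_len(config@strainsPerSpecies[k]))))
    strains <- data.frame(strain_id = strainIds, species = species,
                          stringsAsFactors = FALSE)
    pw <- config@plantedWindows
    sequences <- list()
    windowRows <- list()
    for (li in seq_len(nrow(ls))) {
        loc <- ls$name[li]; L <- ls$length[li]; coding <- ls$coding[li]
        set.seed(.subSeed(config@seed, loc, "root"))
        root <- .randomRootSeq(L, coding)
        rootB <- match(strsplit(root, "")[[1]], .BASES)
        wloc <- pw[pw$locus == loc, , drop = FALSE]
        nInter <- as.integer(floor(config@pInter[[loc]] * L / 2))
        nIntra <- as.integer(floor(config@pIntra[[loc]] * L))
        locSeqs <- character(nrow(strains))
        for (k in seq_along(config@speciesNames)) {
            sp <- config@speciesNames[k]
            set.seed(.subSeed(config@seed, loc, sp, "ancestor"))
            anc <- if (coding) mutateCodonAware(root, nInter, config@omegaTarget)
                   else .mutateNeutral(root, nInter)
            ancB <- match(strsplit(anc, "")[[1]], .BASES)
            if (nrow(wloc)) {
                for (wi in seq_len(nrow(wloc))) {
                    ws <- wloc$start[wi]
                    we <- ws + wloc$windowLength[wi] - 1L
                    ## restore the root window, then diverge non-targets
                    ancB[ws:we] <- rootB[ws:we]
                    if (sp != wloc$targetSpecies[wi]) {
                        set.seed(.subSeed(config@seed, loc, sp, "window", wi))
                        ancB <- .plantWindowDivergence(ancB, ws, we)
                    }
                }
                anc <- paste(.BASES[ancB], collapse = "")
            }
            myStrains <- which(strains$species == sp)
            for (si in myStrains) {
                id <- strains$strain_id[si]
                set.seed(.subSeed(config@seed, loc, sp, id))
                s <- if (coding) mutateCodonAware(anc, nIntra, config@omegaTarget)
                     else .mutateNeutral(anc, nIntra)
                if (nrow(wloc)) {
                    sB <- match(strsplit(s, "")[[1]], .BASES)
                    for (wi in seq_len(nrow(wloc))) {
                        if (sp != wloc$targetSpecies[wi]) next
                        ws <- wloc$start[wi]
                        we <- ws + wloc$windowLength[wi] - 1L
                        sB[ws:we] <- ancB[ws:we]   # invariant in target species
                    }
                    s <- paste(.BASES[sB], collapse = "")
                }
                locSeqs[si] <- s
            }
        }
        ss <- DNAStringSet(locSeqs)
        names(ss) <- strains$strain_id
        sequences[[loc]] <- ss
        if (nrow(wloc)) {
            wloc$end <- wloc$start + wloc$windowLength - 1L
            wloc$seq <- vapply(seq_len(nrow(wloc)), function(wi)
                substr(root, wloc$start[wi], wloc$end[wi]), character(1))
            windowRows[[loc]] <- wloc
        }
    }
    panel <- new("StrainPanel", strains = strains, loci = ls$name,
                 sequences = sequences, referenceStrain = strainIds[1L])
    windows <- if (length(windowRows)) do.call(rbind, windowRows) else
        data.frame(locus = character(), targetSpecies = character(),
                   start = integer(), windowLength = integer(),
                   end = integer(), seq = character(),
                   stringsAsFactors = FALSE)
    rownames(windows) <- NULL
    ## expected amplicon per (locus, target): first window = forward
    ## footprint, last window = reverse footprint
    amps <- list()
    if (nrow(windows)) {
        for (key in unique(paste(windows$locus, windows$targetSpecies))) {
            w <- windows[paste(windows$locus, windows$targetSpecies) == key, ]
            if (nrow(w) < 2L) next
            w <- w[order(w$start), ]
            amps[[key]] <- data.frame(
                locus = w$locus[1L], targetSpecies = w$targetSpecies[1L],
                product_bp = w$end[nrow(w)] - w$start[1L] + 1L,
                stringsAsFactors = FALSE)
        }
    }
    expectedAmplicons <- if (length(amps)) do.call(rbind, amps) else
        data.frame(locus = character(), targetSpecies = character(),
                   product_bp = integer(), stringsAsFactors = FALSE)
    rownames(expectedAmplicons) <- NULL
    allelePartitions <- lapply(ls$name, function(loc) {
        s <- as.character(sequences[[loc]])
        unname(split(names(s), match(s, unique(s))))
    })
    names(allelePartitions) <- ls$name
    truth <- list(
        species = setNames(strains$species, strains$strain_id),
        allelePartitions = allelePartitions,
        windows = windows,
        expectedAmplicons = expectedAmplicons)
    list(panel = panel, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' One FASTA per locus, a metadata TSV in the [readStrainTable()] dialect,
#' and the ground truth as JSON.  Re-reading with [readStrainTable()] and
#' [buildPanel()] reproduces the panel exactly.
#'
#' @param panel a [StrainPanel-class].
#' @param truth truth list from [generatePanel()] (optional; skipped when
#'   \code{NULL}).
#' @param outDir output directory, created if needed.
#' @return invisibly, a character vector of the files written.
#' @export
emitDataset <- function(panel, truth = NULL, outDir) {
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
        stop(sprintf("cannot create output directory %s", outDir))
    files <- character(0)
    meta <- list()
    for (loc in panelLoci(panel)) {
        ss <- locusSequences(panel, loc)
        fp <- file.path(outDir, paste0(loc, ".fasta"))
        writeFasta(ss, fp)
        files <- c(files, fp)
        meta[[loc]] <- data.frame(
            strain_id = names(ss),
            species = speciesLabels(panel)[names(ss)],
            locus = loc,
            fasta_path = paste0(loc, ".fasta"),
            seq_id = names(ss),
            stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, meta)
    ## strain-major order so first-appearance strain order round-trips
    tab <- tab[order(match(tab$strain_id, strainNames(panel)),
                     match(tab$locus, panelLoci(panel))), ]
    mf <- file.path(outDir, "metadata.tsv")
    write.table(tab, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, mf)
    if (!is.null(truth)) {
        tf <- file.path(outDir, "truth.json")
        jsonlite::write_json(truth, tf, auto_unbox = FALSE, digits = NA,
                             pretty = TRUE)
        files <- c(files, tf)
    }
    invisible(files)
}

#' Read a simulator configuration from YAML or JSON
#'
#' All [simConfig()] fields have defaults except \code{seed}.  Recognized
#' keys: \code{seed}, \code{species_names}, \code{strains_per_species},
#' \code{locus_specs} (records with name/length/coding), \code{p_inter},
#' \code{p_intra}, \code{omega_target}, \code{planted_windows} (records with
#' locus/target_species/start/window_length or \code{null}).
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(cfg$seed)) stop("config must set 'seed'")
    args <- list(seed = cfg$seed)
    if (!is.null(cfg$species_names)) args$speciesNames <- unlist(cfg$species_names)
    if (!is.null(cfg$strains_per_species))
        args$strainsPerSpecies <- unlist(cfg$strains_per_species)
    if (!is.null(cfg$locus_specs)) {
        lsp <- as.data.frame(do.call(rbind, lapply(cfg$locus_specs, as.data.frame)))
        lsp$length <- as.integer(lsp$length); lsp$coding <- as.logical(lsp$coding)
        args$locusSpecs <- lsp
    }
    if (!is.null(cfg$p_inter)) args$pInter <- unlist(cfg$p_inter)
    if (!is.null(cfg$p_intra)) args$pIntra <- unlist(cfg$p_intra)
    if (!is.null(cfg$omega_target)) args$omegaTarget <- cfg$omega_target
    if (!is.null(cfg$planted_windows)) {
        pw <- as.data.frame(do.call(rbind,
            lapply(cfg$planted_windows, as.data.frame)))
        names(pw) <- sub("target_species", "targetSpecies",
                         sub("window_length", "windowLength", names(pw)))
        pw$start <- as.integer(pw$start)
        pw$windowLength <- as.integer(pw$windowLength)
        args$plantedWindows <- pw
    } else if ("planted_windows" %in% names(cfg)) {
        args["plantedWindows"] <- list(NULL)   # explicit null disables planting
    }
    do.call(simConfig, args)
}
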