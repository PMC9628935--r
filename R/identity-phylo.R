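## Percent identity, scheme concatenation, p-distances, neighbor joining.

#' Needleman-Wunsch global alignment
#'
#' Linear gap penalty; defaults \code{match = +1}, \code{mismatch = -1},
#' \code{gap = -2}.  \code{N} scores as a mismatch against everything
#' (including another \code{N}).
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap alignment scores (gap per gapped column).
#' @return list with \code{alignedA}, \code{alignedB} (gapped strings of
#'   equal length) and \code{score}.
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (!nzchar(a) || !nzchar(b))
        stop("both sequences must be non-empty")
    letters <- c("A", "C", "G", "T", "N")
    sm <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
    diag(sm) <- match
    sm["N", "N"] <- mismatch   # N never counts as a match
    aln <- Biostrings::pairwiseAlignment(
        pattern = a, subject = b, type = "global",
        substitutionMatrix = sm, gapOpening = 0, gapExtension = abs(gap))
    list(alignedA = as.character(Biostrings::alignedPattern(aln)),
         alignedB = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln))
}

.identityFromAlignment <- function(ga, gb) {
    ca <- strsplit(ga, "")[[1]]
    cb <- strsplit(gb, "")[[1]]
    keep <- !(ca == "-" & cb == "-")   # NW never emits these, but be safe
    ca <- ca[keep]; cb <- cb[keep]
    matched <- sum(ca == cb & ca != "-" & ca != "N")
    100 * matched / length(ca)
}

#' Percent identity of two sequences
#'
#' Sequences are globally aligned ([globalAlign()]); identity is 100 x
#' matched columns / alignment columns (doubly-gapped columns excluded,
#' singly-gapped columns counted as mismatches — the BLAST-like
#' "alignment length" convention).
#'
#' @inheritParams globalAlign
#' @return percentage in \[0, 100\].
#' @examples
#' percentIdentity("ACGT", "ACGA")  # 75
#' @export
percentIdentity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    aln <- globalAlign(a, b, match, mismatch, gap)
    .identityFromAlignment(aln$alignedA, aln$alignedB)
}

#' Polymorphic sites of a sequence relative to a reference
#'
#' The two sequences are globally aligned and columns where both characters
#' are unambiguous bases (\code{A/C/G/T}) and differ are counted.
#'
#' @param seq,ref DNA strings.
#' @return integer count.
#' @export
polymorphicSitesVsReference <- function(seq, ref) {
    aln <- globalAlign(seq, ref)
    ca <- strsplit(aln$alignedA, "")[[1]]
    cb <- strsplit(aln$alignedB, "")[[1]]
    ok <- ca %in% .BASES & cb %in% .BASES
    sum(ok & ca != cb)
}

#' Built-in MLST concatenation schemes
#'
#' The five published schemes bundled with the package: the public
#' B. subtilis scheme (pubMLST) plus the S1-S3 B. subtilis schemes and the
#' L1 B. licheniformis scheme.  Gene names are canonicalized to the
#' seventeen panel locus names (printed variants ptA/pur/tpi are stored as
#' pta/purH/tpiA so schemes resolve against panels).
#'
#' @return named list of [MLSTScheme-class] objects.
#' @export
mlstSchemes <- function() {
    defs <- list(
        pubMLST = c("glpF", "ilvD", "pta", "purH", "pycA", "rpoD", "tpiA"),
        S1 = c("rpoD", "glpF", "ilvD", "pta", "tpiA", "pycA", "purH"),
        S2 = c("gyrA", "gyrB", "purH", "glpF", "pycA", "ilvD", "rpoD",
               "tpiA", "pta"),
        S3 = c("gyrB", "adk", "pycA", "pyrE", "sucC", "mutL", "aroE"),
        L1 = c("adk", "ccpA", "glpF", "gmk", "ilvD", "purH", "spo0A", "tpiA")
    )
    lapply(names(defs), function(nm)
        new("MLSTScheme", name = nm, geneOrder = defs[[nm]])) |>
        setNames(names(defs))
}

#' Concatenate panel loci in scheme order
#'
#' @param panel a [StrainPanel-class].
#' @param scheme an [MLSTScheme-class].
#' @return named \code{DNAStringSet}, one concatenated sequence per strain;
#'   strains missing any scheme locus are excluded with a warning.
#' @export
concatenateScheme <- function(panel, scheme) {
    stopifnot(is(panel, "StrainPanel"), is(scheme, "MLSTScheme"))
    genes <- geneOrder(scheme)
    absent <- setdiff(genes, panelLoci(panel))
    if (length(absent))
        stop(sprintf("scheme %s locus(loci) absent from panel: %s",
                     schemeName(scheme), paste(absent, collapse = ", ")))
    perLocus <- lapply(genes, function(g) locusSequences(panel, g))
    keep <- Reduce(intersect, lapply(perLocus, names), strainNames(panel))
    dropped <- setdiff(strainNames(panel), keep)
    if (length(dropped))
        warning(sprintf("strain(s) missing a scheme locus excluded: %s",
                        paste(dropped, collapse = ", ")))
    if (!length(keep))
        stop("no strain has every scheme locus")
    parts <- lapply(perLocus, function(ss) ss[keep])
    out <- do.call(xscat, parts)
    names(out) <- keep
    out
}

#' Pairwise p-distance matrix
#'
#' \eqn{d_{ij}} is the proportion of differing sites among sites where both
#' sequences carry an unambiguous base (pairwise deletion of \code{N}/gap
#' sites).
#'
#' @param seqs named equal-length character vector or \code{DNAStringSet}.
#' @return symmetric numeric matrix with strain ids as dimnames.
#' @export
pDistanceMatrix <- function(seqs) {
    s <- .asSeqVector(seqs)
    .checkEqualLength(s)
    if (length(s) < 2L) stop("need at least 2 sequences")
    bin <- ape::as.DNAbin(t(sapply(strsplit(s, ""), identity)))
    rownames(bin) <- names(s)
    d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
    m <- as.matrix(d)
    if (any(!is.finite(m)))
        stop("a pair of sequences has zero comparable sites")
    m
}

## Clamp negative NJ branch lengths to zero, transferring the deficit to the
## sister branch so path lengths through the parent are preserved.
.clampNegativeEdges <- function(tree) {
    el <- tree$edge.length
    for (i in seq_along(el)) {
        if (el[i] < 0) {
            parent <- tree$edge[i, 1L]
            sib <- which(tree$edge[, 1L] == parent)
            sib <- setdiff(sib, i)
            if (length(sib))
                el[sib[1L]] <- el[sib[1L]] + el[i]
            el[i] <- 0
        }
    }
    el[el < 0] <- 0
    tree$edge.length <- el
    tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with the deficit transferred to the sister branch.
#' With fewer than 3 taxa a trivial tree is returned with a warning.
#'
#' @param D symmetric distance matrix with labels as dimnames (e.g. from
#'   [pDistanceMatrix()]).
#' @return an [ape::phylo] tree whose tips are the matrix labels.
#' @export
neighborJoining <- function(D) {
    D <- as.matrix(D)
    if (is.null(rownames(D)))
        stop("distance matrix needs labels as dimnames")
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
        stop("distance matrix must be symmetric")
    n <- nrow(D)
    if (n < 3L) {
        warning("fewer than 3 taxa: returning trivial tree")
        if (n == 2L) {
            tree <- ape::read.tree(
                text = sprintf("(%s:%f,%s:%f);", rownames(D)[1L], D[1, 2] / 2,
                               rownames(D)[2L], D[1, 2] / 2))
            return(tree)
        }
        stop("cannot build a tree from fewer than 2 taxa")
    }
    tree <- ape::nj(D)
    .clampNegativeEdges(tree)
}

#' Are species monophyletic on a tree?
#'
#' A species is monophyletic on an unrooted tree when its strains form one
#' side of some edge bipartition.
#'
#' @param tree an [ape::phylo] whose tips are strain ids.
#' @param species named character vector strain id -> species label.
#' @return named logical, one entry per species.
#' @export
speciesMonophyletic <- function(tree, species) {
    tips <- tree$tip.label
    sp <- species[tips]
    if (anyNA(sp)) stop("species label missing for some tips")
    parts <- ape::prop.part(tree)
    clades <- lapply(parts, function(ix) tips[ix])
    out <- logical(0)
    for (s in unique(sp)) {
        mine <- tips[sp == s]
        ok <- length(mine) == 1L ||
            length(mine) == length(tips) ||
            any(vapply(clades, function(cl)
                setequal(cl, mine) || setequal(cl, setdiff(tips, mine)),
                logical(1)))
        out[s] <- ok
    }
    out
}

#' Within- and between-species identity ranges at one locus
#'
#' Minimum and maximum percent identity over all within-species strain pairs
#' and over all between-species pairs.  When every sequence at the locus has
#' equal length and no gaps (the simulator's output), identity is computed
#' directly per column; otherwise pairs are globally aligned.
#'
#' @param panel a [StrainPanel-class].
#' @param locus locus name.
#' @param method \code{"auto"} (default), \code{"hamming"} or
#'   \code{"align"}.
#' @return list with numeric ranges \code{within} and \code{between}
#'   (each \code{c(min, max)}, \code{NA} when no such pair exists).
#' @export
speciesIdentitySummary <- function(panel, locus,
                                   method = c("auto", "hamming", "align")) {
    method <- match.arg(method)
    seqs <- as.character(locusSequences(panel, locus))
    if (length(seqs) < 2L)
        stop("need at least 2 strains with data at the locus")
    sp <- speciesLabels(panel)[names(seqs)]
    eqlen <- length(unique(nchar(seqs))) == 1L && !any(grepl("-", seqs, fixed = TRUE))
    if (method == "hamming" && !eqlen)
        stop("hamming identity requires equal-length, gap-free sequences")
    useHamming <- method == "hamming" || (method == "auto" && eqlen)
    chars <- if (useHamming) strsplit(seqs, "") else NULL
    pid <- function(i, j) {
        if (useHamming) {
            ca <- chars[[i]]; cb <- chars[[j]]
            100 * sum(ca == cb & ca != "N") / length(ca)
        } else percentIdentity(seqs[[i]], seqs[[j]])
    }
    win <- numeric(0); btw <- numeric(0)
    idx <- combn(length(seqs), 2L)
    for (p in seq_len(ncol(idx))) {
        i <- idx[1L, p]; j <- idx[2L, p]
        v <- pid(i, j)
        if (sp[i] == sp[j]) win <- c(win, v) else btw <- c(btw, v)
    }
    list(within = if (length(win)) range(win) else c(NA_real_, NA_real_),
         between = if (length(btw)) range(btw) else c(NA_real_, NA_real_))
}

#' Minimum between-species identity per locus
#'
#' Convenience wrapper building the identity table [rankMarkers()] consumes.
#'
#' @param panel a [StrainPanel-class].
#' @param loci loci to include (default: all panel loci).
#' @return data.frame with columns \code{locus}, \code{min_between_identity},
#'   \code{max_between_identity}, \code{min_within_identity},
#'   \code{max_within_identity}.
#' @export
identitySummaryTable <- function(panel, loci = panelLoci(panel)) {
    rows <- lapply(loci, function(loc) {
        r <- speciesIdentitySummary(panel, loc)
        data.frame(locus = loc,
                   min_between_identity = r$between[1L],
                   max_between_identity = r$between[2L],
                   min_within_identity = r$within[1L],
                   max_within_identity = r$within[2L],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a distance matrix as square TSV
#'
#' @param D matrix from [pDistanceMatrix()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDistanceMatrix <- function(D, path) {
    df <- data.frame(strain = rownames(D), D, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
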