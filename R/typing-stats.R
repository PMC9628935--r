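## Per-locus MLST discrimination statistics: alleles, polymorphic sites,
## typing efficiency, Hunter-Gaston discriminatory power, Nei-Gojobori dN/dS.

.asSeqVector <- function(locusSeqs) {
    if (is(locusSeqs, "DNAStringSet")) {
        out <- as.character(locusSeqs)
    } else if (is.character(locusSeqs)) {
        out <- toupper(locusSeqs)
    } else stop("locus sequences must be a DNAStringSet or character vector")
    if (length(out) == 0L)
        stop("no sequences supplied")
    if (is.null(names(out)) || any(!nzchar(names(out))))
        stop("locus sequences must be named by strain id")
    out
}

.checkEqualLength <- function(seqs) {
    w <- nchar(seqs)
    if (length(unique(w)) > 1L) {
        bad <- names(seqs)[w != w[1L]]
        stop(sprintf("sequences differ in length (e.g. %s); align first",
                     paste(head(bad, 3L), collapse = ", ")))
    }
    w[1L]
}

#' Call alleles at one locus by exact sequence identity
#'
#' Strains with identical sequences share an allele; allele ids are assigned
#' 1..k in order of first occurrence.
#'
#' @param locusSeqs named character vector or \code{DNAStringSet}: strain ->
#'   equal-length locus sequence.
#' @param locus locus name recorded in the result.
#' @return an [AlleleTable-class].
#' @examples
#' callAlleles(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"))
#' @export
callAlleles <- function(locusSeqs, locus = "locus") {
    seqs <- .asSeqVector(locusSeqs)
    .checkEqualLength(seqs)
    ids <- match(seqs, unique(seqs))
    counts <- as.integer(tabulate(ids))
    new("AlleleTable", locus = locus,
        assignment = setNames(as.integer(ids), names(seqs)),
        counts = counts, N = length(seqs))
}

## integer base matrix (strains x sites): A,C,G,T = 1..4, else NA
.baseMatrix <- function(seqs) {
    L <- .checkEqualLength(seqs)
    m <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE), .BASES),
                nrow = length(seqs), ncol = L, byrow = TRUE)
    rownames(m) <- names(seqs)
    m
}

#' Count polymorphic sites at one locus
#'
#' A column is polymorphic when at least two distinct bases from
#' \code{A/C/G/T} occur in it.  Columns containing \code{N} or \code{-} in
#' any sequence are skipped entirely (conservative SNP-calling convention).
#'
#' @inheritParams callAlleles
#' @return integer count of polymorphic columns.
#' @export
countPolymorphicSites <- function(locusSeqs) {
    seqs <- .asSeqVector(locusSeqs)
    m <- .baseMatrix(seqs)
    clean <- colSums(is.na(m)) == 0L
    if (!any(clean)) return(0L)
    mm <- m[, clean, drop = FALSE]
    poly <- colSums(mm != rep(mm[1L, ], each = nrow(mm))) > 0L
    sum(poly)
}

#' Typing efficiency of a locus
#'
#' The number of genotypes (alleles) per polymorphic site,
#' \eqn{TE = k / P}.  Undefined for a monomorphic locus (\eqn{P = 0}).
#'
#' @param nAlleles allele count \eqn{k}.
#' @param nPolymorphicSites polymorphic-site count \eqn{P}.
#' @return \eqn{k / P} at full precision.
#' @examples
#' round(typingEfficiency(19, 1075), 3)  # 0.018
#' @export
typingEfficiency <- function(nAlleles, nPolymorphicSites) {
    if (nPolymorphicSites < 0 || nAlleles < 1)
        stop("need nAlleles >= 1 and nPolymorphicSites >= 0")
    if (nPolymorphicSites == 0)
        stop("typing efficiency is undefined for a monomorphic locus")
    nAlleles / nPolymorphicSites
}

#' Hunter-Gaston discriminatory power
#'
#' Probability that two strains drawn at random (without replacement) carry
#' different alleles:
#' \deqn{DP = 1 - \frac{\sum_j n_j (n_j - 1)}{N (N - 1)}}
#'
#' @param x an [AlleleTable-class], or an integer vector of allele counts
#'   \eqn{n_j}.
#' @return DP in \[0, 1\].
#' @export
discriminatoryPower <- function(x) {
    counts <- if (is(x, "AlleleTable")) alleleCounts(x) else as.integer(x)
    N <- sum(counts)
    if (N < 2L)
        stop("discriminatory power requires at least 2 typed strains")
    1 - sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of a codon
#'
#' For each of the nine single-base alternatives the change is classified
#' under the standard genetic code (changes to stop codons count as
#' nonsynonymous); the synonymous site count is the per-position synonymous
#' fraction summed over the three positions, and \eqn{s + n = 3}.
#'
#' @param codon a 3-character string over \code{A/C/G/T}, not a stop codon.
#' @return named numeric \code{c(s = ..., n = ...)}; \code{c(NA, NA)} with a
#'   \code{"skipped"} attribute for stop codons or ambiguous bases.
#' @examples
#' neiGojoboriSites("TTT")  # s = 1/3
#' @export
neiGojoboriSites <- function(codon) {
    ct <- .codonTables()
    if (nchar(codon) != 3L)
        stop("codon must be 3 nt")
    idx <- .toCodonIndices(toupper(codon))
    if (is.na(idx) || ct$isStop[idx]) {
        out <- c(s = NA_real_, n = NA_real_)
        attr(out, "skipped") <- TRUE
        return(out)
    }
    s <- ct$sSites[idx]
    c(s = s, n = 3 - s)
}

#' Pathway-averaged codon difference counts
#'
#' Observed synonymous/nonsynonymous differences between two sense codons,
#' averaged with equal weight over all minimal substitution pathways
#' (pathways through stop codons excluded; if every pathway is blocked the
#' average is over all pathways).
#'
#' @param codonA,codonB 3-character codons over \code{A/C/G/T}.
#' @return named numeric \code{c(sd = ..., nd = ...)}.
#' @export
codonDiffCounts <- function(codonA, codonB) {
    ct <- .codonTables()
    i <- .toCodonIndices(toupper(codonA))
    j <- .toCodonIndices(toupper(codonB))
    if (is.na(i) || is.na(j) || ct$isStop[i] || ct$isStop[j])
        stop("both codons must be unambiguous sense codons")
    pm <- .pairCountMatrices()
    c(sd = pm$sd[i, j], nd = pm$nd[i, j])
}

#' Pairwise Nei-Gojobori dN and dS with Jukes-Cantor correction
#'
#' Codons containing an ambiguous base, a gap, or a stop codon in either
#' sequence are skipped pairwise.  Proportions are corrected by
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; a proportion \eqn{\ge 3/4}
#' is saturated and reported as \code{NA} with \code{saturated = TRUE}.
#'
#' @param seqA,seqB coding DNA strings of equal length divisible by 3.
#' @return list with \code{dN}, \code{dS}, raw counts \code{Sd}, \code{Nd},
#'   site totals \code{S}, \code{N}, proportions \code{pS}, \code{pN},
#'   number of compared codons \code{codons}, and \code{saturated}.
#' @export
pairwiseDnds <- function(seqA, seqB) {
    seqA <- toupper(as.character(seqA)); seqB <- toupper(as.character(seqB))
    if (nchar(seqA) != nchar(seqB))
        stop("sequences must have equal length")
    ct <- .codonTables()
    pm <- .pairCountMatrices()
    ia <- .toCodonIndices(seqA)
    ib <- .toCodonIndices(seqB)
    ok <- !is.na(ia) & !is.na(ib) & !ct$isStop[pmax(ia, 1L)] &
          !ct$isStop[pmax(ib, 1L)]
    ok[is.na(ok)] <- FALSE
    Lc <- sum(ok)
    if (Lc == 0L)
        stop("no comparable codons")
    ia <- ia[ok]; ib <- ib[ok]
    S <- (sum(ct$sSites[ia]) + sum(ct$sSites[ib])) / 2
    Nn <- 3 * Lc - S
    Sd <- sum(pm$sd[cbind(ia, ib)])
    Nd <- sum(pm$nd[cbind(ia, ib)])
    pS <- Sd / S
    pN <- Nd / Nn
    jc <- function(p) {
        if (p >= 0.75) return(NA_real_)
        -0.75 * log(1 - 4 * p / 3)
    }
    dS <- jc(pS); dN <- jc(pN)
    list(dN = dN, dS = dS, Sd = Sd, Nd = Nd, S = S, N = Nn,
         pS = pS, pN = pN, codons = Lc,
         saturated = is.na(dN) || is.na(dS))
}

#' Locus-wide dN/dS ratio
#'
#' Mean pairwise dN over all unordered strain pairs divided by mean pairwise
#' dS; pairs with a saturated (undefined) correction are excluded with a
#' message.
#'
#' @inheritParams callAlleles
#' @return the ratio, or \code{NA} when mean dS is 0 (no synonymous
#'   divergence) or no pair is usable.
#' @export
locusDnds <- function(locusSeqs) {
    seqs <- .asSeqVector(locusSeqs)
    if (length(seqs) < 2L)
        stop("need at least 2 sequences")
    .checkEqualLength(seqs)
    pairs <- combn(length(seqs), 2L)
    dN <- numeric(0); dS <- numeric(0); nSat <- 0L
    for (p in seq_len(ncol(pairs))) {
        r <- pairwiseDnds(seqs[[pairs[1L, p]]], seqs[[pairs[2L, p]]])
        if (r$saturated) { nSat <- nSat + 1L; next }
        dN <- c(dN, r$dN); dS <- c(dS, r$dS)
    }
    if (nSat > 0L)
        message(sprintf("locusDnds: %d saturated pair(s) excluded", nSat))
    if (!length(dS)) return(NA_real_)
    mS <- mean(dS)
    if (mS == 0) return(NA_real_)
    mean(dN) / mS
}

#' Summarize every panel locus
#'
#' One row per locus with alignment length, allele count, polymorphic sites,
#' locus dN/dS, typing efficiency and Hunter-Gaston discriminatory power.
#' Failures of individual statistics (e.g. TE on a monomorphic locus) are
#' recorded as \code{NA} rather than aborting the table.
#'
#' @param panel a [StrainPanel-class].
#' @param codingLoci loci on which dN/dS is computed; defaults to loci whose
#'   alignment length is divisible by 3.
#' @return data.frame with columns \code{locus}, \code{length_bp},
#'   \code{n_alleles}, \code{n_polymorphic_sites}, \code{dnds}, \code{te},
#'   \code{dp}, plus an attribute \code{meanDnds} (column mean over
#'   non-missing values).
#' @export
summarizeLoci <- function(panel, codingLoci = NULL) {
    stopifnot(is(panel, "StrainPanel"))
    loci <- panelLoci(panel)
    if (!length(loci)) stop("panel has no loci")
    rows <- vector("list", length(loci))
    for (i in seq_along(loci)) {
        loc <- loci[i]
        seqs <- locusSequences(panel, loc)
        at <- callAlleles(seqs, locus = loc)
        nPoly <- countPolymorphicSites(seqs)
        isCoding <- if (is.null(codingLoci))
            (width(seqs)[1L] %% 3L == 0L) else (loc %in% codingLoci)
        dnds <- if (isCoding && length(seqs) >= 2L)
            suppressMessages(tryCatch(locusDnds(seqs), error = function(e) NA_real_))
        else NA_real_
        te <- tryCatch(typingEfficiency(length(alleleCounts(at)), nPoly),
                       error = function(e) NA_real_)
        dp <- tryCatch(discriminatoryPower(at), error = function(e) NA_real_)
        rows[[i]] <- data.frame(
            locus = loc, length_bp = width(seqs)[1L],
            n_alleles = length(alleleCounts(at)),
            n_polymorphic_sites = nPoly,
            dnds = dnds, te = te, dp = dp,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "meanDnds") <- mean(out$dnds, na.rm = TRUE)
    out
}

#' Format a locus summary for display or TSV export
#'
#' TE is rounded to 3 decimals and dN/dS to 4 (display precision only; all
#' internal math is full precision); a footer row carries the dN/dS column
#' mean.  \code{NA} is encoded as \code{"NA"} when written.
#'
#' @param stats data.frame from [summarizeLoci()].
#' @param path optional TSV output path.
#' @return the formatted data.frame (invisibly when \code{path} is given).
#' @export
formatLocusStats <- function(stats, path = NULL) {
    fmt <- data.frame(
        locus = stats$locus,
        length_bp = stats$length_bp,
        n_alleles = stats$n_alleles,
        n_polymorphic_sites = stats$n_polymorphic_sites,
        dnds = round(stats$dnds, 4),
        te = round(stats$te, 3),
        dp = round(stats$dp, 3),
        stringsAsFactors = FALSE)
    footer <- data.frame(locus = "mean", length_bp = NA, n_alleles = NA,
                         n_polymorphic_sites = NA,
                         dnds = round(mean(stats$dnds, na.rm = TRUE), 4),
                         te = NA, dp = NA, stringsAsFactors = FALSE)
    fmt <- rbind(fmt, footer)
    if (!is.null(path)) {
        write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    na = "NA")
        return(invisible(fmt))
    }
    fmt
}

#' Rank loci as candidate species-discrimination markers
#'
#' Two rankings: (a) by descending polymorphic-site count (ties broken by
#' descending allele count, then locus name), the criterion that flags pycA
#' in the source panel; (b) by ascending minimum inter-species identity
#' (lowest cross-species homology first), the criterion that flags aroE.
#'
#' @param stats data.frame from [summarizeLoci()].
#' @param identitySummary data.frame with columns \code{locus} and
#'   \code{min_between_identity} (e.g. built from
#'   [speciesIdentitySummary()] over the panel loci).
#' @return list with \code{bySites} and \code{byIdentity} (ranked locus
#'   character vectors) and \code{candidates} (top locus of each ranking).
#' @export
rankMarkers <- function(stats, identitySummary) {
    if (!nrow(stats)) stop("empty locus stats")
    if (!all(c("locus", "min_between_identity") %in% names(identitySummary)))
        stop("identitySummary needs columns locus and min_between_identity")
    if (!setequal(stats$locus, identitySummary$locus))
        stop("stats and identitySummary must cover the same loci")
    oA <- order(-stats$n_polymorphic_sites, -stats$n_alleles, stats$locus)
    bySites <- stats$locus[oA]
    idt <- identitySummary[match(stats$locus, identitySummary$locus), ]
    oB <- order(idt$min_between_identity, idt$locus)
    byIdentity <- idt$locus[oB]
    list(bySites = bySites, byIdentity = byIdentity,
         candidates = unique(c(bySites[1L], byIdentity[1L])))
}
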