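## Species-specific window discovery, primer pair design, in-silico PCR.

#' Constructors for primers and primer pairs
#'
#' @param name primer name.
#' @param seq 5'->3' sequence over A/C/G/T, 18-30 nt.
#' @return a [Primer-class].
#' @export
primer <- function(name, seq) {
    seq <- toupper(as.character(seq))
    new("Primer", name = name, seq = seq, tm = primerTm(seq))
}

#' @rdname primer
#' @param forward,reverse [Primer-class] objects (or 5'->3' strings, which
#'   are wrapped).
#' @param expectedSize expected product size in bp (NA if unknown).
#' @export
primerPair <- function(forward, reverse, expectedSize = NA_integer_) {
    if (is.character(forward)) forward <- primer("F", forward)
    if (is.character(reverse)) reverse <- primer("R", reverse)
    new("PrimerPair", forward = forward, reverse = reverse,
        expectedSize = as.integer(expectedSize))
}

#' In-silico PCR parameter set
#'
#' @param maxMismatches maximum mismatches per primer site (default 2).
#' @param anchorLen 3'-terminal bases where no mismatch is tolerated
#'   (default 3).
#' @param minProduct,maxProduct product length bounds in bp (defaults
#'   50-5000).
#' @param bothStrands consider both template orientations (default TRUE).
#' @return a [PCRParams-class].
#' @export
pcrParams <- function(maxMismatches = 2L, anchorLen = 3L,
                      minProduct = 50L, maxProduct = 5000L,
                      bothStrands = TRUE) {
    new("PCRParams", maxMismatches = as.integer(maxMismatches),
        anchorLen = as.integer(anchorLen), minProduct = as.integer(minProduct),
        maxProduct = as.integer(maxProduct), bothStrands = bothStrands)
}

#' The published B. subtilis-diagnostic primer pairs
#'
#' The pycA (pyruvate carboxylase) and aroE (shikimate dehydrogenase) pairs
#' with their expected product sizes (233 and 278 bp).
#'
#' @return named list of [PrimerPair-class] objects.
#' @export
bundledPrimers <- function() {
    list(
        pycA = primerPair(primer("pycA-F", "GTCTTCCGTTCAGGAAAGGC"),
                          primer("pycA-R", "GATCTCCCGTTTGGATCGGCTC"),
                          expectedSize = 233L),
        aroE = primerPair(primer("aroE-F", "GGGGAAGGCTTCGTGAAGTC"),
                          primer("aroE-R", "CCCACAGACGTTGTATGGATG"),
                          expectedSize = 278L))
}

#' Wallace-rule melting temperature
#'
#' \eqn{T_m = 2(A + T) + 4(G + C)} degrees C; composition-only, so
#' \code{primerTm(x) == primerTm(reverseComplement(x))}.
#'
#' @param seq DNA string, length >= 10.
#' @return melting temperature in degrees C.
#' @export
primerTm <- function(seq) {
    seq <- toupper(as.character(seq))
    if (nchar(seq) < 10L) stop("Tm rule requires length >= 10")
    ch <- strsplit(seq, "")[[1]]
    at <- sum(ch %in% c("A", "T"))
    gc <- sum(ch %in% c("G", "C"))
    if (at + gc != length(ch)) stop("primer sequence must be over A/C/G/T")
    2 * at + 4 * gc
}

.revcompChr <- function(x) as.character(reverseComplement(DNAString(x)))

## mismatch count of primer vs template window starting at pos (plus-strand
## orientation of the given pattern); template as char vector
.mismatchProfile <- function(tmplChars, pattern, pos) {
    pc <- strsplit(pattern, "")[[1]]
    w <- tmplChars[pos:(pos + length(pc) - 1L)]
    w != pc
}

#' Locate primer binding sites on a template
#'
#' All ungapped alignments of the primer (plus strand) and of its reverse
#' complement (minus strand, when \code{params@bothStrands}) with at most
#' \code{maxMismatches} mismatches and zero mismatches inside the
#' 3'-terminal \code{anchorLen} positions.
#'
#' @param template DNA string or \code{DNAString(Set)} element.
#' @param primer a [Primer-class] or plain 5'->3' string.
#' @param params a [PCRParams-class].
#' @return data.frame with 1-based columns \code{start}, \code{end},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{mismatches}, sorted by
#'   \code{start}.
#' @export
matchPrimer <- function(template, primer, params = pcrParams()) {
    pseq <- if (is(primer, "Primer")) primer@seq else toupper(as.character(primer))
    tmpl <- toupper(as.character(template))
    if (nchar(tmpl) < nchar(pseq))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), mismatches = integer(),
                          stringsAsFactors = FALSE))
    tchars <- strsplit(tmpl, "")[[1]]
    plen <- nchar(pseq)
    anchor <- min(params@anchorLen, plen)
    scan <- function(pattern, strand) {
        hits <- matchPattern(pattern, DNAString(tmpl),
                             max.mismatch = params@maxMismatches,
                             with.indels = FALSE)
        if (length(hits) == 0L)
            return(NULL)
        st <- start(hits)
        keep <- logical(length(st))
        mm <- integer(length(st))
        for (h in seq_along(st)) {
            prof <- .mismatchProfile(tchars, pattern, st[h])
            mm[h] <- sum(prof)
            ## 3' terminus: last anchor bases on "+", first anchor bases on
            ## "-" (the pattern is the primer's reverse complement there)
            anchorIdx <- if (strand == "+")
                (plen - anchor + 1L):plen else seq_len(anchor)
            keep[h] <- mm[h] <= params@maxMismatches &&
                (anchor == 0L || !any(prof[anchorIdx]))
        }
        if (!any(keep)) return(NULL)
        data.frame(start = st[keep], end = st[keep] + plen - 1L,
                   strand = strand, mismatches = mm[keep],
                   stringsAsFactors = FALSE)
    }
    out <- scan(pseq, "+")
    if (params@bothStrands)
        out <- rbind(out, scan(.revcompChr(pseq), "-"))
    if (is.null(out))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), mismatches = integer(),
                          stringsAsFactors = FALSE))
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Predict PCR products on a template
#'
#' A product is reported for every combination of a forward-primer site and
#' a downstream reverse-primer site on the opposite strand whose length
#' (5' end of the forward footprint through the 5' end of the reverse
#' footprint, both footprints included) lies within the configured range.
#' With \code{bothStrands} the swapped orientation (reverse primer annealing
#' the plus strand) is also considered, so reverse-complementing the
#' template leaves the product length set unchanged.
#'
#' @param template DNA string (or named \code{DNAStringSet} element);
#'   a \code{templateId} is recorded in the result.
#' @param pair a [PrimerPair-class].
#' @param params a [PCRParams-class].
#' @param templateId id string recorded in the result.
#' @return data.frame of amplicon hits: \code{template_id}, \code{start},
#'   \code{end} (1-based inclusive full-product coordinates),
#'   \code{strand} (strand the forward primer anneals to),
#'   \code{mm_forward}, \code{mm_reverse}, \code{product_length_bp}.
#' @export
insilicoPcr <- function(template, pair, params = pcrParams(),
                        templateId = "template") {
    stopifnot(is(pair, "PrimerPair"), is(params, "PCRParams"))
    tmpl <- toupper(as.character(template))
    p1 <- params; p1@bothStrands <- TRUE  # strand handled explicitly here
    fHits <- matchPrimer(tmpl, pair@forward, p1)
    rHits <- matchPrimer(tmpl, pair@reverse, p1)
    combine <- function(fwd, rev, strandLabel) {
        ## fwd sites on "+", rev sites on "-" (template coordinates)
        f <- fwd[fwd$strand == "+", , drop = FALSE]
        r <- rev[rev$strand == "-", , drop = FALSE]
        if (!nrow(f) || !nrow(r)) return(NULL)
        out <- list()
        for (i in seq_len(nrow(f))) {
            for (j in seq_len(nrow(r))) {
                len <- r$end[j] - f$start[i] + 1L
                if (len < params@minProduct || len > params@maxProduct) next
                if (r$start[j] <= f$start[i]) next
                out[[length(out) + 1L]] <- data.frame(
                    template_id = templateId,
                    start = f$start[i], end = r$end[j],
                    strand = strandLabel,
                    mm_forward = f$mismatches[i], mm_reverse = r$mismatches[j],
                    product_length_bp = len, stringsAsFactors = FALSE)
            }
        }
        if (length(out)) do.call(rbind, out) else NULL
    }
    hits <- combine(fHits, rHits, "+")
    if (params@bothStrands) {
        ## swapped orientation: reverse primer anneals the plus strand and
        ## the forward primer the minus strand
        hits <- rbind(hits, combine(rHits, fHits, "-"))
    }
    if (is.null(hits))
        return(data.frame(template_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          mm_forward = integer(), mm_reverse = integer(),
                          product_length_bp = integer(),
                          stringsAsFactors = FALSE))
    hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Find species-diagnostic sequence windows at a locus
#'
#' Scans every window of \code{windowLen} that is (a) invariant across all
#' target-species strains and (b) separated from the corresponding window of
#' every non-target strain by at least \code{minMismatches} differences, at
#' least one of which lies in the window's 3'-terminal three positions.
#' Windows are scored by their minimum non-target mismatch count.
#'
#' @param panel a [StrainPanel-class] with equal-length sequences at the
#'   locus.
#' @param locus locus name.
#' @param targetSpecies species label the windows must be diagnostic for.
#' @param windowLen window length in nt (18-30 for primer use).
#' @param minMismatches minimum per-strain mismatch count (default 3).
#' @return data.frame with 1-based \code{start}, \code{end}, \code{seq},
#'   \code{score} (min non-target mismatches), sorted by descending score
#'   then start.
#' @export
findSpecificWindows <- function(panel, locus, targetSpecies, windowLen = 20L,
                                minMismatches = 3L) {
    seqs <- as.character(locusSequences(panel, locus))
    sp <- speciesLabels(panel)[names(seqs)]
    if (!any(sp == targetSpecies))
        stop(sprintf("no strains of species '%s' at locus %s",
                     targetSpecies, locus))
    L <- .checkEqualLength(seqs)
    if (L < windowLen) stop("locus shorter than window")
    m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
    tgt <- m[sp == targetSpecies, , drop = FALSE]
    oth <- m[sp != targetSpecies, , drop = FALSE]
    consensus <- tgt[1L, ]
    invariant <- colSums(tgt != rep(consensus, each = nrow(tgt))) == 0L
    ## per non-target strain, per column: differs from target consensus
    diffs <- oth != rep(consensus, each = nrow(oth))
    nWin <- L - windowLen + 1L
    ## rolling sums via cumulative sums along columns
    rollSum <- function(v, k) {
        cs <- c(0, cumsum(v))
        cs[(k + 1L):(length(v) + 1L)] - cs[1L:(length(v) - k + 1L)]
    }
    invOk <- rollSum(as.numeric(!invariant), windowLen) == 0
    if (nrow(oth)) {
        mmWin <- t(apply(diffs, 1L, rollSum, k = windowLen))  # strains x nWin
        if (nWin == 1L) mmWin <- matrix(mmWin, ncol = 1L)
        tail3 <- t(apply(diffs, 1L, function(v) {
            r3 <- rollSum(v, 3L)                 # windows of 3 ending at j+2
            r3[windowLen - 2L + seq_len(nWin) - 1L]
        }))
        if (nWin == 1L) tail3 <- matrix(tail3, ncol = 1L)
        specOk <- colSums(mmWin < minMismatches) == 0L
        if (minMismatches >= 1L)   # the 3' requirement rides on the filter
            specOk <- specOk & colSums(tail3 < 1L) == 0L
        score <- apply(mmWin, 2L, min)
    } else {
        specOk <- rep(TRUE, nWin)
        score <- rep(Inf, nWin)
    }
    keep <- which(invOk & specOk)
    if (!length(keep))
        return(data.frame(start = integer(), end = integer(),
                          seq = character(), score = numeric(),
                          stringsAsFactors = FALSE))
    out <- data.frame(
        start = keep, end = keep + windowLen - 1L,
        seq = vapply(keep, function(s)
            paste(consensus[s:(s + windowLen - 1L)], collapse = ""),
            character(1)),
        score = score[keep], stringsAsFactors = FALSE)
    out <- out[order(-out$score, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Design primer pairs from candidate windows
#'
#' Pairs each candidate window (forward primer = window sequence) with the
#' reverse complement of a downstream candidate window (reverse primer),
#' keeping pairs whose product length (distance from forward window start to
#' reverse window end, footprints included) and melting temperatures fall in
#' range.  Pairs are ranked by combined specificity score (sum of the two
#' window scores, descending).
#'
#' @param windows data.frame from [findSpecificWindows()] (possibly from
#'   scans at several window lengths, concatenated).
#' @param productRange numeric \code{c(min, max)} product length in bp.
#' @param tmRange numeric \code{c(min, max)} Wallace Tm in degrees C.
#' @param maxPairs keep only the top-ranked pairs (a dense diagnostic locus
#'   can offer thousands of admissible combinations).
#' @return list of [PrimerPair-class] objects (empty, with a message, when
#'   no compatible pair exists).
#' @export
designPairs <- function(windows, productRange = c(100, 1000),
                        tmRange = c(50, 70), maxPairs = 20L) {
    if (nrow(windows) < 2L) {
        message("designPairs: fewer than 2 candidate windows; no pairs")
        return(list())
    }
    w <- windows[order(windows$start), , drop = FALSE]
    w <- w[!duplicated(w[, c("start", "end")]), , drop = FALSE]
    tm <- vapply(w$seq, primerTm, numeric(1))  # composition-invariant under revcomp
    tmOk <- tm >= tmRange[1L] & tm <= tmRange[2L]
    w <- w[tmOk, , drop = FALSE]
    tm <- tm[tmOk]
    n <- nrow(w)
    if (n < 2L) {
        message("designPairs: no window pair satisfies the product/Tm ranges")
        return(list())
    }
    ij <- expand.grid(i = seq_len(n), j = seq_len(n))
    ij <- ij[ij$i < ij$j & w$end[ij$j] > w$end[ij$i], , drop = FALSE]
    len <- w$end[ij$j] - w$start[ij$i] + 1L
    ok <- len >= productRange[1L] & len <= productRange[2L]
    ij <- ij[ok, , drop = FALSE]; len <- len[ok]
    if (!nrow(ij)) {
        message("designPairs: no window pair satisfies the product/Tm ranges")
        return(list())
    }
    score <- w$score[ij$i] + w$score[ij$j]
    o <- head(order(-score, w$start[ij$i], w$start[ij$j]), maxPairs)
    lapply(o, function(k) {
        i <- ij$i[k]; j <- ij$j[k]
        primerPair(
            primer(sprintf("F_%d", w$start[i]), w$seq[i]),
            primer(sprintf("R_%d", w$start[j]), .revcompChr(w$seq[j])),
            expectedSize = len[k])
    })
}

#' Per-strain amplification matrix and specificity verdicts
#'
#' Runs [insilicoPcr()] for every pair against every strain, using each
#' strain's per-locus sequences as templates (a strain amplifies if any of
#' its locus sequences yields a product).  A pair is
#' \code{SPECIFIC(<species>)} iff all strains of \code{targetSpecies}
#' amplify and no other strain does.
#'
#' @param pairs list of [PrimerPair-class] (named, ideally).
#' @param panel a [StrainPanel-class].
#' @param params a [PCRParams-class].
#' @param targetSpecies species label used for the verdict.
#' @param loci template loci to scan (default: all panel loci).
#' @return list with \code{matrix} (character, pairs x strains; product
#'   length(s) or \code{"-"}) and \code{verdict} (named character per pair).
#' @export
specificityReport <- function(pairs, panel, params = pcrParams(),
                              targetSpecies = NULL,
                              loci = panelLoci(panel)) {
    strains <- strainNames(panel)
    if (!length(pairs))
        return(list(matrix = matrix(character(0), nrow = 0L, ncol = length(strains),
                                    dimnames = list(NULL, strains)),
                    verdict = character(0)))
    if (is.null(names(pairs)) || any(!nzchar(names(pairs))))
        names(pairs) <- paste0("pair", seq_along(pairs))
    sp <- speciesLabels(panel)
    mat <- matrix("-", nrow = length(pairs), ncol = length(strains),
                  dimnames = list(names(pairs), strains))
    for (pi in seq_along(pairs)) {
        for (st in strains) {
            lens <- integer(0)
            for (loc in loci) {
                ss <- locusSequences(panel, loc)
                if (!st %in% names(ss)) next
                hits <- insilicoPcr(ss[[st]], pairs[[pi]], params,
                                    templateId = paste(st, loc, sep = ":"))
                lens <- c(lens, hits$product_length_bp)
            }
            if (length(lens))
                mat[pi, st] <- paste(sort(unique(lens)), collapse = ",")
        }
    }
    verdict <- setNames(rep("NOT SPECIFIC", length(pairs)), names(pairs))
    if (!is.null(targetSpecies)) {
        for (pi in seq_along(pairs)) {
            amp <- mat[pi, ] != "-"
            tgt <- sp[strains] == targetSpecies
            if (all(amp[tgt]) && !any(amp[!tgt]))
                verdict[pi] <- sprintf("SPECIFIC(%s)", targetSpecies)
        }
    }
    list(matrix = mat, verdict = verdict)
}

#' Read / write primer tables
#'
#' TSV with columns \code{name}, \code{sequence}, \code{pair},
#' \code{expected_size} (the two primers of a pair share the \code{pair}
#' label; orientation is taken from a trailing \code{-F}/\code{-R} in the
#' name or from row order within the pair).
#'
#' @param path TSV path.
#' @return named list of [PrimerPair-class].
#' @export
readPrimerTable <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", stringsAsFactors = FALSE)
    need <- c("name", "sequence", "pair", "expected_size")
    if (!all(need %in% names(tab)))
        stop(sprintf("primer table needs columns: %s",
                     paste(need, collapse = ", ")))
    out <- list()
    for (pid in unique(tab$pair)) {
        rows <- tab[tab$pair == pid, , drop = FALSE]
        if (nrow(rows) != 2L)
            stop(sprintf("pair '%s' must have exactly 2 rows", pid))
        isR <- grepl("-R$", rows$name)
        if (sum(isR) == 1L) rows <- rows[order(isR), , drop = FALSE]
        sz <- suppressWarnings(as.integer(rows$expected_size))
        sz <- sz[!is.na(sz)][1]
        out[[pid]] <- primerPair(
            primer(rows$name[1L], rows$sequence[1L]),
            primer(rows$name[2L], rows$sequence[2L]),
            expectedSize = if (length(sz)) sz else NA_integer_)
    }
    out
}

#' @rdname readPrimerTable
#' @param pairs named list of [PrimerPair-class].
#' @return invisibly, \code{path}.
#' @export
writePrimerTable <- function(pairs, path) {
    rows <- list()
    for (nm in names(pairs)) {
        pp <- pairs[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
            name = c(pp@forward@name, pp@reverse@name),
            sequence = c(pp@forward@seq, pp@reverse@seq),
            pair = nm,
            expected_size = c(pp@expectedSize, NA),
            stringsAsFactors = FALSE)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(name = character(), sequence = character(),
                   pair = character(), expected_size = integer())
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}
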