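## Independent brute-force oracles.  These deliberately avoid the package's
## lookup tables and vectorized code paths: string-based genetic-code
## lookups, explicit pair enumeration, naive recursion.

.oracleCode <- Biostrings::GENETIC_CODE

oracleRevcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## probability two random distinct strains carry different alleles,
## by explicit enumeration of all unordered strain pairs
oracleDP <- function(counts) {
    alleles <- rep(seq_along(counts), counts)
    n <- length(alleles)
    same <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            if (alleles[i] == alleles[j]) same <- same + 1L
        }
    }
    ## ordered same-pairs over ordered pairs; integer operands, so the
    ## division is bit-identical to any formula with the same numerator
    1 - (2L * same) / (n * (n - 1L))
}

## per-codon Nei-Gojobori site counts by enumerating the 9 alternatives
oracleSites <- function(codon) {
    aa <- .oracleCode[[codon]]
    s <- 0
    for (p in 1:3) {
        syn <- 0
        for (b in c("A", "C", "G", "T")) {
            if (substr(codon, p, p) == b) next
            alt <- codon
            substr(alt, p, p) <- b
            aaAlt <- .oracleCode[[alt]]
            if (aaAlt != "*" && aaAlt == aa) syn <- syn + 1
        }
        s <- s + syn / 3
    }
    c(s = s, n = 3 - s)
}

.allPerms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in .allPerms(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

## pathway-averaged (sd, nd) for a sense codon pair: walk every ordering of
## the differing positions, drop orderings that pass through a stop codon
## (average over all orderings if none survives)
oraclePathwayCounts <- function(a, b) {
    d <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(d)) return(c(sd = 0, nd = 0))
    syn <- numeric(0); ok <- logical(0)
    for (ord in .allPerms(d)) {
        cur <- a; nSyn <- 0; valid <- TRUE
        for (p in ord) {
            nxt <- cur
            substr(nxt, p, p) <- substr(b, p, p)
            if (.oracleCode[[nxt]] == "*") valid <- FALSE
            else if (.oracleCode[[cur]] != "*" &&
                     .oracleCode[[nxt]] == .oracleCode[[cur]])
                nSyn <- nSyn + 1
            cur <- nxt
        }
        syn <- c(syn, nSyn); ok <- c(ok, valid)
    }
    use <- if (any(ok)) ok else rep(TRUE, length(ok))
    sd <- mean(syn[use])
    c(sd = sd, nd = length(d) - sd)
}

## optimal global alignment score by an explicit R score matrix (the
## implementation under test delegates to Biostrings' C aligner)
oracleAlignScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    n <- length(ca); m <- length(cb)
    S <- matrix(0, n + 1L, m + 1L)
    S[, 1L] <- gap * 0:n
    S[1L, ] <- gap * 0:m
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            sub <- if (ca[i] == cb[j]) match else mismatch
            S[i + 1L, j + 1L] <- max(S[i, j] + sub,
                                     S[i, j + 1L] + gap,
                                     S[i + 1L, j] + gap)
        }
    }
    S[n + 1L, m + 1L]
}

## sliding-window Hamming scan with 3' anchor, both strands
oracleHammingScan <- function(template, primerSeq, maxMM = 2L, anchor = 3L) {
    tc <- strsplit(template, "")[[1]]
    scan1 <- function(pat, strand) {
        pc <- strsplit(pat, "")[[1]]
        k <- length(pc)
        hits <- NULL
        for (s in seq_len(length(tc) - k + 1L)) {
            mm <- tc[s:(s + k - 1L)] != pc
            anchorIdx <- if (strand == "+") (k - anchor + 1L):k else 1L:anchor
            if (sum(mm) <= maxMM && (anchor == 0L || !any(mm[anchorIdx])))
                hits <- rbind(hits, data.frame(start = s, strand = strand,
                                               mismatches = sum(mm)))
        }
        hits
    }
    out <- rbind(scan1(primerSeq, "+"), scan1(oracleRevcomp(primerSeq), "-"))
    if (is.null(out)) data.frame(start = integer(), strand = character(),
                                 mismatches = integer())
    else out[order(out$start, out$strand), , drop = FALSE]
}

## polymorphic-site count by per-column distinct-base counting
oraclePolySites <- function(seqs) {
    m <- do.call(rbind, strsplit(seqs, ""))
    n <- 0L
    for (j in seq_len(ncol(m))) {
        col <- m[, j]
        if (any(!col %in% c("A", "C", "G", "T"))) next
        if (length(unique(col)) >= 2L) n <- n + 1L
    }
    n
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

randomCodingDna <- function(nCodons) {
    sense <- names(.oracleCode)[.oracleCode != "*"]
    paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}
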