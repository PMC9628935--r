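## Shared codon bookkeeping for Nei-Gojobori counting and the codon-aware
## simulator.  All tables are precomputed once per session and cached.

.pkgCache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

## codon index: 1..64, (b1-1)*16 + (b2-1)*4 + b3 with A,C,G,T = 1..4
.codonIndex <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

.codonStrings <- function() {
    g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                     stringsAsFactors = FALSE)
    paste0(g$b1, g$b2, g$b3)
}

## Build (once) the genetic-code tables: amino acids, stop flags, per-codon
## synonymous site fractions, and proposal classification arrays.
.codonTables <- function() {
    if (!is.null(.pkgCache$ct)) return(.pkgCache$ct)
    codons <- .codonStrings()
    aa <- unname(GENETIC_CODE[codons])
    isStop <- aa == "*"
    ## synChange[c, p, b]: replacing position p of codon c by base b keeps
    ## the amino acid; stopRes[c, p, b]: the replacement yields a stop codon
    synChange <- array(FALSE, dim = c(64L, 3L, 4L))
    stopRes <- array(FALSE, dim = c(64L, 3L, 4L))
    baseIdx <- t(vapply(strsplit(codons, ""), function(ch) match(ch, .BASES),
                        integer(3)))
    for (ci in 1:64) {
        for (p in 1:3) {
            for (b in 1:4) {
                if (b == baseIdx[ci, p]) next
                nb <- baseIdx[ci, ]
                nb[p] <- b
                nj <- .codonIndex(nb[1], nb[2], nb[3])
                stopRes[ci, p, b] <- isStop[nj]
                synChange[ci, p, b] <- !isStop[nj] && aa[nj] == aa[ci]
            }
        }
    }
    ## Nei-Gojobori site counts: fraction of the 3 alternatives at each
    ## position that are synonymous (changes to stops are nonsynonymous)
    sSites <- rep(NA_real_, 64L)
    for (ci in which(!isStop)) {
        s <- 0
        for (p in 1:3)
            s <- s + sum(synChange[ci, p, ]) / 3
        sSites[ci] <- s
    }
    ct <- list(codons = codons, aa = aa, isStop = isStop, baseIdx = baseIdx,
               synChange = synChange, stopRes = stopRes, sSites = sSites)
    .pkgCache$ct <- ct
    ct
}

.PERMS <- list(
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

## Pathway-averaged (Sd, Nd) for one sense-codon pair, excluding pathways
## through stop codons (all-pathway average as fallback if every pathway is
## blocked).
.pairPathwayCounts <- function(ci, cj, ct) {
    bi <- ct$baseIdx[ci, ]
    bj <- ct$baseIdx[cj, ]
    d <- which(bi != bj)
    m <- length(d)
    if (m == 0L) return(c(sd = 0, nd = 0))
    perms <- .PERMS[[m]]
    synTot <- numeric(length(perms))
    valid <- logical(length(perms))
    for (k in seq_along(perms)) {
        cur <- bi
        syn <- 0
        ok <- TRUE
        for (p in d[perms[[k]]]) {
            prevIdx <- .codonIndex(cur[1], cur[2], cur[3])
            cur[p] <- bj[p]
            newIdx <- .codonIndex(cur[1], cur[2], cur[3])
            if (ct$isStop[newIdx]) { ok <- FALSE }
            if (!ct$isStop[newIdx] && !ct$isStop[prevIdx] &&
                ct$aa[newIdx] == ct$aa[prevIdx])
                syn <- syn + 1
        }
        synTot[k] <- syn
        valid[k] <- ok
    }
    use <- if (any(valid)) valid else rep(TRUE, length(perms))
    sd <- mean(synTot[use])
    c(sd = sd, nd = m - sd)
}

## 64x64 matrices of pathway-averaged synonymous/nonsynonymous difference
## counts (NA where either codon is a stop), cached.
.pairCountMatrices <- function() {
    if (!is.null(.pkgCache$pm)) return(.pkgCache$pm)
    ct <- .codonTables()
    sd <- matrix(NA_real_, 64L, 64L)
    nd <- matrix(NA_real_, 64L, 64L)
    sense <- which(!ct$isStop)
    for (ci in sense) {
        for (cj in sense) {
            if (cj < ci) next
            v <- .pairPathwayCounts(ci, cj, ct)
            sd[ci, cj] <- sd[cj, ci] <- v[["sd"]]
            nd[ci, cj] <- nd[cj, ci] <- v[["nd"]]
        }
    }
    pm <- list(sd = sd, nd = nd)
    .pkgCache$pm <- pm
    pm
}

## Map a DNA string (multiple of 3, ACGT only elsewhere NA) to codon indices.
.toCodonIndices <- function(seq) {
    b <- match(strsplit(seq, "")[[1]], .BASES)       # non-ACGT -> NA
    n <- length(b)
    if (n %% 3L != 0L)
        stop("sequence length must be divisible by 3")
    dim(b) <- c(3L, n %/% 3L)
    idx <- .codonIndex(b[1L, ], b[2L, ], b[3L, ])
    idx
}
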