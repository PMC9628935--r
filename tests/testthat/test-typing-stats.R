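test_that("callAlleles groups identical sequences in first-occurrence order", {
    at <- callAlleles(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"))
    expect_equal(unname(alleleAssignments(at)), c(1L, 1L, 2L))
    expect_equal(alleleCounts(at), c(2L, 1L))
    expect_equal(nTyped(at), 3L)

    expect_equal(length(alleleCounts(callAlleles(
        setNames(rep("ACGT", 21), paste0("s", 1:21))))), 1L)

    expect_error(callAlleles(c(s1 = "ACGT", s2 = "ACG")), "length")
    expect_error(callAlleles(character(0)))
})

test_that("countPolymorphicSites matches the per-column oracle", {
    expect_equal(countPolymorphicSites(c(a = "ACGT", b = "ACGT")), 0L)
    expect_equal(countPolymorphicSites(c(a = "ACGT", b = "ACGA",
                                         c = "TCGA")), 2L)
    ## N-containing columns are skipped entirely
    expect_equal(countPolymorphicSites(c(a = "ANGT", b = "ACGA")), 1L)

    set.seed(21)
    for (rep in 1:20) {
        seqs <- vapply(1:5, function(i) {
            s <- randomDna(30)
            if (rep %% 3 == 0)   # sprinkle Ns into some panels
                substr(s, sample(30, 1), sample(30, 1)) <- "N"
            s
        }, character(1))
        names(seqs) <- paste0("s", 1:5)
        expect_equal(countPolymorphicSites(seqs), oraclePolySites(seqs))
    }
})

test_that("typing efficiency is alleles per polymorphic site", {
    expect_equal(round(typingEfficiency(19, 1075), 3), 0.018)
    expect_equal(round(typingEfficiency(11, 78), 3), 0.141)
    expect_error(typingEfficiency(5, 0), "monomorphic")
})

test_that("discriminatory power equals the pair-counting oracle", {
    expect_equal(discriminatoryPower(rep(1L, 8)), 1)      # all singletons
    expect_equal(discriminatoryPower(7L), 0)              # one allele
    expect_equal(discriminatoryPower(c(3L, 2L, 1L, 1L)), 1 - 8 / 42)
    expect_equal(discriminatoryPower(c(3L, 2L, 1L, 1L)),
                 oracleDP(c(3L, 2L, 1L, 1L)))
    expect_error(discriminatoryPower(1L), "at least 2")

    set.seed(31)
    for (rep in 1:200) {
        N <- sample(2:30, 1)
        k <- sample(seq_len(N), 1)
        counts <- as.integer(tabulate(sample(k, N, replace = TRUE)))
        counts <- counts[counts > 0]
        expect_identical(discriminatoryPower(counts), oracleDP(counts))
    }
})

test_that("Nei-Gojobori site counts match enumeration for every sense codon", {
    tt <- neiGojoboriSites("TTT")
    expect_equal(unname(tt["s"]), 1 / 3)
    expect_equal(unname(tt["n"]), 8 / 3)
    expect_equal(unname(neiGojoboriSites("ATG")["s"]), 0)

    code <- Biostrings::GENETIC_CODE
    for (codon in names(code)[code != "*"]) {
        got <- neiGojoboriSites(codon)
        want <- oracleSites(codon)
        expect_equal(unname(got["s"]), unname(want["s"]), tolerance = 1e-12)
        expect_equal(unname(got["s"] + got["n"]), 3)
    }
    expect_true(is.na(neiGojoboriSites("TAA")["s"]))  # stop -> skip flag
})

test_that("pathway-averaged difference counts match the enumerating oracle", {
    expect_equal(codonDiffCounts("TTT", "TTC"), c(sd = 1, nd = 0))
    set.seed(51)
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    for (rep in 1:150) {
        pair <- sample(sense, 2)
        got <- codonDiffCounts(pair[1], pair[2])
        want <- oraclePathwayCounts(pair[1], pair[2])
        expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
})

test_that("pairwise dN/dS behaves on canonical cases and matches the oracle", {
    s <- "ATGGCTAAA"
    r <- pairwiseDnds(s, s)
    expect_equal(r$dN, 0)
    expect_equal(r$dS, 0)

    ## one synonymous difference in a context long enough to keep the
    ## Jukes-Cantor correction defined
    r2 <- pairwiseDnds("TTTGGAGGA", "TTCGGAGGA")
    expect_equal(r2$Sd, 1)
    expect_equal(r2$Nd, 0)
    expect_equal(r2$dN, 0)
    expect_gt(r2$dS, 0)

    ## a bare single-codon pair saturates pS and is flagged
    expect_true(pairwiseDnds("TTT", "TTC")$saturated)

    set.seed(61)
    for (rep in 1:10) {
        a <- randomCodingDna(100)
        b <- randomCodingDna(100)
        r <- pairwiseDnds(a, b)
        ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
        cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
        counts <- mapply(function(x, y) oraclePathwayCounts(x, y), ca, cb)
        expect_equal(r$Sd, sum(counts["sd", ]), tolerance = 1e-9)
        expect_equal(r$Nd, sum(counts["nd", ]), tolerance = 1e-9)
    }
})

test_that("locus dN/dS handles degenerate panels", {
    ## all variation synonymous -> ratio 0
    seqs <- c(a = "TTTGGAGGAGGA", b = "TTCGGAGGAGGA", c = "TTTGGGGGAGGA")
    expect_equal(locusDnds(seqs), 0)
    ## identical panel -> NA
    expect_true(is.na(locusDnds(c(a = "ATGAAA", b = "ATGAAA"))))
})

test_that("summarizeLoci composes per-locus statistics consistently", {
    sim <- cachedSim(1)
    stats <- summarizeLoci(sim$panel)
    expect_equal(nrow(stats), 18L)
    ## TE consistency on every row
    ok <- !is.na(stats$te)
    expect_equal(stats$te[ok],
                 stats$n_alleles[ok] / stats$n_polymorphic_sites[ok])
    ## DP bounds and dN/dS present for coding loci
    expect_true(all(stats$dp >= 0 & stats$dp <= 1))
    expect_true(all(!is.na(stats$dnds[stats$locus != "rrs"])))
    expect_true(is.na(stats$dnds[stats$locus == "rrs"]))

    ## a monomorphic locus yields TE = NA, DP = 0
    p <- panelFromList(list(mono = c(s1 = "ACGTACGT", s2 = "ACGTACGT")),
                       species = c(s1 = "sp1", s2 = "sp2"))
    row <- summarizeLoci(p)
    expect_true(is.na(row$te))
    expect_equal(row$dp, 0)

    ## formatted table carries the column-mean footer
    fmt <- formatLocusStats(stats)
    expect_equal(fmt$locus[nrow(fmt)], "mean")
    expect_equal(fmt$dnds[nrow(fmt)],
                 round(mean(stats$dnds, na.rm = TRUE), 4))
})

test_that("marker ranking follows polymorphism and homology criteria", {
    stats <- data.frame(
        locus = c("adk", "aroE", "pycA"),
        length_bp = c(654L, 843L, 3450L),
        n_alleles = c(11L, 18L, 19L),
        n_polymorphic_sites = c(78L, 322L, 1075L),
        dnds = c(0.41, 0.39, 0.40), te = c(0.141, 0.056, 0.018),
        dp = c(0.935, 0.983, 0.991), stringsAsFactors = FALSE)
    ids <- data.frame(locus = c("adk", "aroE", "pycA"),
                      min_between_identity = c(78.1, 67.0, 79.7),
                      stringsAsFactors = FALSE)
    r <- rankMarkers(stats, ids)
    expect_equal(r$bySites[1L], "pycA")
    expect_equal(r$byIdentity[1L], "aroE")
    expect_setequal(r$candidates, c("pycA", "aroE"))

    ## ties fall back to locus name
    tied <- stats
    tied$n_polymorphic_sites <- 100L
    tied$n_alleles <- 10L
    expect_equal(rankMarkers(tied, ids)$bySites, sort(stats$locus))

    ## a locus simulated at double divergence tops the homology ranking
    cfg <- smallConfig(seed = 13, pInter = c(locA = 0.25, locB = 0.5,
                                             nc16 = 0.008))
    sim <- generatePanel(cfg)
    idt <- identitySummaryTable(sim$panel)
    st <- summarizeLoci(sim$panel)
    expect_equal(rankMarkers(st, idt)$byIdentity[1L], "locB")
})
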