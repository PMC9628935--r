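test_that("Wallace Tm is composition-only", {
    expect_equal(primerTm(paste(rep("A", 14), collapse = "")), 28)
    ## published pycA-F: 11 G+C, 9 A+T
    expect_equal(primerTm("GTCTTCCGTTCAGGAAAGGC"), 62)
    expect_equal(primerTm("GGGGAAGGCTTCGTGAAGTC"), 64)
    set.seed(91)
    for (rep in 1:10) {
        s <- randomDna(22)
        expect_equal(primerTm(s), primerTm(oracleRevcomp(s)))
    }
})

test_that("primer site matching equals the Hamming-scan oracle", {
    set.seed(92)
    pr <- primer("p", randomDna(20))
    tmpl <- paste0(randomDna(60), pr@seq, randomDna(60))
    hits <- matchPrimer(tmpl, pr)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$strand, "+")
    expect_equal(hits$mismatches, 0L)
    expect_equal(hits$start, 61L)

    tmplRC <- paste0(randomDna(30), oracleRevcomp(pr@seq), randomDna(30))
    hitsRC <- matchPrimer(tmplRC, pr)
    expect_equal(nrow(hitsRC), 1L)
    expect_equal(hitsRC$strand, "-")

    ## a mismatch in the 3' anchor kills the site even under the budget
    t2 <- pr@seq
    substr(t2, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  substr(t2, 20, 20))[1]
    expect_equal(nrow(matchPrimer(paste0(randomDna(20), t2, randomDna(20)),
                                  pr)), 0L)

    ## property vs oracle on mutated templates
    params <- pcrParams(maxMismatches = 2L, anchorLen = 3L)
    for (rep in 1:60) {
        p <- randomDna(18)
        base <- randomDna(220)
        ## embed a perfect copy and two mutated copies
        s1 <- p
        s2 <- p; substr(s2, 5, 5) <- setdiff(c("A","C","G","T"), substr(p,5,5))[1]
        s3 <- oracleRevcomp(p)
        tmpl <- paste0(substr(base, 1, 60), s1, substr(base, 61, 120), s2,
                       substr(base, 121, 180), s3, substr(base, 181, 220))
        got <- matchPrimer(tmpl, p, params)
        want <- oracleHammingScan(tmpl, p, 2L, 3L)
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
        expect_equal(got$mismatches, want$mismatches)
    }
})

test_that("in-silico PCR reproduces the published product sizes", {
    prs <- bundledPrimers()
    set.seed(93)
    tmplP <- paste0(randomDna(40), prs$pycA@forward@seq, randomDna(191),
                    oracleRevcomp(prs$pycA@reverse@seq), randomDna(40))
    hits <- insilicoPcr(tmplP, prs$pycA)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$product_length_bp, 233L)
    expect_equal(hits$end - hits$start + 1L, hits$product_length_bp)

    tmplA <- paste0(randomDna(25), prs$aroE@forward@seq, randomDna(237),
                    oracleRevcomp(prs$aroE@reverse@seq), randomDna(25))
    expect_equal(insilicoPcr(tmplA, prs$aroE)$product_length_bp, 278L)

    ## strand invariance
    hitsRC <- insilicoPcr(oracleRevcomp(tmplP), prs$pycA)
    expect_equal(sort(hitsRC$product_length_bp),
                 sort(hits$product_length_bp))

    ## product arithmetic F + spacer(k) + revcomp(R)
    for (k in c(60L, 123L, 400L)) {
        f <- randomDna(20); r <- randomDna(22)
        tm <- paste0(randomDna(10), f, randomDna(k), oracleRevcomp(r),
                     randomDna(10))
        h <- insilicoPcr(tm, primerPair(f, r))
        expect_true((20L + k + 22L) %in% h$product_length_bp)
    }
})

test_that("diagnostic window discovery honours its filters", {
    sim <- cachedSim(1)
    p <- sim$panel
    w <- findSpecificWindows(p, "aroE", "B_subtilis", 20L, 3L)
    planted <- sim$truth$windows
    planted <- planted[planted$locus == "aroE" & planted$windowLength == 20L, ]
    expect_true(planted$start %in% w$start)
    ## the planted window carries 4 planted substitutions per non-target
    ## species ancestor, so its score is at least 3
    expect_gte(w$score[w$start == planted$start], 3)

    ## relaxation: minMismatches = 0 returns every target-invariant window
    w0 <- findSpecificWindows(p, "aroE", "B_subtilis", 20L, 0L)
    expect_gt(nrow(w0), nrow(w))

    ## target-internal variation at every window -> empty
    half <- paste(rep("AC", 15), collapse = "")
    seqs <- c(t1 = paste0(half, half), t2 = paste0(half, chartr("AC", "GT", half)),
              o1 = paste0(chartr("A", "T", half), half))
    seqs <- vapply(seqs, function(s) substr(s, 1, 40), character(1))
    ## make t1 and t2 differ somewhere inside every 18-mer
    t2 <- seqs[["t1"]]
    for (i in seq(1, 40, by = 9))
        substr(t2, i, i) <- setdiff(c("A","C","G","T"), substr(t2, i, i))[1]
    pan <- panelFromList(list(l = c(t1 = seqs[["t1"]], t2 = t2,
                                    o1 = seqs[["o1"]])),
                         species = c(t1 = "tgt", t2 = "tgt", o1 = "oth"))
    expect_equal(nrow(findSpecificWindows(pan, "l", "tgt", 18L, 1L)), 0L)

    expect_error(findSpecificWindows(p, "aroE", "no_such_species"), "species")
})

test_that("pair design composes windows into oriented primer pairs", {
    ## constructed fixture mirroring the pycA design: two windows 233 bp
    ## end-to-end (20 + 191 + 22)
    wins <- data.frame(
        start = c(101L, 312L), end = c(120L, 333L),
        seq = c(randomDna(20), randomDna(22)),
        score = c(5, 4), stringsAsFactors = FALSE)
    prs <- designPairs(wins, productRange = c(200, 300), tmRange = c(0, 200))
    expect_length(prs, 1L)
    expect_equal(prs[[1L]]@expectedSize, 233L)
    expect_equal(prs[[1L]]@reverse@seq, oracleRevcomp(wins$seq[2L]))

    ## disabling the Tm filter can only widen the result
    narrow <- designPairs(wins, c(200, 300), tmRange = c(64, 66))
    expect_lte(length(narrow), length(prs))

    expect_length(suppressMessages(
        designPairs(wins[1, ], c(200, 300), c(0, 200))), 0L)
})

test_that("specificity reports flag target-only amplification", {
    sim <- cachedSim(1)
    p <- sim$panel
    wins <- findSpecificWindows(p, "pycA", "B_subtilis", 20L, 3L)
    prs <- designPairs(wins, productRange = c(100, 1000), tmRange = c(40, 80),
                       maxPairs = 1L)
    rep <- specificityReport(prs, p, targetSpecies = "B_subtilis",
                             loci = "pycA")
    expect_equal(unname(rep$verdict), "SPECIFIC(B_subtilis)")
    sp <- speciesLabels(p)
    amp <- rep$matrix[1L, ] != "-"
    expect_true(all(amp[sp == "B_subtilis"]))
    expect_false(any(amp[sp != "B_subtilis"]))

    ## a primer pair lifted from a conserved stretch amplifies everything
    cons <- as.character(locusSequences(p, "rrs")[[1L]])
    uni <- primerPair(substr(cons, 1, 20),
                      oracleRevcomp(substr(cons, 281, 300)))
    repU <- specificityReport(list(uni = uni), p,
                              targetSpecies = "B_subtilis", loci = "rrs")
    expect_equal(unname(repU$verdict), "NOT SPECIFIC")

    empty <- specificityReport(list(), p)
    expect_equal(nrow(empty$matrix), 0L)
})

test_that("primer tables round-trip", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writePrimerTable(bundledPrimers(), tf)
    back <- readPrimerTable(tf)
    expect_named(back, c("pycA", "aroE"))
    expect_equal(back$pycA@forward@seq, bundledPrimers()$pycA@forward@seq)
    expect_equal(back$pycA@expectedSize, 233L)
    expect_equal(back$aroE@expectedSize, 278L)
})
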