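test_that("global alignment scores match the recursive oracle", {
    a <- globalAlign("ACGT", "ACGT")
    expect_equal(a$score, 4)
    expect_equal(a$alignedA, "ACGT")

    b <- globalAlign("ACGT", "ACG")
    expect_equal(nchar(b$alignedB), nchar(b$alignedA))
    expect_match(b$alignedB, "-")

    set.seed(71)
    for (rep in 1:25) {
        x <- randomDna(sample(4:12, 1))
        y <- randomDna(sample(4:12, 1))
        expect_equal(globalAlign(x, y)$score, oracleAlignScore(x, y))
    }
})

test_that("percent identity follows the alignment-length convention", {
    expect_equal(percentIdentity("ACGT", "ACGT"), 100)
    expect_equal(percentIdentity("ACGT", "ACGA"), 75)
    set.seed(72)
    for (rep in 1:10) {
        x <- randomDna(20); y <- randomDna(20)
        expect_equal(percentIdentity(x, y), percentIdentity(y, x))
    }
})

test_that("reference-based polymorphic sites agree with identity algebraically", {
    expect_equal(polymorphicSitesVsReference("ACGT", "ACGT"), 0L)
    expect_equal(polymorphicSitesVsReference("ACGT", "ACGA"), 1L)
    set.seed(73)
    for (rep in 1:10) {
        L <- 40
        x <- randomDna(L)
        y <- x
        k <- sample(1:5, 1)
        for (i in sample(L, k))
            substr(y, i, i) <- setdiff(c("A", "C", "G", "T"),
                                       substr(x, i, i))[sample(3, 1)]
        cnt <- polymorphicSitesVsReference(y, x)
        id <- percentIdentity(y, x)
        expect_equal(cnt, round(L * (1 - id / 100)))
    }
})

test_that("scheme concatenation preserves content and order", {
    sim <- cachedSim(1)
    p <- sim$panel
    schemes <- mlstSchemes()
    expect_named(schemes, c("pubMLST", "S1", "S2", "S3", "L1"))
    expect_equal(geneOrder(schemes$pubMLST),
                 c("glpF", "ilvD", "pta", "purH", "pycA", "rpoD", "tpiA"))

    cc <- concatenateScheme(p, schemes$pubMLST)
    lens <- vapply(geneOrder(schemes$pubMLST), function(g)
        unique(Biostrings::width(locusSequences(p, g))), integer(1))
    expect_equal(unique(Biostrings::width(cc)), sum(lens))

    ## same genes, different order: same per-strain character multiset
    c1 <- concatenateScheme(p, schemes$S1)
    for (st in strainNames(p)[1:3])
        expect_equal(sort(strsplit(as.character(cc[[st]]), "")[[1]]),
                     sort(strsplit(as.character(c1[[st]]), "")[[1]]))

    single <- methods::new("MLSTScheme", name = "one", geneOrder = "adk")
    expect_equal(as.character(concatenateScheme(p, single)),
                 as.character(locusSequences(p, "adk")))

    bogus <- methods::new("MLSTScheme", name = "x", geneOrder = "nope")
    expect_error(concatenateScheme(p, bogus), "absent")
})

test_that("p-distances count differing comparable sites", {
    D <- pDistanceMatrix(c(a = "ACGT", b = "ACGA"))
    expect_equal(D["a", "b"], 0.25)
    expect_equal(D, t(D))
    expect_equal(diag(D), c(a = 0, b = 0))
    ## pairwise deletion of ambiguous sites
    D2 <- pDistanceMatrix(c(a = "ACGN", b = "ACTN"))
    expect_equal(D2["a", "b"], 1 / 3)
})

test_that("neighbor joining recovers additive trees exactly", {
    ## fixed 4-taxon case
    tr <- ape::read.tree(text = "((a:1,b:2):1.5,c:3,d:4);")
    D <- ape::cophenetic.phylo(tr)
    nj <- neighborJoining(D)
    expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(nj$edge.length), sort(tr$edge.length))

    ## property: random additive matrices over 5-8 leaves
    set.seed(81)
    for (rep in 1:15) {
        n <- sample(5:8, 1)
        t0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
        D0 <- ape::cophenetic.phylo(t0)
        nj0 <- neighborJoining(D0)
        expect_equal(ape::dist.topo(ape::unroot(nj0), ape::unroot(t0)), 0,
                     ignore_attr = TRUE)
    }

    expect_warning(neighborJoining(matrix(c(0, 1, 1, 0), 2, 2,
                                          dimnames = list(c("a", "b"),
                                                          c("a", "b")))),
                   "trivial")
})

test_that("species monophyly detection works on labelled trees", {
    tr <- ape::read.tree(text = "(((a1:1,a2:1):2,(b1:1,b2:1):2):1,c1:3);")
    sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
    expect_true(all(speciesMonophyletic(tr, sp)))

    mixed <- ape::read.tree(text = "(((a1:1,b1:1):2,(a2:1,b2:1):2):1,c1:3);")
    m <- speciesMonophyletic(mixed, sp)
    expect_false(m[["A"]])
    expect_false(m[["B"]])
    expect_true(m[["C"]])
})

test_that("species identity summaries separate within from between", {
    cfg <- smallConfig(seed = 17, pIntra = 0)
    sim <- generatePanel(cfg)
    r <- speciesIdentitySummary(sim$panel, "locA")
    expect_equal(r$within, c(100, 100))
    expect_true(r$between[2L] < 100)

    ## hamming fast path agrees with the aligner at low divergence (gaps
    ## cannot pay for themselves there); at high divergence the aligner can
    ## only report equal-or-higher identity
    cfg2 <- smallConfig(seed = 18)
    sim2 <- generatePanel(cfg2)
    rH <- speciesIdentitySummary(sim2$panel, "locB", method = "hamming")
    rA <- speciesIdentitySummary(sim2$panel, "locB", method = "align")
    expect_equal(rH$within, rA$within, tolerance = 1e-9)
    expect_true(all(rA$between >= rH$between - 1e-9))

    single <- panelFromList(list(l = c(s1 = "ACGT", s2 = "ACGA")),
                            species = c(s1 = "sp", s2 = "sp"))
    r2 <- speciesIdentitySummary(single, "l")
    expect_true(all(is.na(r2$between)))
})
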