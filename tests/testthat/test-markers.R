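defs <- markerDefs

mutateAt <- function(s, pos, base) { substr(s, pos, pos) <- base; s }

test_that("marker definitions satisfy the product-length arithmetic", {
    el <- function(l) defs[[l]]@expectedLengths
    expect_equal(el("DW1")[["dominant"]] - el("DW1")[["recessive"]], 0)
    expect_equal(el("DW2")[["dominant"]] - el("DW2")[["recessive"]], 2)
    expect_equal(el("DW3")[["dominant"]] - el("DW3")[["recessive"]], 882)
    expect_equal(el("DW3")[["dominant"]], 1263 + 882)
    expect_equal(unname(el("DW1")), c(427, 427))
    expect_equal(unname(el("DW2")), c(995, 997))
    # inconsistent lengths are rejected at construction
    bad <- defs$DW2
    expect_error({ bad@expectedLengths <- c(recessive = 995, dominant = 999)
                   validObject(bad) }, "inconsistent")
})

test_that("reference amplicons are bracketed by the primer pair", {
    for (l in names(defs)) {
        d <- defs[[l]]
        expect_identical(substr(d@refAmplicon, 1, nchar(d@primerFwd)),
                         d@primerFwd)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(d@primerRev)))
        n <- nchar(d@refAmplicon)
        expect_identical(substr(d@refAmplicon, n - nchar(rc) + 1, n), rc)
    }
})

test_that("the Dw1 SNP caller reads the diagnostic base", {
    d <- defs$DW1
    domSeq <- alleleAmplicon(d, "DOMINANT")
    recSeq <- alleleAmplicon(d, "RECESSIVE")
    expect_identical(callDw1(ampliconObservation("a", "DW1", domSeq), d)@genotype,
                     "Dw1Dw1")
    expect_identical(callDw1(ampliconObservation("a", "DW1", recSeq), d)@genotype,
                     "dw1dw1")
    nCall <- callDw1(ampliconObservation("a", "DW1",
                                         mutateAt(recSeq, d@siteOffset, "N")), d)
    expect_false(nCall@callable)
    expect_true("AMBIGUOUS_BASE" %in% nCall@flags)
    gCall <- callDw1(ampliconObservation("a", "DW1",
                                         mutateAt(recSeq, d@siteOffset, "G")), d)
    expect_false(gCall@callable)
})

test_that("a single anchor mismatch falls back to the fuzzy scan with a flag", {
    d <- defs$DW1
    s <- alleleAmplicon(d, "DOMINANT")
    s <- mutateAt(s, d@siteOffset - 5L,
                  setdiff(c("A", "C", "G", "T"),
                          substr(s, d@siteOffset - 5L, d@siteOffset - 5L))[1])
    cc <- callDw1(ampliconObservation("a", "DW1", s), d)
    expect_true(cc@callable)
    expect_identical(cc@genotype, "Dw1Dw1")
    expect_true("ANCHOR_SHIFTED" %in% cc@flags)
})

test_that("destroyed anchors make the observation uncallable", {
    d <- defs$DW1
    s <- alleleAmplicon(d, "RECESSIVE")
    # scramble the whole left anchor region
    substr(s, d@siteOffset - 15L, d@siteOffset - 1L) <- "TTTTTTTTTTTTTTT"
    cc <- callDw1(ampliconObservation("a", "DW1", s), d)
    expect_false(cc@callable)
    expect_match(cc@evidenceNote, "anchors not found")
})

test_that("the Dw2 caller distinguishes GA present, deleted and corrupted", {
    d <- defs$DW2
    domSeq <- alleleAmplicon(d, "DOMINANT")    # 997 bp, GA present
    recSeq <- alleleAmplicon(d, "RECESSIVE")   # 995 bp, GA absent
    expect_equal(nchar(domSeq), 997)
    expect_equal(nchar(recSeq), 995)
    expect_identical(callDw2(ampliconObservation("a", "DW2", domSeq), d)@genotype,
                     "Dw2Dw2")
    expect_identical(callDw2(ampliconObservation("a", "DW2", recSeq), d)@genotype,
                     "dw2dw2")
    # GA -> GC: neither allele's feature
    gc <- mutateAt(domSeq, d@siteOffset + 2L, "C")
    expect_false(callDw2(ampliconObservation("a", "DW2", gc), d)@callable)
    # partial deletion: only the G remains
    partial <- paste0(substr(recSeq, 1, d@siteOffset), "G",
                      substr(recSeq, d@siteOffset + 1L, nchar(recSeq)))
    expect_false(callDw2(ampliconObservation("a", "DW2", partial), d)@callable)
})

test_that("Dw3 gel calling windows behave at and beyond the tolerance boundary", {
    d <- defs$DW3
    call <- function(len, ...)
        callDw3(ampliconObservation("a", "DW3", bandLength = len), d, ...)
    expect_identical(call(1263)@genotype, "dw3dw3")
    expect_identical(call(2145)@genotype, "Dw3Dw3")
    expect_false(call(1700)@callable)
    # boundary both sides of each window (5% default tolerance)
    inside <- call(1263 * 1.049)
    expect_identical(inside@genotype, "dw3dw3")
    expect_true("SIZE_TOLERANCE_USED" %in% inside@flags)
    expect_false(call(1263 * 1.051)@callable)
    expect_identical(call(2145 * 0.951)@genotype, "Dw3Dw3")
    expect_false(call(2145 * 0.949)@callable)
    expect_false(call(1263 * 0.949)@callable)
    # a tolerance that merges the windows is a configuration error
    expect_error(call(1500, tolerance = 0.35), "overlap")
})

test_that("Dw3 sequence mode detects the tandem duplication", {
    d <- defs$DW3
    domSeq <- alleleAmplicon(d, "DOMINANT")
    recSeq <- alleleAmplicon(d, "RECESSIVE")
    expect_equal(nchar(domSeq), 2145)
    expect_identical(callDw3(ampliconObservation("a", "DW3", domSeq), d)@genotype,
                     "Dw3Dw3")
    expect_identical(callDw3(ampliconObservation("a", "DW3", recSeq), d)@genotype,
                     "dw3dw3")
})

test_that("the Dw4 call is a constant recessive genotype", {
    one <- callDw4("SX44B")
    expect_identical(one@genotype, "dw4dw4")
    expect_match(one@evidenceNote, "uncloned")
    expect_identical(callDw4("SX44B")@genotype, callDw4("SX44B")@genotype)
    panel <- referencePanel()
    calls <- vapply(accessionNames(panel),
                    function(a) callDw4(a)@genotype, character(1))
    expect_identical(unname(unique(calls)), "dw4dw4")
    expect_length(calls, 95L)
})

test_that("four homozygous calls assemble into a genotype, incomplete sets fail", {
    mk <- function(locus, geno)
        new("MarkerCall", accession = "a", locus = locus, genotype = geno,
            callable = TRUE, evidenceNote = "", flags = character())
    g <- assembleGenotype(list(mk("DW1", "Dw1Dw1"), mk("DW2", "dw2dw2"),
                               mk("DW3", "dw3dw3"), callDw4("a")))
    expect_identical(formatGenotype(g, shorthand = TRUE), "Dw1-dw2-dw3-dw4")
    g2 <- assembleGenotype(list(mk("DW1", "dw1dw1"), mk("DW2", "Dw2Dw2"),
                                mk("DW3", "dw3dw3"), callDw4("a")))
    expect_identical(formatGenotype(g2, shorthand = TRUE), "dw1-Dw2-dw3-dw4")
    expect_error(assembleGenotype(list(mk("DW1", "Dw1Dw1"), mk("DW2", "dw2dw2"),
                                       mk("DW3", "dw3dw3"))), "one call per locus")
    unc <- new("MarkerCall", accession = "a", locus = "DW3",
               genotype = NA_character_, callable = FALSE,
               evidenceNote = "band outside windows", flags = character())
    expect_error(assembleGenotype(list(mk("DW1", "Dw1Dw1"), mk("DW2", "dw2dw2"),
                                       unc, callDw4("a"))), "DW3")
})

test_that("calling recovers the generating allele for every locus and allele", {
    set.seed(7)
    for (rep in 1:10) for (l in names(defs)) for (al in c("RECESSIVE", "DOMINANT")) {
        s <- generateAmplicon(defs[[l]], al)
        cc <- callMarker(ampliconObservation("a", l, s), defs[[l]])
        expect_true(cc@callable)
        expect_identical(cc@genotype,
                         .hom <- paste0(rep(paste0(
                             if (al == "DOMINANT") "Dw" else "dw",
                             substr(l, 3, 3)), 2), collapse = ""))
    }
})

test_that("gel calls are invariant to band perturbation within tolerance", {
    d <- defs$DW3
    set.seed(11)
    for (i in 1:50) {
        jitter <- stats::runif(1, -0.049, 0.049)
        len <- 1263 * (1 + jitter)
        expect_identical(
            callDw3(ampliconObservation("a", "DW3", bandLength = len), d)@genotype,
            "dw3dw3")
    }
})
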