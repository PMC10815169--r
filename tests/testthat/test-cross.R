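test_that("homozygous parents give a single deterministic F1 genotype", {
    # A2V4A x CS3541B
    cr <- predictF1("Dw1-dw2-dw3-dw4", "dw1-Dw2-dw3-dw4")
    off <- offspring(cr)
    expect_identical(off$genotype, "Dw1dw1-Dw2dw2-dw3dw3-dw4dw4")
    expect_equal(off$probability, 1)
    # TX623A x TX3197B: same parental genotype on both sides
    cr2 <- predictF1("dw1-Dw2-dw3-dw4", "dw1-Dw2-dw3-dw4")
    expect_identical(offspring(cr2)$genotype, "dw1dw1-Dw2Dw2-dw3dw3-dw4dw4")
    # selfing a homozygote is the identity
    cr3 <- predictF1("Dw1-Dw2-Dw3-dw4", "Dw1-Dw2-Dw3-dw4")
    expect_identical(offspring(cr3)$genotype,
                     canonicalGenotype("Dw1-Dw2-Dw3-dw4"))
})

test_that("a heterozygous locus segregates 1/4 : 1/2 : 1/4", {
    het <- "Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4"
    off <- offspring(predictF1(het, het))
    p <- setNames(off$probability, off$genotype)
    expect_equal(unname(p["Dw1Dw1-Dw2Dw2-dw3dw3-dw4dw4"]), 0.25)
    expect_equal(unname(p["Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4"]), 0.5)
    expect_equal(unname(p["dw1dw1-Dw2Dw2-dw3dw3-dw4dw4"]), 0.25)
    # matches the exhaustive gamete-pairing oracle
    oracle <- bruteForceF1(parseGenotype(het), parseGenotype(het))
    expect_equal(p[order(names(p))], oracle)
})

test_that("prediction matches exhaustive gamete enumeration on random parents", {
    set.seed(101)
    for (i in 1:25) {
        f <- randomGenotype(); m <- randomGenotype()
        off <- offspring(predictF1(f, m))
        got <- setNames(off$probability, off$genotype)
        expect_equal(got[order(names(got))], bruteForceF1(f, m))
    }
})

test_that("offspring probabilities always sum to one", {
    set.seed(102)
    for (i in 1:50) {
        off <- offspring(predictF1(randomGenotype(), randomGenotype()))
        expect_equal(sum(off$probability), 1)
    }
})

test_that("reciprocal crosses predict identical offspring distributions", {
    set.seed(103)
    for (i in 1:20) {
        f <- randomGenotype(); m <- randomGenotype()
        a <- offspring(predictF1(f, m))
        b <- offspring(predictF1(m, f))
        expect_identical(a$genotype, b$genotype)
        expect_equal(a$probability, b$probability)
    }
})

test_that("offspring dwarf classes aggregate correctly", {
    # A2V4A x SX1042 -> two-dwarf with probability 1
    cls <- predictF1Class(predictF1("Dw1-dw2-dw3-dw4", "dw1-Dw2-dw3-dw4"))
    expect_identical(cls$dwarf_class, "two-dwarf")
    expect_equal(cls$probability, 1)
    # TX623A x SX1042 -> three-dwarf
    cls2 <- predictF1Class(predictF1("dw1-Dw2-dw3-dw4", "dw1-Dw2-dw3-dw4"))
    expect_identical(cls2$dwarf_class, "three-dwarf")
    # fully recessive selfing
    cls3 <- predictF1Class(predictF1("dw1-dw2-dw3-dw4", "dw1-dw2-dw3-dw4"))
    expect_identical(cls3$dwarf_class, "four-dwarf")
    # segregating cross aggregates per class
    het <- "Dw1dw1-dw2dw2-dw3dw3-dw4dw4"
    cls4 <- predictF1Class(predictF1(het, het))
    p <- setNames(cls4$probability, cls4$dwarf_class)
    expect_equal(unname(p["three-dwarf"]), 0.75)
    expect_equal(unname(p["four-dwarf"]), 0.25)
})

test_that("the five-parent diallel reproduces every published F1 genotype", {
    panel <- panelData(referencePanel())
    parents <- c("A2V4B", "SX44B", "CS3541B", "TX623B", "TX3197B")
    geno <- setNames(panel$genotype[match(parents, panel$name)], parents)
    dia <- buildDiallel(geno)
    expect_length(dia@cells, 20L)
    fix <- read.csv(fixturePath("diallel_f1.csv"), check.names = FALSE)
    for (i in seq_len(nrow(fix))) {
        # crosses use A-line females; genotypes come from the B maintainer
        f <- sub("A$", "B", fix$female[i])
        cell <- diallelCell(dia, f, fix$male[i])
        expect_identical(offspring(cell)$genotype,
                         canonicalGenotype(fix$f1_genotype[i]),
                         info = paste(fix$female[i], "x", fix$male[i]))
        expect_equal(offspring(cell)$probability, 1)
    }
    # reciprocal symmetry as printed: (A2V4A x TX3197B) = (TX3197A x A2V4B)
    expect_identical(offspring(diallelCell(dia, "A2V4B", "TX3197B"))$genotype,
                     offspring(diallelCell(dia, "TX3197B", "A2V4B"))$genotype)
})

test_that("diallel construction validates its parents", {
    expect_error(buildDiallel(c(a = "Dw1-dw2-dw3-dw4")), "two")
    expect_error(buildDiallel(setNames(rep("Dw1-dw2-dw3-dw4", 2), c("a", "a"))),
                 "duplicate")
    two <- buildDiallel(c(a = "Dw1-dw2-dw3-dw4", b = "dw1-Dw2-dw3-dw4"))
    expect_length(two@cells, 2L)
})

test_that("test crosses group into the published four genotype groups", {
    panel <- panelData(referencePanel())
    fix <- read.csv(fixturePath("testcross_f1.csv"), check.names = FALSE)
    geno <- function(nm) {
        nm <- sub("^(A2V4|SX44|TX623|TX3197)A$", "\\1B", nm)
        panel$genotype[match(nm, panel$name)]
    }
    crosses <- lapply(seq_len(nrow(fix)), function(i)
        predictF1(geno(fix$female[i]), geno(fix$male[i]),
                  fix$female[i], fix$male[i]))
    groups <- groupTestcrosses(crosses)
    expect_length(groups, 4L)
    expect_identical(unname(vapply(groups, nrow, integer(1))),
                     rep(4L, 4))
    expect_setequal(names(groups), canonicalGenotype(unique(fix$f1_genotype)))
    # published co-grouping: A2V4A x TX7078 and SX44A x SX1042 share a group
    g1 <- groups[["Dw1dw1-Dw2dw2-dw3dw3-dw4dw4"]]
    expect_true(any(g1$female == "A2V4A" & g1$male == "TX7078"))
    expect_true(any(g1$female == "SX44A" & g1$male == "SX1042"))
    # every predicted F1 genotype matches the printed one, cross for cross
    for (i in seq_len(nrow(fix)))
        expect_identical(offspring(crosses[[i]])$genotype,
                         canonicalGenotype(fix$f1_genotype[i]))
})

test_that("grouping rejects segregating crosses and accepts a singleton", {
    het <- predictF1("Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4", "Dw1-Dw2-dw3-dw4",
                     "f", "m")
    expect_error(groupTestcrosses(list(het)), "segregates")
    single <- groupTestcrosses(list(predictF1("Dw1-dw2-dw3-dw4",
                                              "dw1-Dw2-dw3-dw4", "f", "m")))
    expect_length(single, 1L)
    expect_identical(nrow(single[[1]]), 1L)
})
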