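## Mendelian F1 prediction: independent segregation of the four height
## loci, no linkage, no parent-of-origin effects.

.locusOffspring <- function(fAlleles, mAlleles) {
    # P(dominant gamete) = fraction of dominant copies in the parent
    pf <- mean(fAlleles)
    pm <- mean(mAlleles)
    p <- c(DD = pf * pm,
           Dd = pf * (1 - pm) + (1 - pf) * pm,
           dd = (1 - pf) * (1 - pm))
    p[p > 0]
}

.asGenotype <- function(g) {
    if (is.character(g)) parseGenotype(g) else {
        stopifnot(is(g, "DwGenotype")); g
    }
}

#' Predict the F1 genotype distribution of a cross
#'
#' Each parent contributes one of its two copies per locus with
#' probability 1/2; loci combine independently and identical multi-locus
#' genotypes are collapsed, summing probabilities. Two homozygous
#' parents therefore yield a single offspring genotype with
#' probability 1, while heterozygous parents segregate (e.g. a
#' heterozygous x heterozygous locus gives 1/4 : 1/2 : 1/4).
#'
#' @param female,male parent genotypes
#'   (\code{\linkS4class{DwGenotype}} or genotype string).
#' @param femaleId,maleId parent labels stored on the result.
#' @return a \code{\linkS4class{CrossResult}}.
#' @examples
#' cr <- predictF1("Dw1-dw2-dw3-dw4", "dw1-Dw2-dw3-dw4")
#' offspring(cr)   # Dw1dw1-Dw2dw2-dw3dw3-dw4dw4, p = 1
#' @export
predictF1 <- function(female, male, femaleId = "female", maleId = "male") {
    fg <- .asGenotype(female)@alleles
    mg <- .asGenotype(male)@alleles
    perLocus <- lapply(DW_LOCI, function(l)
        .locusOffspring(fg[l, ], mg[l, ]))
    names(perLocus) <- DW_LOCI
    combos <- expand.grid(lapply(perLocus, names),
                          stringsAsFactors = FALSE)
    prob <- apply(expand.grid(lapply(perLocus, unname)), 1, prod)
    tokens <- function(state, locus) {
        d <- substr(locus, 3, 3)
        switch(state,
               DD = paste0("Dw", d, "Dw", d),
               Dd = paste0("Dw", d, "dw", d),
               dd = paste0("dw", d, "dw", d))
    }
    geno <- vapply(seq_len(nrow(combos)), function(i)
        paste(mapply(tokens, unlist(combos[i, ]), DW_LOCI),
              collapse = "-"), character(1))
    off <- data.frame(genotype = geno, probability = prob,
                      stringsAsFactors = FALSE)
    off <- stats::aggregate(probability ~ genotype, off, sum)
    off$dwarf_class <- as.character(classifyDwarfType(off$genotype))
    off <- off[order(-off$probability, off$genotype), , drop = FALSE]
    rownames(off) <- NULL
    new("CrossResult", female = femaleId, male = maleId, offspring = off)
}

#' Offspring table of a cross
#'
#' @param x a \code{\linkS4class{CrossResult}}.
#' @return data.frame with columns \code{genotype}, \code{probability},
#'   \code{dwarf_class}.
#' @export
offspring <- function(x) {
    stopifnot(is(x, "CrossResult"))
    x@offspring
}

#' Dwarf-class distribution of predicted offspring
#'
#' Classifies each offspring genotype and aggregates probabilities per
#' dwarf class.
#'
#' @param result a \code{\linkS4class{CrossResult}}.
#' @return data.frame with columns \code{dwarf_class},
#'   \code{probability}, classes in decreasing probability.
#' @export
predictF1Class <- function(result) {
    stopifnot(is(result, "CrossResult"))
    agg <- stats::aggregate(probability ~ dwarf_class, result@offspring, sum)
    agg <- agg[order(-agg$probability, agg$dwarf_class), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Build a complete diallel among a parent set
#'
#' Predicts the F1 of every ordered off-diagonal pair. In hybrid seed
#' production the female of each cross is a cytoplasmic male-sterile A
#' line and the male a fertile line; A/B line pairs are genotypically
#' identical, so a single genotype per parent suffices for both
#' directions. Reciprocal cells carry identical offspring genotype sets
#' by construction.
#'
#' @param parents named character vector of genotype strings (names are
#'   parent ids), or a named list of \code{\linkS4class{DwGenotype}}s.
#' @return a \code{\linkS4class{DiallelTable}}.
#' @export
buildDiallel <- function(parents) {
    ids <- names(parents)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("parents must be named by parent id", call. = FALSE)
    if (anyDuplicated(ids))
        stop(sprintf("duplicate parent id: %s", ids[duplicated(ids)][1]),
             call. = FALSE)
    if (length(ids) < 2L)
        stop("a diallel needs at least two parents", call. = FALSE)
    cells <- list()
    for (f in ids) for (m in ids) {
        if (f == m) next
        cells[[paste(f, m, sep = "|")]] <-
            predictF1(parents[[f]], parents[[m]], f, m)
    }
    new("DiallelTable", parents = ids, cells = cells)
}

#' Extract one cell of a diallel
#'
#' @param x a \code{\linkS4class{DiallelTable}}.
#' @param female,male parent ids.
#' @return the \code{\linkS4class{CrossResult}} for that ordered pair.
#' @export
diallelCell <- function(x, female, male) {
    stopifnot(is(x, "DiallelTable"))
    key <- paste(female, male, sep = "|")
    if (is.null(x@cells[[key]]))
        stop(sprintf("no cell %s", key), call. = FALSE)
    x@cells[[key]]
}

#' Flatten a diallel to a data.frame
#'
#' @param x a \code{\linkS4class{DiallelTable}}.
#' @return data.frame with one row per (cell, offspring genotype):
#'   \code{female}, \code{male}, \code{genotype}, \code{probability},
#'   \code{dwarf_class}.
#' @export
diallelFrame <- function(x) {
    stopifnot(is(x, "DiallelTable"))
    rows <- lapply(x@cells, function(cr)
        cbind(female = cr@female, male = cr@male, cr@offspring,
              stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Group test crosses by predicted F1 genotype
#'
#' Test-cross designs pair each sterile line with each restorer; because
#' all parents are homozygous inbreds, each cross has a single predicted
#' F1 genotype, and crosses sharing that genotype form a group. A cross
#' with a segregating (multi-genotype) offspring distribution cannot be
#' grouped and raises an error.
#'
#' @param crosses list of single-offspring
#'   \code{\linkS4class{CrossResult}}s.
#' @return named list (key: canonical F1 genotype string) of data.frames
#'   with columns \code{female}, \code{male}.
#' @export
groupTestcrosses <- function(crosses) {
    multi <- vapply(crosses, function(cr) nrow(cr@offspring) > 1L, logical(1))
    if (any(multi)) {
        bad <- crosses[[which(multi)[1]]]
        stop(sprintf(
            "cross %s x %s segregates (%d offspring genotypes); grouping requires homozygous parents",
            bad@female, bad@male, nrow(bad@offspring)), call. = FALSE)
    }
    keys <- vapply(crosses, function(cr) cr@offspring$genotype[1], character(1))
    out <- lapply(split(seq_along(crosses), keys), function(idx)
        data.frame(
            female = vapply(crosses[idx], slot, character(1), "female"),
            male = vapply(crosses[idx], slot, character(1), "male"),
            stringsAsFactors = FALSE))
    # preserve first-appearance order of groups
    out[unique(keys)]
}

setMethod("show", "CrossResult", function(object) {
    cat(sprintf("CrossResult: %s x %s\n", object@female, object@male))
    print(object@offspring)
})

setMethod("show", "DiallelTable", function(object) {
    cat(sprintf("DiallelTable: %d parents, %d cells\n",
                length(object@parents), length(object@cells)))
    cat("  parents:", paste(object@parents, collapse = ", "), "\n")
})
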