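## Four-locus genotype model: parsing, formatting, dwarf classification.

.canonAlleles <- function(m) {
    # dominant copy first within each locus; keeps genotype equality simple
    m <- m[DW_LOCI, , drop = FALSE]
    t(apply(m, 1, sort, decreasing = TRUE))
}

#' Construct a four-locus genotype
#'
#' @param dw1,dw2,dw3,dw4 logical length-2 vectors, one element per
#'   allele copy, \code{TRUE} = dominant.
#' @return A \code{\linkS4class{DwGenotype}}.
#' @examples
#' g <- DwGenotype(dw1 = c(TRUE, TRUE), dw2 = c(FALSE, FALSE),
#'                 dw3 = c(FALSE, FALSE), dw4 = c(FALSE, FALSE))
#' classifyDwarfType(g)
#' @export
DwGenotype <- function(dw1, dw2, dw3, dw4) {
    m <- rbind(DW1 = dw1, DW2 = dw2, DW3 = dw3, DW4 = dw4)
    storage.mode(m) <- "logical"
    m <- .canonAlleles(m)
    rownames(m) <- DW_LOCI
    new("DwGenotype", alleles = m)
}

.alleleTokenRx <- "^[Dd][Ww][1-4]$"

.parseToken <- function(tok, orig) {
    # one dash-separated token: "Dw1" (shorthand) or "Dw1dw1" (long form)
    n <- nchar(tok)
    if (!n %in% c(3L, 6L))
        stop(sprintf("malformed allele token '%s' in genotype '%s'",
                     tok, orig), call. = FALSE)
    copies <- if (n == 3L) c(tok, tok) else
        c(substr(tok, 1, 3), substr(tok, 4, 6))
    if (!all(grepl(.alleleTokenRx, copies)))
        stop(sprintf("malformed allele token '%s' in genotype '%s'",
                     tok, orig), call. = FALSE)
    digits <- substr(copies, 3, 3)
    if (digits[1] != digits[2])
        stop(sprintf("allele copies of token '%s' name different loci in '%s'",
                     tok, orig), call. = FALSE)
    list(locus = paste0("DW", digits[1]),
         dominant = substr(copies, 1, 1) == "D")
}

#' Parse a genotype string
#'
#' Accepts the conventional dashed notation, either long form with both
#' copies per locus (\code{"Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4"}) or the
#' shorthand used for fully homozygous material (\code{"Dw1-Dw2-dw3-dw4"}),
#' where a single token expands to a homozygous pair. A copy is dominant
#' iff its token starts with a capital \code{D}; the case of the second
#' letter is ignored, so the typeset variant \code{"DW2"} reads as a
#' dominant copy. Loci may appear in any order but each exactly once.
#'
#' @param s genotype string.
#' @return A \code{\linkS4class{DwGenotype}}.
#' @seealso \code{\link{formatGenotype}}, the inverse.
#' @examples
#' parseGenotype("Dw1-Dw2-dw3-dw4")
#' parseGenotype("dw1dw1-Dw2DW2-dw3dw3-dw4dw4")
#' @export
parseGenotype <- function(s) {
    stopifnot(is.character(s), length(s) == 1L, !is.na(s))
    toks <- strsplit(trimws(s), "-", fixed = TRUE)[[1]]
    if (length(toks) != 4L)
        stop(sprintf("genotype '%s' has %d dash-separated tokens, expected 4",
                     s, length(toks)), call. = FALSE)
    parsed <- lapply(toks, .parseToken, orig = s)
    loci <- vapply(parsed, `[[`, character(1), "locus")
    if (anyDuplicated(loci))
        stop(sprintf("locus %s appears more than once in genotype '%s'",
                     loci[duplicated(loci)][1], s), call. = FALSE)
    m <- matrix(FALSE, 4, 2, dimnames = list(DW_LOCI, NULL))
    for (p in parsed) m[p$locus, ] <- p$dominant
    new("DwGenotype", alleles = .canonAlleles(m))
}

#' Serialize a genotype
#'
#' Long form lists both copies per locus with the dominant copy first
#' (\code{"Dw1dw1-..."}); shorthand collapses homozygous pairs to a
#' single token and is only legal for fully homozygous genotypes. Loci
#' are always emitted in Dw1..Dw4 order.
#'
#' @param g a \code{\linkS4class{DwGenotype}}.
#' @param shorthand emit the homozygous shorthand form.
#' @return character scalar.
#' @examples
#' formatGenotype(parseGenotype("Dw1-Dw2-Dw3-dw4"), shorthand = TRUE)
#' @export
formatGenotype <- function(g, shorthand = FALSE) {
    stopifnot(is(g, "DwGenotype"))
    a <- g@alleles
    digit <- substr(DW_LOCI, 3, 3)
    tok <- function(dom, d) paste0(ifelse(dom, "Dw", "dw"), d)
    if (shorthand) {
        if (any(a[, 1] != a[, 2]))
            stop("shorthand form requires a fully homozygous genotype",
                 call. = FALSE)
        return(paste(tok(a[, 1], digit), collapse = "-"))
    }
    paste(paste0(tok(a[, 1], digit), tok(a[, 2], digit)), collapse = "-")
}

#' Canonicalize genotype strings
#'
#' Round-trips each string through the parser so that spelling variants
#' (shorthand, locus order, second-letter case) map to one canonical
#' long-form serialization. Vectorized.
#'
#' @param s character vector of genotype strings.
#' @param shorthand emit shorthand (homozygous genotypes only).
#' @return character vector.
#' @export
canonicalGenotype <- function(s, shorthand = FALSE) {
    vapply(s, function(x) formatGenotype(parseGenotype(x), shorthand),
           character(1), USE.NAMES = FALSE)
}

#' Number of recessive-homozygous loci
#'
#' @param g a \code{\linkS4class{DwGenotype}} or genotype string.
#' @return integer in 0..4.
#' @export
dwarfGeneCount <- function(g) {
    if (is.character(g)) g <- parseGenotype(g)
    stopifnot(is(g, "DwGenotype"))
    sum(!g@alleles[, 1] & !g@alleles[, 2])
}

#' Classify a genotype into its dwarf class
#'
#' The five-level height categorization counts the loci that are
#' recessive-homozygous: a locus carrying at least one dominant copy is
#' not counted, so heterozygous loci behave as dominant. Total on all
#' valid genotypes; the zero- and four-dwarf classes are representable
#' even though typical breeding panels contain neither.
#'
#' @param g a \code{\linkS4class{DwGenotype}}, a genotype string, or a
#'   character vector of genotype strings.
#' @return factor with levels \code{DWARF_CLASSES} (same length as the
#'   input vector).
#' @examples
#' classifyDwarfType("Dw1Dw1-dw2dw2-dw3dw3-dw4dw4")   # three-dwarf
#' classifyDwarfType("Dw1dw1-Dw2dw2-dw3dw3-dw4dw4")   # two-dwarf
#' @export
classifyDwarfType <- function(g) {
    if (is(g, "DwGenotype"))
        return(factor(DWARF_CLASSES[dwarfGeneCount(g) + 1L],
                      levels = DWARF_CLASSES))
    stopifnot(is.character(g))
    n <- vapply(g, function(x) dwarfGeneCount(parseGenotype(x)), integer(1))
    factor(DWARF_CLASSES[n + 1L], levels = DWARF_CLASSES, exclude = NULL)
}

setMethod("show", "DwGenotype", function(object) {
    cat("DwGenotype:", formatGenotype(object), "\n")
    cat("  class:", as.character(classifyDwarfType(object)),
        sprintf("(%d recessive-homozygous loci)\n", dwarfGeneCount(object)))
})
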