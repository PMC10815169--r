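#' @import methods
NULL

#' The four classical sorghum plant-height loci, in canonical order.
#'
#' @export
DW_LOCI <- c("DW1", "DW2", "DW3", "DW4")

#' Dwarf-class labels in the five-level height categorization.
#'
#' A genotype's dwarf class is the number of loci that are
#' recessive-homozygous; heterozygous loci count as dominant.
#'
#' @export
DWARF_CLASSES <- c("zero-dwarf", "one-dwarf", "two-dwarf",
                   "three-dwarf", "four-dwarf")

#' Four-locus plant-height genotype
#'
#' Holds the allele configuration at the four height loci Dw1--Dw4 as a
#' 4 x 2 logical matrix (\code{TRUE} = dominant copy). The pair of copies
#' at a locus is unordered; objects are stored with the dominant copy
#' first, so two genotypes are identical iff their matrices are equal.
#'
#' Use \code{\link{parseGenotype}} / \code{\link{formatGenotype}} to
#' convert to and from the conventional dashed string form
#' (e.g. \code{"Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4"}, shorthand
#' \code{"Dw1-Dw2-dw3-dw4"} for fully homozygous genotypes).
#'
#' @slot alleles 4 x 2 logical matrix, rows named \code{DW1..DW4};
#'   \code{TRUE} marks a dominant copy.
#' @export
setClass("DwGenotype", representation(alleles = "matrix"))

setValidity("DwGenotype", function(object) {
    a <- object@alleles
    if (!is.logical(a) || !identical(dim(a), c(4L, 2L)))
        return("alleles must be a 4 x 2 logical matrix")
    if (!identical(rownames(a), DW_LOCI))
        return(sprintf("rows must be named %s", paste(DW_LOCI, collapse = ",")))
    if (anyNA(a))
        return("allele states must not be NA")
    if (any(!a[, 1] & a[, 2]))
        return("dominant copy must be stored first at each locus")
    TRUE
})

#' Marker definition for one plant-height locus
#'
#' Describes the diagnostic PCR assay at one locus: the primer pair, a
#' reference amplicon for the recessive allele, and the allele-defining
#' feature. The three cloned loci use three different feature kinds:
#' a single-base A/T change (Dw1), a 2-bp GA deletion (dw2) and an
#' 882-bp tandem duplication (Dw3).
#'
#' All coordinates (\code{siteOffset}, \code{dupStart}) are 1-based
#' offsets into \code{refAmplicon}; published genome-scale positions are
#' retained as free-text metadata only, since they cannot be resolved
#' within the amplicon coordinate system.
#'
#' @slot locus one of \code{DW1}, \code{DW2}, \code{DW3}.
#' @slot primerFwd,primerRev primer sequences, 5'->3'.
#' @slot refAmplicon the recessive-allele product (plain DNA string).
#' @slot markerKind \code{"SNP"}, \code{"DELETION"} or \code{"INSERTION"}.
#' @slot siteOffset SNP: position of the diagnostic base; DELETION: last
#'   reference base before the point where the dominant allele carries
#'   the (otherwise deleted) bases.
#' @slot dominantBase SNP only: the base carried by the dominant allele.
#' @slot indelSeq DELETION only: the bases present in the dominant allele
#'   and absent from the recessive one.
#' @slot dupStart,dupLength INSERTION only: the block of the reference
#'   that is tandem-duplicated in the dominant allele.
#' @slot expectedLengths named numeric, product length per allele
#'   (\code{recessive}, \code{dominant}).
#' @slot publishedPosition coordinate label as published, metadata only.
#' @slot anchorWidth width (nt) of the exact flanking anchors used to
#'   locate the marker site in observed sequence.
#' @slot maxShift maximum positional shift allowed in the fuzzy-anchor
#'   fallback search.
#' @export
setClass("MarkerDefinition", representation(
    locus = "character",
    primerFwd = "character",
    primerRev = "character",
    refAmplicon = "character",
    markerKind = "character",
    siteOffset = "integer",
    dominantBase = "character",
    indelSeq = "character",
    dupStart = "integer",
    dupLength = "integer",
    expectedLengths = "numeric",
    publishedPosition = "character",
    anchorWidth = "integer",
    maxShift = "integer"))

setValidity("MarkerDefinition", function(object) {
    if (!object@locus %in% DW_LOCI[1:3])
        return("locus must be DW1, DW2 or DW3")
    if (!object@markerKind %in% c("SNP", "DELETION", "INSERTION"))
        return("markerKind must be SNP, DELETION or INSERTION")
    el <- object@expectedLengths
    if (!all(c("recessive", "dominant") %in% names(el)))
        return("expectedLengths must name 'recessive' and 'dominant'")
    if (nchar(object@refAmplicon) != el[["recessive"]])
        return("refAmplicon length must equal the recessive product length")
    diff <- el[["dominant"]] - el[["recessive"]]
    ok <- switch(object@markerKind,
        SNP = diff == 0,
        DELETION = diff == nchar(object@indelSeq),
        INSERTION = diff == object@dupLength)
    if (!isTRUE(ok))
        return(sprintf(
            "expectedLengths inconsistent with %s feature (difference %d)",
            object@markerKind, as.integer(diff)))
    TRUE
})

#' One amplicon observation for one accession at one locus
#'
#' Evidence is either a sequenced amplicon (Dw1, Dw2; also usable for
#' Dw3) or a gel band length in bp (Dw3); exactly one of the two must be
#' present.
#'
#' @slot accession accession identifier.
#' @slot locus one of \code{DW1}, \code{DW2}, \code{DW3}.
#' @slot sequence amplicon sequence (IUPAC DNA) or \code{NA}.
#' @slot bandLength measured band length in bp or \code{NA}.
#' @export
setClass("AmpliconObservation", representation(
    accession = "character",
    locus = "character",
    sequence = "character",
    bandLength = "numeric"))

setValidity("AmpliconObservation", function(object) {
    hasSeq <- !is.na(object@sequence)
    hasLen <- !is.na(object@bandLength)
    if (hasSeq == hasLen)
        return("exactly one of sequence and bandLength must be set")
    if (hasLen && object@bandLength <= 0)
        return("bandLength must be positive")
    if (!object@locus %in% DW_LOCI)
        return("unknown locus")
    TRUE
})

#' One allele determination at one locus
#'
#' All panel material is assumed inbred, so a callable result is always
#' a homozygous locus genotype (e.g. \code{"Dw1Dw1"}). Quality flags:
#' \code{ANCHOR_SHIFTED} (fuzzy-anchor fallback used),
#' \code{AMBIGUOUS_BASE} (non-A/T base at the Dw1 site),
#' \code{SIZE_TOLERANCE_USED} (gel band accepted within, but not at, the
#' expected length).
#'
#' @slot accession accession identifier.
#' @slot locus locus name.
#' @slot genotype homozygous token such as \code{"dw3dw3"}, or \code{NA}
#'   when uncallable.
#' @slot callable whether an allele could be determined.
#' @slot evidenceNote human-readable description of the evidence.
#' @slot flags character vector of quality flags.
#' @export
setClass("MarkerCall", representation(
    accession = "character",
    locus = "character",
    genotype = "character",
    callable = "logical",
    evidenceNote = "character",
    flags = "character"))

setValidity("MarkerCall", function(object) {
    if (object@callable && is.na(object@genotype))
        return("callable calls must carry a genotype")
    if (!object@callable && !is.na(object@genotype))
        return("uncallable calls must not carry a genotype")
    TRUE
})

#' Predicted offspring of one cross
#'
#' The F1 genotype distribution of a single cross under independent
#' Mendelian segregation of the four loci. Homozygous x homozygous
#' parents give a single offspring genotype with probability 1.
#'
#' @slot female,male parent identifiers.
#' @slot offspring data.frame with columns \code{genotype} (canonical
#'   long-form string), \code{probability}, \code{dwarf_class}.
#' @export
setClass("CrossResult", representation(
    female = "character",
    male = "character",
    offspring = "data.frame"))

setValidity("CrossResult", function(object) {
    off <- object@offspring
    need <- c("genotype", "probability", "dwarf_class")
    if (!all(need %in% names(off)))
        return("offspring must have genotype, probability, dwarf_class")
    if (abs(sum(off$probability) - 1) > 1e-9)
        return("offspring probabilities must sum to 1")
    if (anyDuplicated(off$genotype))
        return("offspring genotypes must be unique")
    TRUE
})

#' Complete diallel of a parent set
#'
#' All ordered off-diagonal crosses among a set of parents. Reciprocal
#' cells always contain the same offspring genotype set (no
#' parent-of-origin effects are modelled).
#'
#' @slot parents parent identifiers, in order.
#' @slot cells named list of \code{\linkS4class{CrossResult}}, names
#'   \code{"<female>|<male>"}.
#' @export
setClass("DiallelTable", representation(
    parents = "character",
    cells = "list"))

setValidity("DiallelTable", function(object) {
    p <- object@parents
    if (length(p) < 2 || anyDuplicated(p))
        return("at least two unique parents required")
    want <- as.vector(outer(p, p, function(f, m) paste(f, m, sep = "|")))
    want <- setdiff(want, paste(p, p, sep = "|"))
    if (!setequal(names(object@cells), want))
        return("cells must cover exactly the off-diagonal ordered pairs")
    TRUE
})

#' Accession panel
#'
#' An ordered collection of breeding accessions with line type
#' (male-sterile A/B lines vs fertility restorer R lines), subspecies
#' label, optional four-locus genotype and optional architecture traits.
#'
#' @slot accessions data.frame, one row per accession; \code{name} is
#'   unique. Optional columns: \code{genotype} plus the five trait
#'   columns in cm and the derived ratio.
#' @slot provenance free-text origin of the table.
#' @export
setClass("Panel", representation(
    accessions = "data.frame",
    provenance = "character"))

setValidity("Panel", function(object) {
    df <- object@accessions
    if (!all(c("name", "line_type") %in% names(df)))
        return("accessions must have columns name and line_type")
    if (anyDuplicated(df$name))
        return(sprintf("duplicate accession name: %s",
                       df$name[duplicated(df$name)][1]))
    bad <- setdiff(unique(df$line_type), c("male_sterile", "restorer"))
    if (length(bad))
        return(sprintf("unknown line_type: %s", bad[1]))
    TRUE
})
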