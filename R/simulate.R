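## Synthetic-data generator: allele-true amplicon sequences and
## genotype-class phenotype panels. Defaults reproduce the study
## conditions of the 95-accession reference panel (class means/SDs of
## its seven genotype blocks).

#' Default per-class phenotype parameters
#'
#' One row per genotype class of the reference breeding panel, with the
#' generating mean and SD for plant height, spike length and spike
#' stalk length (cm). Multi-accession classes use their observed block
#' mean/SD; the two singleton classes have no observable SD, so their
#' SDs default to 10 percent of the class mean, in line with the
#' coefficients of variation of the multi-accession blocks.
#'
#' @return data.frame with columns \code{genotype}, \code{n_panel},
#'   \code{plant_mean}, \code{plant_sd}, \code{spike_mean},
#'   \code{spike_sd}, \code{stalk_mean}, \code{stalk_sd}.
#' @export
dwClassDefaults <- function() {
    d <- data.frame(
        genotype = c("Dw1-dw2-dw3-dw4", "dw1-Dw2-dw3-dw4",
                     "dw1-dw2-Dw3-dw4", "dw1-Dw2-Dw3-dw4",
                     "Dw1-dw2-Dw3-dw4", "Dw1-Dw2-dw3-dw4",
                     "Dw1-Dw2-Dw3-dw4"),
        n_panel = c(4L, 46L, 1L, 3L, 1L, 30L, 10L),
        plant_mean = c(110.58, 106.56, 90.33, 103.56, 217.00, 124.00, 179.53),
        plant_sd   = c(17.24, 16.47, NA, 12.25, NA, 20.28, 62.00),
        spike_mean = c(25.67, 27.91, 27.67, 25.11, 22.00, 26.38, 24.68),
        spike_sd   = c(1.22, 5.22, NA, 2.14, NA, 5.74, 5.71),
        stalk_mean = c(35.25, 39.20, 39.00, 44.56, 53.00, 31.80, 33.04),
        stalk_sd   = c(3.69, 7.34, NA, 6.21, NA, 6.84, 7.01),
        stringsAsFactors = FALSE)
    for (tr in c("plant", "spike", "stalk")) {
        sdc <- paste0(tr, "_sd"); mc <- paste0(tr, "_mean")
        d[[sdc]][is.na(d[[sdc]])] <- 0.1 * d[[mc]][is.na(d[[sdc]])]
    }
    d
}

#' Build a simulation configuration
#'
#' @param seed integer master seed; fully determines all output.
#' @param nPerClass lines simulated per genotype class; a single value
#'   is recycled over the classes of \code{classParams}. Classes with
#'   \code{n = 0} are allowed.
#' @param classParams per-class generating parameters, as in
#'   \code{\link{dwClassDefaults}} (the default).
#' @param noiseRate per-base substitution rate applied to simulated
#'   amplicons outside marker sites and anchors, in [0, 0.05].
#' @param gelSdBp SD (bp) of Gaussian gel sizing error for simulated
#'   Dw3 band lengths.
#' @return a validated config list of class \code{"dw_sim_config"}.
#' @export
simulationConfig <- function(seed = 1L, nPerClass = 10L,
                             classParams = dwClassDefaults(),
                             noiseRate = 0, gelSdBp = 0) {
    if (noiseRate < 0 || noiseRate > 0.05)
        stop("noiseRate must be in [0, 0.05]", call. = FALSE)
    if (gelSdBp < 0)
        stop("gelSdBp must be >= 0", call. = FALSE)
    means <- unlist(classParams[, grep("_mean$", names(classParams))])
    if (any(means <= 0))
        stop("class means must be positive", call. = FALSE)
    if (any(unlist(classParams[, grep("_sd$", names(classParams))]) < 0))
        stop("class SDs must be nonnegative", call. = FALSE)
    n <- rep_len(as.integer(nPerClass), nrow(classParams))
    if (any(n < 0)) stop("nPerClass must be nonnegative", call. = FALSE)
    structure(list(seed = as.integer(seed), nPerClass = n,
                   classParams = classParams, noiseRate = noiseRate,
                   gelSdBp = gelSdBp),
              class = "dw_sim_config")
}

## Small deterministic integer hash for per-line, per-locus RNG
## substreams: adding lines or classes never reshuffles earlier draws.
.streamSeed <- function(...) {
    h <- 17
    for (v in c(...)) h <- (h * 31 + as.numeric(v)) %% 2147483647
    as.integer(h)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
}

#' The amplicon sequence of one allele
#'
#' Derives the allele's product from the reference (recessive) amplicon:
#' the dominant allele substitutes the diagnostic base (SNP), inserts
#' the otherwise-deleted bases (DELETION) or appends a tandem copy of
#' the duplication block (INSERTION).
#'
#' @param def a \code{\linkS4class{MarkerDefinition}}.
#' @param allele \code{"DOMINANT"} or \code{"RECESSIVE"}.
#' @return character DNA sequence of the expected product length.
#' @export
alleleAmplicon <- function(def, allele = c("RECESSIVE", "DOMINANT")) {
    allele <- match.arg(allele)
    ref <- def@refAmplicon
    if (allele == "RECESSIVE") return(ref)
    switch(def@markerKind,
        SNP = paste0(substr(ref, 1, def@siteOffset - 1L), def@dominantBase,
                     substr(ref, def@siteOffset + 1L, nchar(ref))),
        DELETION = paste0(substr(ref, 1, def@siteOffset), def@indelSeq,
                          substr(ref, def@siteOffset + 1L, nchar(ref))),
        INSERTION = {
            blockEnd <- def@dupStart + def@dupLength - 1L
            paste0(substr(ref, 1, blockEnd),
                   substr(ref, def@dupStart, blockEnd),
                   substr(ref, blockEnd + 1L, nchar(ref)))
        })
}

## 1-based positions that sequence noise must never touch: the marker
## site with its anchors (and both junction copies for the duplication).
.protectedPositions <- function(def, allele) {
    w <- def@anchorWidth
    switch(def@markerKind,
        SNP = (def@siteOffset - w):(def@siteOffset + w),
        DELETION = {
            extra <- if (allele == "DOMINANT") nchar(def@indelSeq) else 0L
            (def@siteOffset - w + 1L):(def@siteOffset + w + extra)
        },
        INSERTION = {
            blockEnd <- def@dupStart + def@dupLength - 1L
            first <- (blockEnd - w + 1L):(blockEnd + w)
            if (allele == "RECESSIVE") first
            else c(first, (blockEnd + def@dupLength - w + 1L):
                          (blockEnd + def@dupLength + w))
        })
}

#' Simulate one amplicon read
#'
#' Generates the allele-true product and optionally applies uniform
#' substitution noise outside the marker site and its anchors, so the
#' generating allele is always recoverable by construction at the
#' marker itself.
#'
#' @param def a \code{\linkS4class{MarkerDefinition}}.
#' @param allele \code{"DOMINANT"} or \code{"RECESSIVE"}.
#' @param noiseRate per-base substitution probability outside the
#'   protected positions.
#' @return character DNA sequence.
#' @export
generateAmplicon <- function(def, allele = c("RECESSIVE", "DOMINANT"),
                             noiseRate = 0) {
    allele <- match.arg(allele)
    seqc <- alleleAmplicon(def, allele)
    if (noiseRate <= 0) return(seqc)
    n <- nchar(seqc)
    hit <- which(stats::runif(n) < noiseRate)
    hit <- setdiff(hit, .protectedPositions(def, allele))
    if (!length(hit)) return(seqc)
    chars <- strsplit(seqc, "")[[1]]
    bases <- c("A", "C", "G", "T")
    for (i in hit)
        chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    paste(chars, collapse = "")
}

## genotype string -> per-locus allele for homozygous simulated lines
.classAlleles <- function(genotype) {
    a <- parseGenotype(genotype)@alleles
    ifelse(a[, 1], "DOMINANT", "RECESSIVE")
}

#' Simulate a breeding panel with amplicon evidence
#'
#' Draws, per genotype class, \code{n} homozygous inbred lines:
#' phenotypes come from the class distributions (Normal, truncated at
#' zero by resampling; plant height and spike length drawn, stem height
#' defined as their difference, spike stalk length drawn and truncated
#' to the stem so the additive trait identities hold by construction)
#' and amplicon evidence for the three callable loci carries each
#' line's true alleles. A fixed master seed fully determines the output;
#' per-line, per-locus substreams keep existing lines stable when more
#' are added.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{panel} (a \code{\linkS4class{Panel}} with
#'   genotype and trait columns), \code{evidence}
#'   (\code{Biostrings::DNAStringSet}, names \code{"line|locus"}) and
#'   \code{bandLengths} (data.frame of simulated Dw3 gel sizes).
#' @export
simulatePanel <- function(cfg) {
    stopifnot(inherits(cfg, "dw_sim_config"))
    defs <- loadMarkerDefinitions()
    cp <- cfg$classParams
    rows <- list(); seqs <- character(); bands <- list()
    for (ci in seq_len(nrow(cp))) {
        geno <- cp$genotype[ci]
        alleles <- .classAlleles(geno)
        for (k in seq_len(cfg$nPerClass[ci])) {
            nm <- sprintf("SIM_C%d_%03d", ci, k)
            ph <- .withSeed(.streamSeed(cfg$seed, ci, k, 0), {
                drawPos <- function(m, s) {
                    for (i in 1:100) {
                        x <- stats::rnorm(1, m, s)
                        if (x > 0) return(x)
                    }
                    m
                }
                repeat {
                    plant <- drawPos(cp$plant_mean[ci], cp$plant_sd[ci])
                    spike <- drawPos(cp$spike_mean[ci], cp$spike_sd[ci])
                    if (plant > spike) break
                }
                stem <- plant - spike
                repeat {
                    stalk <- drawPos(cp$stalk_mean[ci], cp$stalk_sd[ci])
                    if (stalk < stem) break
                }
                c(plant = plant, stem = stem, stalk = stalk, spike = spike)
            })
            rows[[nm]] <- data.frame(
                name = nm, line_type = "restorer",
                subspecies = "synthetic", genotype = geno,
                plant_height_cm = ph[["plant"]],
                stem_height_cm = ph[["stem"]],
                spike_stalk_length_cm = ph[["stalk"]],
                spike_length_cm = ph[["spike"]],
                stringsAsFactors = FALSE)
            for (li in 1:3) {
                locus <- DW_LOCI[li]
                seqs[paste(nm, locus, sep = "|")] <-
                    .withSeed(.streamSeed(cfg$seed, ci, k, li),
                              generateAmplicon(defs[[locus]], alleles[locus],
                                               cfg$noiseRate))
            }
            trueLen <- defs$DW3@expectedLengths[[
                if (alleles[["DW3"]] == "DOMINANT") "dominant" else "recessive"]]
            bands[[nm]] <- data.frame(
                accession = nm, locus = "DW3",
                band_length_bp = .withSeed(.streamSeed(cfg$seed, ci, k, 9),
                    trueLen + stats::rnorm(1, 0, cfg$gelSdBp)),
                stringsAsFactors = FALSE)
        }
    }
    acc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(acc))
        acc <- data.frame(name = character(), line_type = character())
    else
        acc <- deriveMetrics(acc)
    list(panel = new("Panel", accessions = acc,
                     provenance = sprintf("simulated (seed %d)", cfg$seed)),
         evidence = Biostrings::DNAStringSet(seqs),
         bandLengths = do.call(rbind, c(bands, list(make.row.names = FALSE))))
}

#' Write simulated outputs
#'
#' Emits the same panel CSV and FASTA formats the loaders consume.
#'
#' @param sim result of \code{\link{simulatePanel}}.
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
writeSimulated <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    panelPath <- file.path(dir, "simulated_panel.csv")
    fastaPath <- file.path(dir, "simulated_evidence.fasta")
    utils::write.csv(panelData(sim$panel), panelPath, row.names = FALSE)
    Biostrings::writeXStringSet(sim$evidence, fastaPath)
    invisible(c(panel = panelPath, evidence = fastaPath))
}
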