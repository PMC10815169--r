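## Plant-architecture trait derivation and per-genotype-class summaries.
##
## Measured traits (cm, accession means of three field replicates):
## plant height, stem height, spike stalk length (flag-leaf ring to
## panicle base), spike length. Derived: height under the flag leaf
## (stem - spike stalk) and the spike-stalk/stem-height ratio.

.MEASURED <- c("plant_height_cm", "stem_height_cm",
               "spike_stalk_length_cm", "spike_length_cm")
.TRAITS <- c(.MEASURED, "height_under_flag_leaf_cm", "stalk_stem_ratio")

#' Trait column names used throughout the package
#'
#' @return character vector of the six trait columns (four measured,
#'   two derived).
#' @export
traitNames <- function() .TRAITS

#' Derive architecture metrics for phenotype records
#'
#' Fills the two derived traits: height under the flag leaf
#' (\code{stem - spike stalk}) and the spike-stalk/stem-height ratio.
#' Plant height should decompose as \code{stem + spike} up to
#' measurement rounding; records violating this beyond \code{tolerance}
#' are flagged in the \code{height_inconsistent} column, not rejected.
#' Nonpositive stem/plant/spike measurements are a validation error
#' (a zero spike stalk length is allowed and gives ratio 0).
#'
#' @param records data.frame with the four measured trait columns.
#' @param tolerance allowed absolute deviation (cm) of
#'   \code{plant - (stem + spike)}; default 0.05, the rounding slack of
#'   values reported to two decimals.
#' @return the input with \code{height_under_flag_leaf_cm},
#'   \code{stalk_stem_ratio} and \code{height_inconsistent} columns
#'   (re)computed.
#' @examples
#' deriveMetrics(data.frame(plant_height_cm = 115, stem_height_cm = 88.67,
#'                          spike_stalk_length_cm = 39,
#'                          spike_length_cm = 26.33))
#' @export
deriveMetrics <- function(records, tolerance = 0.05) {
    miss <- setdiff(.MEASURED, names(records))
    if (length(miss))
        stop("missing measured trait columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
    pos <- c("plant_height_cm", "stem_height_cm", "spike_length_cm")
    for (col in pos)
        if (any(records[[col]] <= 0, na.rm = TRUE))
            stop(sprintf("nonpositive %s in row %d", col,
                         which(records[[col]] <= 0)[1]), call. = FALSE)
    if (any(records$spike_stalk_length_cm < 0, na.rm = TRUE))
        stop("negative spike stalk length", call. = FALSE)
    records$height_under_flag_leaf_cm <-
        records$stem_height_cm - records$spike_stalk_length_cm
    records$stalk_stem_ratio <-
        records$spike_stalk_length_cm / records$stem_height_cm
    records$height_inconsistent <-
        abs(records$plant_height_cm -
            (records$stem_height_cm + records$spike_length_cm)) > tolerance
    records
}

#' Summarise one group of phenotype records
#'
#' Computes, per trait, the group size, arithmetic mean, sample
#' standard deviation (n - 1 denominator) and coefficient of variation
#' (SD/mean, reported as a fraction). SD and COV are \code{NA} for
#' singleton groups. Values are kept at full precision; round at the
#' reporting stage.
#'
#' @param records data.frame of phenotype records (derived columns are
#'   computed if absent).
#' @param group label stored on the summary.
#' @return data.frame (one row per trait): \code{group}, \code{trait},
#'   \code{n}, \code{mean}, \code{sd}, \code{cov}.
#' @examples
#' h <- data.frame(plant_height_cm = c(115, 86, 126.33, 115),
#'                 stem_height_cm = c(88.67, 61.67, 101.33, 88),
#'                 spike_stalk_length_cm = c(39, 34, 37.33, 30.67),
#'                 spike_length_cm = c(26.33, 24.33, 25, 27))
#' summarizeGroup(h)   # mean plant height 110.58, SD 17.24
#' @export
summarizeGroup <- function(records, group = "group") {
    if (nrow(records) == 0L)
        stop("cannot summarise an empty group", call. = FALSE)
    if (!all(.TRAITS %in% names(records)))
        records <- deriveMetrics(records)
    n <- nrow(records)
    out <- do.call(rbind, lapply(.TRAITS, function(tr) {
        x <- records[[tr]]
        m <- mean(x)
        s <- if (n >= 2L) stats::sd(x) else NA_real_
        data.frame(group = group, trait = tr, n = n, mean = m, sd = s,
                   cov = s / m, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Summarise a panel by genotype class
#'
#' Groups accessions by canonical genotype string and emits one
#' \code{\link{summarizeGroup}} block per genotype. Groups are ordered
#' by dwarf class (most dwarfing loci first, i.e. three-dwarf before
#' two-dwarf before one-dwarf) and, within a class, by first occurrence
#' in the panel. Accessions without a genotype or without complete
#' measurements are listed in the exclusion report, never silently
#' dropped.
#'
#' @param panel a \code{\linkS4class{Panel}} (or its accession
#'   data.frame) carrying genotype and trait columns.
#' @return list with \code{summaries} (stacked per-group summary rows,
#'   plus \code{dwarf_class}) and \code{excluded} (data.frame:
#'   \code{name}, \code{reason}).
#' @export
summarizePanel <- function(panel) {
    df <- if (is(panel, "Panel")) panel@accessions else panel
    if (nrow(df) == 0L)
        return(list(summaries = data.frame(), excluded = data.frame()))
    noGeno <- is.na(df$genotype) | !nzchar(df$genotype)
    noPheno <- !stats::complete.cases(df[, .MEASURED, drop = FALSE])
    excluded <- data.frame(
        name = df$name[noGeno | noPheno],
        reason = ifelse(noGeno[noGeno | noPheno],
                        "missing genotype", "incomplete phenotype"),
        stringsAsFactors = FALSE)
    keep <- df[!(noGeno | noPheno), , drop = FALSE]
    if (nrow(keep) == 0L)
        return(list(summaries = data.frame(), excluded = excluded))
    keep$genotype <- canonicalGenotype(keep$genotype)
    keep <- deriveMetrics(keep)
    groups <- unique(keep$genotype)
    nRec <- vapply(groups, function(g)
        dwarfGeneCount(parseGenotype(g)), integer(1))
    groups <- groups[order(-nRec, match(groups, keep$genotype))]
    summaries <- do.call(rbind, lapply(groups, function(g)
        summarizeGroup(keep[keep$genotype == g, , drop = FALSE], group = g)))
    summaries$dwarf_class <- as.character(classifyDwarfType(summaries$group))
    rownames(summaries) <- NULL
    list(summaries = summaries, excluded = excluded)
}

#' Signed difference between two group means
#'
#' Differences are taken on means rounded to the two-decimal reporting
#' scale, matching how breeding reports tabulate group heights, so that
#' published deltas are reproduced exactly.
#'
#' @param a,b per-group summaries as returned by
#'   \code{\link{summarizeGroup}} (or slices of
#'   \code{summarizePanel()$summaries}).
#' @param trait trait column name.
#' @return \code{round(mean_a, 2) - round(mean_b, 2)}.
#' @export
compareGroupMeans <- function(a, b, trait) {
    pick <- function(s) {
        row <- s[s$trait == trait, , drop = FALSE]
        if (nrow(row) != 1L)
            stop(sprintf("trait '%s' not present exactly once in summary",
                         trait), call. = FALSE)
        row$mean
    }
    round(pick(a), 2) - round(pick(b), 2)
}
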