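## Panel readers/writers, reporting and the pipeline driver.

#' Load an accession panel from CSV
#'
#' Required columns: \code{name}, \code{line_type} (values
#' \code{male_sterile} / \code{restorer}). Optional: \code{subspecies},
#' \code{genotype} (dashed genotype strings, validated and kept
#' verbatim) and the trait columns. Accession names are opaque byte
#' strings -- pedigree-style names and non-ASCII characters are
#' preserved verbatim. Malformed rows are reported with their file line
#' numbers.
#'
#' @param path CSV file (UTF-8, comma-separated, header required).
#' @return a \code{\linkS4class{Panel}}.
#' @examples
#' p <- loadPanel(system.file("extdata", "panel_accessions.csv",
#'                            package = "DwTyper"))
#' lineTypeCounts(p)
#' @export
loadPanel <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
    need <- c("name", "line_type")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("panel is missing required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    # data line i sits on file line i + 1 (header)
    dup <- which(duplicated(df$name))
    if (length(dup))
        stop(sprintf("duplicate accession name '%s' at line %d",
                     df$name[dup[1]], dup[1] + 1L), call. = FALSE)
    if ("genotype" %in% names(df)) {
        for (i in seq_len(nrow(df))) {
            g <- df$genotype[i]
            if (is.na(g) || !nzchar(g)) next
            ok <- tryCatch({ parseGenotype(g); TRUE },
                           error = function(e) conditionMessage(e))
            if (!isTRUE(ok))
                stop(sprintf("line %d: %s", i + 1L, ok), call. = FALSE)
        }
    }
    new("Panel", accessions = df,
        provenance = paste("loaded from", basename(path)))
}

#' Accession table of a panel
#' @param x a \code{\linkS4class{Panel}}.
#' @return the accession data.frame.
#' @export
panelData <- function(x) {
    stopifnot(is(x, "Panel"))
    x@accessions
}

#' Accession names
#' @param x a \code{\linkS4class{Panel}}.
#' @return character vector.
#' @export
accessionNames <- function(x) panelData(x)$name

#' Accession counts by line type
#' @param x a \code{\linkS4class{Panel}}.
#' @return named integer vector.
#' @export
lineTypeCounts <- function(x) {
    tab <- table(panelData(x)$line_type)
    stats::setNames(as.integer(tab), names(tab))
}

setMethod("show", "Panel", function(object) {
    df <- object@accessions
    cat(sprintf("Panel: %d accessions (%s)\n", nrow(df),
                paste(sprintf("%s: %d", names(table(df$line_type)),
                              table(df$line_type)), collapse = ", ")))
    if ("genotype" %in% names(df))
        cat(sprintf("  genotyped: %d\n",
                    sum(!is.na(df$genotype) & nzchar(df$genotype))))
    cat(" ", object@provenance, "\n")
})

#' Render per-genotype summary blocks as an aligned text report
#'
#' One block per genotype group in table layout: the member accessions
#' with their traits, then Avg / SD / COV rows rounded to two decimals.
#'
#' @param panelSummary result of \code{\link{summarizePanel}}.
#' @param panel the source \code{\linkS4class{Panel}} (for member rows).
#' @return character vector of report lines, invisibly printable via
#'   \code{writeLines}.
#' @export
renderGroupReport <- function(panelSummary, panel) {
    df <- deriveMetrics(panelData(panel))
    df$genotype <- canonicalGenotype(df$genotype)
    traits <- traitNames()
    hdr <- sprintf("%-24s %10s %10s %10s %10s %10s %8s", "name",
                   "plant", "stem", "stalk", "spike", "hufl", "ratio")
    lines <- character()
    for (g in unique(panelSummary$summaries$group)) {
        s <- panelSummary$summaries
        s <- s[s$group == g, , drop = FALSE]
        lines <- c(lines,
                   sprintf("== %s (%s, n=%d) ==", g, s$dwarf_class[1],
                           s$n[1]), hdr)
        mem <- df[df$genotype == g, , drop = FALSE]
        fmtRow <- function(nm, v)
            sprintf("%-24s %10.2f %10.2f %10.2f %10.2f %10.2f %8.2f", nm,
                    v[1], v[2], v[3], v[4], v[5], v[6])
        for (i in seq_len(nrow(mem)))
            lines <- c(lines, fmtRow(mem$name[i],
                                     unlist(mem[i, traits])))
        stat <- function(col) s[[col]][match(traits, s$trait)]
        lines <- c(lines, fmtRow("Avg", stat("mean")),
                   fmtRow("SD", stat("sd")), fmtRow("COV", stat("cov")), "")
    }
    lines
}

.needStage <- function(have, stage, what) {
    if (!have)
        stop(sprintf("stage '%s' requires %s", stage, what), call. = FALSE)
}

#' Run the genotyping/analysis pipeline
#'
#' Chains the package's stages over file inputs, writing CSV (and text
#' report) outputs to \code{outDir}. Stages:
#' \describe{
#'   \item{genotype}{call alleles from FASTA evidence
#'     (\code{"accession|locus"} records) and assemble genotypes.}
#'   \item{classify}{dwarf-class table from genotypes (panel column or
#'     the genotype stage).}
#'   \item{summarize}{per-genotype trait summary of the panel, plus an
#'     aligned-text report and an exclusion report.}
#'   \item{cross}{predict F1s for a cross plan CSV (columns
#'     \code{female}, \code{male}) using panel genotypes; A-line females
#'     fall back to their B-line maintainer's genotype.}
#'   \item{diallel}{complete diallel among \code{config$parents}.}
#'   \item{simulate}{write a synthetic panel + FASTA evidence from
#'     \code{config$sim} (see \code{\link{simulationConfig}}).}
#' }
#' Stage dependencies are validated before any work; outputs are
#' deterministic given identical inputs and seed. Every accession read
#' is accounted for either in an output or in the exclusion report.
#'
#' @param config list with any of: \code{panel} (CSV path),
#'   \code{evidence} (FASTA path), \code{markers} (YAML path),
#'   \code{crossPlan} (CSV path), \code{parents} (character vector of
#'   parent ids), \code{stages} (character), \code{outDir},
#'   \code{seed}, \code{sim}.
#' @return (invisibly) a named list of in-memory stage results.
#' @export
runPipeline <- function(config) {
    stages <- config$stages
    if (is.null(stages) || length(stages) == 0L)
        stop("config$stages must name at least one stage", call. = FALSE)
    known <- c("genotype", "classify", "summarize", "cross", "diallel",
               "simulate")
    bad <- setdiff(stages, known)
    if (length(bad))
        stop("unknown stage(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    outDir <- config$outDir %||% "."
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed %||% 1L

    # validate dependencies up front, before any work
    panelNeeded <- intersect(stages, c("summarize", "cross"))
    if (length(panelNeeded)) .needStage(!is.null(config$panel),
                                        panelNeeded[1], "config$panel")
    if ("genotype" %in% stages)
        .needStage(!is.null(config$evidence), "genotype", "config$evidence")
    if ("classify" %in% stages)
        .needStage("genotype" %in% stages || !is.null(config$panel),
                   "classify", "genotypes (config$panel or genotype stage)")
    if ("cross" %in% stages)
        .needStage(!is.null(config$crossPlan), "cross", "config$crossPlan")
    if ("diallel" %in% stages)
        .needStage(!is.null(config$parents), "diallel", "config$parents")
    if ("simulate" %in% stages)
        .needStage(!is.null(config$sim), "simulate", "config$sim")

    res <- list()
    panel <- if (!is.null(config$panel)) loadPanel(config$panel) else NULL
    if (!is.null(panel))
        message(sprintf("loaded panel: %d accessions",
                        nrow(panelData(panel))))

    if ("genotype" %in% stages) {
        defs <- loadMarkerDefinitions(config$markers)
        called <- callEvidence(config$evidence, defs)
        utils::write.csv(called$calls,
                         file.path(outDir, "marker_calls.csv"),
                         row.names = FALSE)
        geno <- data.frame(name = names(called$genotypes),
                           genotype = unname(called$genotypes),
                           stringsAsFactors = FALSE)
        utils::write.csv(geno, file.path(outDir, "genotypes.csv"),
                         row.names = FALSE)
        message(sprintf("genotype: %d calls, %d accessions assembled",
                        nrow(called$calls), nrow(geno)))
        res$genotype <- called
    }

    if ("classify" %in% stages) {
        geno <- if (!is.null(res$genotype))
            res$genotype$genotypes
        else {
            df <- panelData(panel)
            stats::setNames(df$genotype, df$name)
        }
        keep <- !is.na(geno) & nzchar(geno)
        cls <- data.frame(name = names(geno)[keep],
                          genotype = canonicalGenotype(geno[keep]),
                          dwarf_class =
                              as.character(classifyDwarfType(geno[keep])),
                          stringsAsFactors = FALSE)
        utils::write.csv(cls, file.path(outDir, "dwarf_classes.csv"),
                         row.names = FALSE)
        message(sprintf("classify: %d genotypes, %d without genotype",
                        nrow(cls), sum(!keep)))
        res$classify <- cls
    }

    if ("summarize" %in% stages) {
        ps <- summarizePanel(panel)
        utils::write.csv(ps$summaries,
                         file.path(outDir, "group_summaries.csv"),
                         row.names = FALSE)
        utils::write.csv(ps$excluded,
                         file.path(outDir, "excluded_accessions.csv"),
                         row.names = FALSE)
        writeLines(renderGroupReport(ps, panel),
                   file.path(outDir, "group_report.txt"))
        message(sprintf("summarize: %d groups, %d accessions excluded",
                        length(unique(ps$summaries$group)),
                        nrow(ps$excluded)))
        res$summarize <- ps
    }

    if ("cross" %in% stages || "diallel" %in% stages) {
        df <- panelData(panel %||% loadPanel(config$panel))
        lookup <- stats::setNames(df$genotype, df$name)
        hasGeno <- function(id) !is.na(lookup[id]) && nzchar(lookup[id])
        resolveGeno <- function(id) {
            if (hasGeno(id)) return(lookup[[id]])
            # A-line females are genotyped via their B-line maintainer
            bLine <- sub("A$", "B", id)
            if (bLine != id && hasGeno(bLine)) return(lookup[[bLine]])
            stop(sprintf("no genotype for parent '%s'", id), call. = FALSE)
        }
        if ("cross" %in% stages) {
            plan <- utils::read.csv(config$crossPlan, check.names = FALSE,
                                    stringsAsFactors = FALSE)
            crosses <- lapply(seq_len(nrow(plan)), function(i) {
                f <- plan$female[i]; m <- plan$male[i]
                if (!grepl("A$", f))
                    warning(sprintf(
                        "female '%s' does not look like an A line", f),
                        call. = FALSE)
                predictF1(resolveGeno(f), resolveGeno(m), f, m)
            })
            flat <- do.call(rbind, lapply(crosses, function(cr)
                cbind(female = cr@female, male = cr@male, cr@offspring)))
            utils::write.csv(flat, file.path(outDir, "f1_predictions.csv"),
                             row.names = FALSE)
            message(sprintf("cross: %d crosses predicted", length(crosses)))
            res$cross <- crosses
        }
        if ("diallel" %in% stages) {
            parents <- vapply(config$parents, resolveGeno, character(1))
            names(parents) <- config$parents
            dia <- buildDiallel(parents)
            utils::write.csv(diallelFrame(dia),
                             file.path(outDir, "diallel.csv"),
                             row.names = FALSE)
            message(sprintf("diallel: %d cells", length(dia@cells)))
            res$diallel <- dia
        }
    }

    if ("simulate" %in% stages) {
        sim <- simulatePanel(config$sim)
        writeSimulated(sim, outDir)
        message(sprintf("simulate: %d lines, %d evidence records",
                        nrow(panelData(sim$panel)), length(sim$evidence)))
        res$simulate <- sim
    }

    invisible(res)
}
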