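fixturePath <- function(name)
    system.file("extdata", name, package = "DwTyper", mustWork = TRUE)

referencePanel <- function() loadPanel(fixturePath("panel_accessions.csv"))

markerDefs <- loadMarkerDefinitions()

## random valid genotype: each of the 8 copies dominant with prob 1/2
randomGenotype <- function() {
    DwGenotype(dw1 = sample(c(TRUE, FALSE), 2, replace = TRUE),
               dw2 = sample(c(TRUE, FALSE), 2, replace = TRUE),
               dw3 = sample(c(TRUE, FALSE), 2, replace = TRUE),
               dw4 = sample(c(TRUE, FALSE), 2, replace = TRUE))
}

## Independent Mendelian oracle: enumerate all 2^4 x 2^4 gamete
## combinations (each parent contributes copy 1 or copy 2 at every
## locus), each with probability 1/256, and aggregate genotype strings.
bruteForceF1 <- function(female, male) {
    fa <- female@alleles; ma <- male@alleles
    picks <- expand.grid(rep(list(1:2), 4))
    out <- list()
    for (i in seq_len(nrow(picks))) for (j in seq_len(nrow(picks))) {
        fg <- fa[cbind(1:4, as.integer(picks[i, ]))]
        mg <- ma[cbind(1:4, as.integer(picks[j, ]))]
        g <- DwGenotype(dw1 = c(fg[1], mg[1]), dw2 = c(fg[2], mg[2]),
                        dw3 = c(fg[3], mg[3]), dw4 = c(fg[4], mg[4]))
        key <- formatGenotype(g)
        out[[key]] <- (out[[key]] %||% 0) + 1 / 256
    }
    probs <- unlist(out)
    probs[order(names(probs))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
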