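# Small in-code fixture builders shared across test files.

# A MotifSummary with prescribed inclusive canonical count (other classes 0).
makeSummary <- function(canonical, total) {
    counts <- stats::setNames(c(as.integer(canonical), 0L, 0L),
                              cmaflux::MOTIF_CLASSES)
    methods::new("MotifSummary", nProteins = as.integer(total),
                 mode = "inclusive", counts = counts,
                 fractions = counts / total)
}

# A paired-design quantification SummarizedExperiment from a matrix whose
# columns alternate control/NL per donor.
makeQuantSE <- function(mat, condition, donor = NULL, scale = "log2") {
    cd <- S4Vectors::DataFrame(condition = condition,
                               row.names = colnames(mat))
    if (!is.null(donor)) cd$donor <- donor
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(x = mat), colData = cd)
    S4Vectors::metadata(se)$scale <- scale
    se
}

# A minimal DifferentialResult-shaped table for testing the substrate filter
# in isolation.
makeDiff <- function(proteinId, log2FC, pValue, flag = "ok") {
    S4Vectors::DataFrame(proteinId = proteinId, log2FC = log2FC,
                         pValue = pValue,
                         flag = rep(flag, length.out = length(proteinId)))
}
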