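## S4 class definitions and accessors for the package's core objects.

#' Motif classes recognised by the scanner
#'
#' Character vector of the three KFERQ-like motif classes, in priority order
#' (used by exclusive per-protein assignment).
#'
#' @export
MOTIF_CLASSES <- c("canonical", "phospho_generated", "acetyl_generated")

.STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' KFERQ-like motif rule set
#'
#' Encodes the residue classes and composition constraints that define a
#' KFERQ-like pentapeptide targeting motif: a terminal glutamine anchor plus
#' four residues drawn from a hydrophobic class, a positively charged class
#' and exactly one negatively charged residue. Post-translational
#' modifications extend the canonical rule: a phosphorylatable serine,
#' threonine or tyrosine can stand in for the negative residue
#' (phosphorylation-generated motifs), and an acetylatable terminal lysine
#' can stand in for the glutamine anchor (acetylation-generated motifs).
#'
#' @slot hydrophobic single-letter hydrophobic residue class.
#' @slot positive single-letter positively charged residue class.
#' @slot negative single-letter negatively charged residue class.
#' @slot anchor the anchor residue (glutamine).
#' @slot phosphoMimics residues that mimic a negative charge when
#'   phosphorylated.
#' @slot acetylAnchorMimic residue that mimics the anchor when acetylated
#'   (lysine).
#' @slot hydrophobicRange length-2 integer, allowed hydrophobic count among
#'   the four non-anchor residues.
#' @slot positiveRange length-2 integer, allowed positive count.
#' @slot negativeCount required count of negative residues.
#'
#' @seealso [MotifRuleSet()] for the user constructor, [classifyWindow()],
#'   [scanProteins()].
#' @name MotifRuleSet-class
#' @exportClass MotifRuleSet
setClass("MotifRuleSet", representation(
    hydrophobic      = "character",
    positive         = "character",
    negative         = "character",
    anchor           = "character",
    phosphoMimics    = "character",
    acetylAnchorMimic = "character",
    hydrophobicRange = "integer",
    positiveRange    = "integer",
    negativeCount    = "integer"))

setValidity("MotifRuleSet", function(object) {
    msg <- character()
    classes <- list(hydrophobic = object@hydrophobic,
                    positive = object@positive,
                    negative = object@negative)
    all1 <- unlist(classes, use.names = FALSE)
    if (any(nchar(c(all1, object@anchor, object@phosphoMimics,
                    object@acetylAnchorMimic)) != 1L))
        msg <- c(msg, "all residues must be single letters")
    if (anyDuplicated(all1))
        msg <- c(msg, "hydrophobic, positive and negative classes must be pairwise disjoint")
    if (length(object@anchor) != 1L || object@anchor %in% all1)
        msg <- c(msg, "anchor must be a single residue outside the three classes")
    if (any(object@phosphoMimics %in% c(all1, object@anchor)))
        msg <- c(msg, "phospho-mimic residues must lie outside the classes and anchor")
    if (length(object@acetylAnchorMimic) != 1L)
        msg <- c(msg, "acetyl anchor mimic must be a single residue")
    if (length(object@hydrophobicRange) != 2L || length(object@positiveRange) != 2L ||
        length(object@negativeCount) != 1L)
        msg <- c(msg, "composition constraints malformed")
    if (length(msg)) msg else TRUE
})

#' Construct a KFERQ-like motif rule set
#'
#' Returns the default rule dialect: anchor Q at either terminus, and among
#' the remaining four residues 1--2 hydrophobic (F/I/L/V), 1--2 positive
#' (K/R) and exactly 1 negative (E/D), with all four residues accounted for
#' by the three classes. Phosphorylation-generated motifs recount one S/T/Y
#' as the negative residue; acetylation-generated motifs recount a terminal K
#' as the anchor. Every component is overridable, so divergent rule dialects
#' can be loaded without touching the scanner.
#'
#' @param hydrophobic,positive,negative residue classes.
#' @param anchor anchor residue.
#' @param phosphoMimics phosphorylatable acid-mimic residues.
#' @param acetylAnchorMimic acetylatable anchor-mimic residue.
#' @param hydrophobicRange,positiveRange allowed count ranges (length 2).
#' @param negativeCount required negative-residue count.
#' @return A [MotifRuleSet-class] object.
#' @examples
#' rules <- MotifRuleSet()
#' classifyWindow("KFERQ", rules)
#' @export
MotifRuleSet <- function(hydrophobic = c("F", "I", "L", "V"),
                         positive = c("K", "R"),
                         negative = c("E", "D"),
                         anchor = "Q",
                         phosphoMimics = c("S", "T", "Y"),
                         acetylAnchorMimic = "K",
                         hydrophobicRange = c(1L, 2L),
                         positiveRange = c(1L, 2L),
                         negativeCount = 1L) {
    new("MotifRuleSet",
        hydrophobic = toupper(hydrophobic),
        positive = toupper(positive),
        negative = toupper(negative),
        anchor = toupper(anchor),
        phosphoMimics = toupper(phosphoMimics),
        acetylAnchorMimic = toupper(acetylAnchorMimic),
        hydrophobicRange = as.integer(hydrophobicRange),
        positiveRange = as.integer(positiveRange),
        negativeCount = as.integer(negativeCount))
}

setMethod("show", "MotifRuleSet", function(object) {
    cat("MotifRuleSet\n")
    cat("  hydrophobic {", paste(object@hydrophobic, collapse = ","),
        "} x", paste(object@hydrophobicRange, collapse = "-"), "\n")
    cat("  positive    {", paste(object@positive, collapse = ","),
        "} x", paste(object@positiveRange, collapse = "-"), "\n")
    cat("  negative    {", paste(object@negative, collapse = ","),
        "} x", object@negativeCount, "\n")
    cat("  anchor", object@anchor,
        "| phospho mimics {", paste(object@phosphoMimics, collapse = ","),
        "} | acetyl anchor mimic", object@acetylAnchorMimic, "\n")
})

#' Per-class motif abundance summary
#'
#' Counts and fractions of proteins in a collection containing at least one
#' motif of each class. In inclusive mode a protein counts towards every
#' class it contains; in exclusive mode each protein is assigned to a single
#' class by the priority canonical > phosphorylation-generated >
#' acetylation-generated.
#'
#' @slot nProteins total number of proteins summarised.
#' @slot mode "inclusive" or "exclusive".
#' @slot counts named integer, proteins per motif class.
#' @slot fractions named numeric, counts / nProteins.
#' @name MotifSummary-class
#' @exportClass MotifSummary
setClass("MotifSummary", representation(
    nProteins = "integer",
    mode      = "character",
    counts    = "integer",
    fractions = "numeric"))

setValidity("MotifSummary", function(object) {
    msg <- character()
    if (!identical(names(object@counts), MOTIF_CLASSES) ||
        !identical(names(object@fractions), MOTIF_CLASSES))
        msg <- c(msg, "counts/fractions must be named by the three motif classes")
    if (any(!is.finite(object@fractions)) ||
        any(object@fractions < 0 | object@fractions > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (identical(object@mode, "exclusive") &&
        sum(object@counts) > object@nProteins)
        msg <- c(msg, "exclusive counts cannot exceed the protein total")
    if (length(msg)) msg else TRUE
})

setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))
setGeneric("motifFractions", function(x) standardGeneric("motifFractions"))

#' @describeIn MotifSummary-class per-class protein counts.
#' @param x a \code{MotifSummary}.
#' @export
setMethod("motifCounts", "MotifSummary", function(x) x@counts)

#' @describeIn MotifSummary-class per-class protein fractions.
#' @export
setMethod("motifFractions", "MotifSummary", function(x) x@fractions)

setMethod("show", "MotifSummary", function(object) {
    cat("MotifSummary over", object@nProteins, "proteins (",
        object@mode, "counting )\n")
    df <- data.frame(class = MOTIF_CLASSES,
                     proteins = object@counts,
                     fraction = round(object@fractions, 4),
                     row.names = NULL)
    print(df)
})

#' CMA transcriptional network table
#'
#' Gene-level description of the chaperone-mediated autophagy network used by
#' the transcriptional score: each gene carries a role (effector, positive or
#' negative modulator), a signed direction (+1 for effectors and positive
#' modulators, -1 for negative modulators) and a weight magnitude. LAMP2, the
#' limiting effector encoding the lysosomal receptor LAMP-2A, carries weight
#' 2; every other gene defaults to weight 1.
#'
#' @slot table data.frame with columns gene, role, direction, weight.
#' @seealso [CmaNetwork()], [defaultCmaNetwork()], [computeCmaScore()].
#' @name CmaNetwork-class
#' @exportClass CmaNetwork
setClass("CmaNetwork", representation(table = "data.frame"))

.CMA_ROLES <- c("effector", "positive_modulator", "negative_modulator")

setValidity("CmaNetwork", function(object) {
    tb <- object@table
    msg <- character()
    need <- c("gene", "role", "direction", "weight")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(tb$gene))
        msg <- c(msg, "duplicate gene symbols")
    if (!all(tb$role %in% .CMA_ROLES))
        msg <- c(msg, paste("roles must be one of",
                            paste(.CMA_ROLES, collapse = ", ")))
    if (!all(tb$direction %in% c(-1, 1)))
        msg <- c(msg, "direction must be +1 or -1")
    if (any(tb$weight <= 0))
        msg <- c(msg, "weights must be positive")
    bad <- (tb$role == "negative_modulator" & tb$direction != -1) |
           (tb$role != "negative_modulator" & tb$direction != 1)
    if (any(bad))
        msg <- c(msg, "direction must be -1 for negative modulators and +1 otherwise")
    if ("LAMP2" %in% tb$gene) {
        i <- match("LAMP2", tb$gene)
        if (tb$weight[i] != 2 || tb$direction[i] != 1)
            msg <- c(msg, "LAMP2 must carry weight 2 and direction +1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CMA network table
#'
#' @param gene character vector of gene symbols.
#' @param role role per gene: "effector", "positive_modulator" or
#'   "negative_modulator".
#' @param direction optional signed direction per gene; derived from role
#'   when omitted (-1 for negative modulators, +1 otherwise).
#' @param weight optional positive weight per gene; defaults to 1 except
#'   LAMP2, which defaults to 2.
#' @return A [CmaNetwork-class] object.
#' @examples
#' net <- CmaNetwork(gene = c("LAMP2", "HSPA8", "RARA"),
#'                   role = c("effector", "effector", "negative_modulator"))
#' networkTable(net)
#' @export
CmaNetwork <- function(gene, role, direction = NULL, weight = NULL) {
    gene <- as.character(gene)
    role <- as.character(role)
    if (length(role) != length(gene))
        stop("'gene' and 'role' must have equal length")
    if (is.null(direction))
        direction <- ifelse(role == "negative_modulator", -1, 1)
    if (is.null(weight))
        weight <- ifelse(gene == "LAMP2", 2, 1)
    new("CmaNetwork", table = data.frame(
        gene = gene, role = role,
        direction = as.numeric(direction), weight = as.numeric(weight),
        stringsAsFactors = FALSE))
}

setGeneric("networkTable", function(x) standardGeneric("networkTable"))

#' @describeIn CmaNetwork-class the underlying data.frame.
#' @param x a \code{CmaNetwork}.
#' @export
setMethod("networkTable", "CmaNetwork", function(x) x@table)

setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @describeIn CmaNetwork-class the gene symbols in the network.
#' @export
setMethod("networkGenes", "CmaNetwork", function(x) x@table$gene)

setMethod("show", "CmaNetwork", function(object) {
    tb <- object@table
    cat("CmaNetwork with", nrow(tb), "genes:",
        sum(tb$role == "effector"), "effectors,",
        sum(tb$role == "positive_modulator"), "positive and",
        sum(tb$role == "negative_modulator"), "negative modulators\n")
    print(utils::head(tb, 8), row.names = FALSE)
    if (nrow(tb) > 8) cat("  ...", nrow(tb) - 8, "more\n")
})

#' Per-sample CMA transcriptional score result
#'
#' @slot scores named numeric, one score per sample (or cell).
#' @slot genesUsed network genes that entered the average.
#' @slot genesDropped data.frame(gene, reason) of network genes excluded
#'   (absent from the matrix or with zero variance across samples).
#' @seealso [computeCmaScore()], [scoreGroups()].
#' @name CmaScoreResult-class
#' @exportClass CmaScoreResult
setClass("CmaScoreResult", representation(
    scores       = "numeric",
    genesUsed    = "character",
    genesDropped = "data.frame"))

setValidity("CmaScoreResult", function(object) {
    if (any(!is.finite(object@scores)))
        return("scores must be finite")
    TRUE
})

setGeneric("cmaScores", function(x) standardGeneric("cmaScores"))

#' @describeIn CmaScoreResult-class named per-sample scores.
#' @param x a \code{CmaScoreResult}.
#' @export
setMethod("cmaScores", "CmaScoreResult", function(x) x@scores)

setGeneric("genesUsed", function(x) standardGeneric("genesUsed"))

#' @describeIn CmaScoreResult-class genes entering the average.
#' @export
setMethod("genesUsed", "CmaScoreResult", function(x) x@genesUsed)

setGeneric("genesDropped", function(x) standardGeneric("genesDropped"))

#' @describeIn CmaScoreResult-class dropped genes with reasons.
#' @export
setMethod("genesDropped", "CmaScoreResult", function(x) x@genesDropped)

setMethod("show", "CmaScoreResult", function(object) {
    cat("CmaScoreResult:", length(object@scores), "samples,",
        length(object@genesUsed), "network genes used,",
        nrow(object@genesDropped), "dropped\n")
    print(round(utils::head(object@scores, 6), 4))
})

#' Putative CMA substrate call set
#'
#' Proteins passing the substrate filter applied to a lysosomal-inhibition
#' differential result: linear fold change above \code{fcMin} in the
#' accumulation direction, raw p-value below \code{pMax}, and (when
#' \code{requireMotif}) at least one KFERQ-like motif.
#'
#' @slot label condition label (e.g. "healthy", "AMD").
#' @slot proteins called protein accessions.
#' @slot fcMin,pMax thresholds used.
#' @slot requireMotif whether the motif gate was applied.
#' @slot direction "up" (accumulation only) or "both".
#' @slot nTested number of proteins that entered the filter.
#' @seealso [callSubstrates()], [overlapSets()].
#' @name SubstrateCallSet-class
#' @exportClass SubstrateCallSet
setClass("SubstrateCallSet", representation(
    label        = "character",
    proteins     = "character",
    fcMin        = "numeric",
    pMax         = "numeric",
    requireMotif = "logical",
    direction    = "character",
    nTested      = "integer"))

setValidity("SubstrateCallSet", function(object) {
    if (anyDuplicated(object@proteins))
        return("called proteins must be unique")
    TRUE
})

setGeneric("substrateIds", function(x) standardGeneric("substrateIds"))

#' @describeIn SubstrateCallSet-class called protein accessions.
#' @param x a \code{SubstrateCallSet}.
#' @export
setMethod("substrateIds", "SubstrateCallSet", function(x) x@proteins)

setMethod("show", "SubstrateCallSet", function(object) {
    cat("SubstrateCallSet", if (nzchar(object@label)) sQuote(object@label) else "",
        ":", length(object@proteins), "of", object@nTested,
        "tested proteins called\n")
    cat("  filter: FC >", object@fcMin, "(", object@direction,
        "), p <", object@pMax,
        if (object@requireMotif) ", KFERQ-motif required" else "", "\n")
})
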