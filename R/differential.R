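## Lysosomal-inhibition flux proteomics: row-wise differential testing,
## motif-gated substrate calling and set overlap.

.asQuantInput <- function(x, colData = NULL, scale = NULL) {
    if (methods::is(x, "SummarizedExperiment")) {
        mat <- as.matrix(SummarizedExperiment::assay(x))
        cd <- as.data.frame(SummarizedExperiment::colData(x))
        if (is.null(scale))
            scale <- S4Vectors::metadata(x)$scale
    } else {
        mat <- as.matrix(x)
        cd <- as.data.frame(colData)
    }
    .stopIfNot(!is.null(cd) && "condition" %in% names(cd),
               "sample annotation must carry a 'condition' column")
    .stopIfNot(nrow(cd) == ncol(mat),
               "sample annotation rows must match matrix columns")
    cond <- as.character(cd$condition)
    if (!all(cond %in% c("control", "NL")))
        stop("condition must be 'control' or 'NL', got: ",
             paste(setdiff(unique(cond), c("control", "NL")), collapse = ", "))
    if (is.null(rownames(mat)))
        stop("quantification matrix must carry protein accessions as rownames")
    list(mat = mat, condition = cond,
         donor = if ("donor" %in% names(cd)) as.character(cd$donor) else NULL,
         scale = if (is.null(scale)) "log2" else scale)
}

#' Row-wise differential test of an N/L flux-proteomics experiment
#'
#' Tests every protein for accumulation under lysosomal-proteolysis
#' inhibition (NH4Cl + leupeptin, "NL") relative to control. With a paired
#' design, per-donor log2 differences (NL - control) are tested with a
#' one-sample t-test; unpaired designs use Welch's two-sample t-test. Raw
#' intensities are log2-transformed and (optionally) median-centred per
#' sample first; no imputation is performed. Proteins quantified in fewer
#' than two values per group (or fewer than two complete donor pairs) are
#' flagged and not tested; proteins entirely absent in one condition are
#' flagged \code{one_condition_only}.
#'
#' @param x protein x sample matrix (rownames = accessions) or a
#'   [SummarizedExperiment::SummarizedExperiment] whose \code{colData}
#'   carries \code{condition} ("control"/"NL") and optionally \code{donor}.
#' @param colData sample annotation data.frame for matrix input.
#' @param design "auto" (paired when donor ids are present), "paired" or
#'   "unpaired".
#' @param scale "log2" (default for matrix input) or "raw"; raw intensities
#'   must be positive and are log2-transformed.
#' @param normalize median-centre log2 intensities per sample before testing
#'   (applied to raw-scale input only; emulates standard label-free
#'   pipelines).
#' @return An [S4Vectors::DataFrame] with one row per protein:
#'   \code{proteinId}, \code{log2FC} (NL - control), \code{t}, \code{df},
#'   \code{pValue}, \code{qValue} (BH across tested proteins),
#'   \code{nControl}, \code{nNL}, \code{nPairs}, and \code{flag}
#'   ("ok", "insufficient_n", "one_condition_only", "degenerate_variance").
#' @seealso [callSubstrates()]
#' @export
rowwiseTest <- function(x, colData = NULL,
                        design = c("auto", "paired", "unpaired"),
                        scale = NULL, normalize = TRUE) {
    design <- match.arg(design)
    q <- .asQuantInput(x, colData, scale)
    mat <- q$mat
    scale <- match.arg(q$scale, c("log2", "raw"))
    if (scale == "raw") {
        if (any(mat <= 0, na.rm = TRUE))
            stop("raw intensities must be positive")
        mat <- log2(mat)
        if (normalize) {
            meds <- apply(mat, 2, stats::median, na.rm = TRUE)
            mat <- sweep(mat, 2, meds - mean(meds))
        }
    }
    if (design == "auto")
        design <- if (!is.null(q$donor) && length(unique(q$donor)) >= 2L)
            "paired" else "unpaired"
    np <- nrow(mat)
    if (design == "paired") {
        .stopIfNot(!is.null(q$donor), "paired design requires donor ids")
        donors <- unique(q$donor)
        D <- vapply(donors, function(d) {
            nl <- mat[, q$condition == "NL" & q$donor == d, drop = FALSE]
            ct <- mat[, q$condition == "control" & q$donor == d, drop = FALSE]
            rowMeans(nl, na.rm = TRUE) - rowMeans(ct, na.rm = TRUE)
        }, numeric(np))
        if (np == 1L) D <- matrix(D, nrow = 1L)
        D[!is.finite(D)] <- NA
        nPairs <- rowSums(!is.na(D))
        md <- rowMeans(D, na.rm = TRUE)
        sdD <- sqrt(rowSums((D - md)^2, na.rm = TRUE) / pmax(nPairs - 1L, 1L))
        se <- sdD / sqrt(nPairs)
        df <- nPairs - 1L
        tt <- .safeT(md, se, df)
        n1 <- rowSums(!is.na(mat[, q$condition == "control", drop = FALSE]))
        n2 <- rowSums(!is.na(mat[, q$condition == "NL", drop = FALSE]))
        tested <- nPairs >= 2L
        degen <- tested & sdD == 0
        log2FC <- md
        t <- tt$t; p <- tt$p
    } else {
        g1 <- mat[, q$condition == "control", drop = FALSE]
        g2 <- mat[, q$condition == "NL", drop = FALSE]
        n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
        m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
        v1 <- rowSums((g1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1L, 1L)
        v2 <- rowSums((g2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1L, 1L)
        se2 <- v1 / n1 + v2 / n2
        df <- se2^2 / ((v1 / n1)^2 / pmax(n1 - 1L, 1L) +
                       (v2 / n2)^2 / pmax(n2 - 1L, 1L))
        tt <- .safeT(m2 - m1, sqrt(se2), df)
        tested <- n1 >= 2L & n2 >= 2L
        degen <- tested & (v1 + v2) == 0
        df[degen] <- n1[degen] + n2[degen] - 2L   # limiting contract rows
        log2FC <- m2 - m1
        nPairs <- rep(NA_integer_, np)
        t <- tt$t; p <- tt$p
    }
    oneCond <- (n1 == 0L & n2 > 0L) | (n2 == 0L & n1 > 0L)
    flag <- rep("ok", np)
    flag[!tested] <- "insufficient_n"
    flag[oneCond] <- "one_condition_only"
    flag[degen] <- "degenerate_variance"
    log2FC[n1 == 0L | n2 == 0L] <- NA_real_
    t[!tested] <- NA_real_
    p[!tested] <- NA_real_
    q_ <- rep(NA_real_, np)
    q_[tested] <- stats::p.adjust(p[tested], method = "BH")
    S4Vectors::DataFrame(
        proteinId = rownames(mat),
        log2FC = unname(log2FC), t = unname(t),
        df = unname(df), pValue = unname(p), qValue = q_,
        nControl = unname(n1), nNL = unname(n2), nPairs = unname(nPairs),
        flag = flag)
}

#' Call putative CMA substrates from a differential result
#'
#' Applies the substrate filter: linear fold change above \code{fcMin} in
#' the accumulation direction (log2FC > log2(fcMin)), raw p-value below
#' \code{pMax}, and — when \code{requireMotif} — at least one KFERQ-like
#' motif in the companion annotation. Only proteins with flag "ok" (tested,
#' non-degenerate) enter the filter. Accumulation-only direction reflects
#' the experimental logic: blocking lysosomal proteolysis reveals
#' degradation substrates as enriched proteins; a two-sided variant is
#' available via \code{direction = "both"}.
#'
#' @param diff output of [rowwiseTest()].
#' @param motifs motif annotation: a named logical vector over accessions,
#'   or a character vector of motif-positive accessions. Accessions not
#'   covered by the annotation are treated as motif-negative with a logged
#'   notice.
#' @param fcMin minimum linear fold change (> 0); default 1.25.
#' @param pMax maximum raw p-value (in (0, 1]); default 0.01.
#' @param requireMotif apply the motif gate (default TRUE).
#' @param direction "up" (default) or "both".
#' @param label condition label stored in the result.
#' @return A [SubstrateCallSet-class].
#' @export
callSubstrates <- function(diff, motifs = character(), fcMin = 1.25,
                           pMax = 0.01, requireMotif = TRUE,
                           direction = c("up", "both"), label = "") {
    direction <- match.arg(direction)
    if (!is.numeric(fcMin) || length(fcMin) != 1L || fcMin <= 0)
        stop("'fcMin' must be a single positive number")
    if (!is.numeric(pMax) || length(pMax) != 1L || pMax <= 0 || pMax > 1)
        stop("'pMax' must lie in (0, 1]")
    df <- as.data.frame(diff)
    if (is.logical(motifs)) {
        .stopIfNot(!is.null(names(motifs)), "logical 'motifs' must be named")
        motifPos <- names(motifs)[motifs]
        covered <- names(motifs)
    } else {
        motifPos <- as.character(motifs)
        covered <- motifPos
    }
    uncovered <- setdiff(df$proteinId, covered)
    if (requireMotif && is.logical(motifs) && length(uncovered))
        message(length(uncovered),
                " protein(s) missing from the motif annotation treated as motif-negative")
    tested <- df$flag == "ok"
    lfcCut <- log2(fcMin)
    passFC <- if (direction == "up") df$log2FC > lfcCut
              else abs(df$log2FC) > lfcCut
    pass <- tested & !is.na(df$pValue) & passFC & df$pValue < pMax
    if (requireMotif)
        pass <- pass & df$proteinId %in% motifPos
    new("SubstrateCallSet",
        label = label,
        proteins = df$proteinId[pass],
        fcMin = fcMin, pMax = pMax,
        requireMotif = requireMotif, direction = direction,
        nTested = sum(tested))
}

#' Overlap between two substrate (or id) sets
#'
#' Exact set arithmetic plus the Jaccard index |A n B| / |A u B|; the
#' Jaccard of two empty sets is defined as 0 with a notice.
#'
#' @param a,b [SubstrateCallSet-class] objects or character vectors of ids.
#' @return A list: \code{sizeA}, \code{sizeB}, \code{intersectionSize},
#'   \code{unionSize}, \code{jaccard}, \code{shared}, \code{uniqueA},
#'   \code{uniqueB}.
#' @examples
#' overlapSets(c("P1", "P2", "P3"), c("P2", "P3", "P4"))$jaccard
#' @export
overlapSets <- function(a, b) {
    A <- unique(if (methods::is(a, "SubstrateCallSet")) substrateIds(a) else as.character(a))
    B <- unique(if (methods::is(b, "SubstrateCallSet")) substrateIds(b) else as.character(b))
    u <- union(A, B)
    i <- intersect(A, B)
    if (length(u) == 0L)
        message("both sets empty; Jaccard index defined as 0")
    list(sizeA = length(A), sizeB = length(B),
         intersectionSize = length(i), unionSize = length(u),
         jaccard = if (length(u)) length(i) / length(u) else 0,
         shared = i,
         uniqueA = setdiff(A, B), uniqueB = setdiff(B, A))
}
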