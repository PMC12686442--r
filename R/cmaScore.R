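## Transcriptional CMA activity score: weighted, directed average of
## per-gene z-scored (log) expression over the CMA network.

#' Default CMA network table
#'
#' Loads the curated effector/modulator table shipped with the package
#' (\code{inst/extdata/cma_network.tsv}). LAMP2 — encoding the rate-limiting
#' lysosomal receptor LAMP-2A — carries weight 2 and direction +1; other
#' effectors and positive modulators carry +1, negative modulators -1. The
#' membership is an editable default: the score itself is
#' membership-agnostic and accepts any [CmaNetwork-class].
#'
#' @return A [CmaNetwork-class].
#' @export
defaultCmaNetwork <- function() {
    readCmaNetwork(system.file("extdata", "cma_network.tsv",
                               package = "cmaflux", mustWork = TRUE))
}

#' Read a CMA network table from TSV or YAML
#'
#' TSV files need columns \code{gene} and \code{role} (optionally
#' \code{direction} and \code{weight}); YAML files a list of records with
#' the same fields.
#'
#' @param path input file; format chosen by extension (.yaml/.yml vs
#'   tab-separated otherwise).
#' @return A [CmaNetwork-class].
#' @export
readCmaNetwork <- function(path) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        recs <- yaml::read_yaml(path)
        tb <- do.call(rbind, lapply(recs, function(r)
            data.frame(gene = r$gene, role = r$role,
                       direction = if (is.null(r$direction)) NA_real_ else r$direction,
                       weight = if (is.null(r$weight)) NA_real_ else r$weight,
                       stringsAsFactors = FALSE)))
    } else {
        tb <- utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    }
    direction <- if ("direction" %in% names(tb) && !all(is.na(tb$direction)))
        tb$direction else NULL
    weight <- if ("weight" %in% names(tb) && !all(is.na(tb$weight)))
        tb$weight else NULL
    CmaNetwork(tb$gene, tb$role, direction = direction, weight = weight)
}

.asExpressionMatrix <- function(expr) {
    if (methods::is(expr, "SummarizedExperiment")) {
        scale <- S4Vectors::metadata(expr)$scale
        mat <- SummarizedExperiment::assay(expr)
        list(mat = as.matrix(mat), scale = scale)
    } else {
        list(mat = as.matrix(expr), scale = NULL)
    }
}

#' Compute the per-sample CMA transcriptional score
#'
#' For each network gene present in the matrix: raw counts are transformed
#' to log2(x + 1), then z-scored across samples using the population
#' (n-denominator) standard deviation; the per-sample score is the weighted,
#' directed average \eqn{\sum_g d_g w_g z_{gs} / \sum_g w_g} over the genes
#' used. Network genes absent from the matrix or with zero variance across
#' samples are dropped (with a warning for zero variance) and the weight
#' normaliser is recomputed over the remainder.
#'
#' @param expr genes x samples matrix (rownames = gene symbols) or a
#'   [SummarizedExperiment::SummarizedExperiment] (first assay; a
#'   \code{metadata(expr)$scale} entry overrides \code{scale}).
#' @param network a [CmaNetwork-class].
#' @param scale "log_normalized" (values used as-is) or "raw_counts"
#'   (log2(x + 1) applied first).
#' @return A [CmaScoreResult-class].
#' @examples
#' net <- CmaNetwork("G1", "effector")
#' expr <- matrix(c(0, 2), nrow = 1, dimnames = list("G1", c("s1", "s2")))
#' cmaScores(computeCmaScore(expr, net))  # -1, +1
#' @export
computeCmaScore <- function(expr, network = defaultCmaNetwork(),
                            scale = c("log_normalized", "raw_counts")) {
    x <- .asExpressionMatrix(expr)
    mat <- x$mat
    scale <- if (!is.null(x$scale)) match.arg(x$scale, c("log_normalized", "raw_counts"))
             else match.arg(scale)
    if (ncol(mat) < 2L)
        stop("need at least 2 samples to z-score expression")
    if (is.null(rownames(mat)))
        stop("'expr' must carry gene symbols as rownames")
    tb <- networkTable(network)
    if (scale == "raw_counts") {
        if (any(mat < 0, na.rm = TRUE))
            stop("raw counts must be non-negative")
        mat <- log2(mat + 1)
    }
    absent <- setdiff(tb$gene, rownames(mat))
    present <- tb[tb$gene %in% rownames(mat), , drop = FALSE]
    sub <- mat[present$gene, , drop = FALSE]
    mu <- rowMeans(sub)
    sdp <- sqrt(rowMeans((sub - mu)^2))   # population SD
    zeroVar <- sdp == 0
    dropped <- data.frame(gene = c(absent, present$gene[zeroVar]),
                          reason = c(rep("absent", length(absent)),
                                     rep("zero_variance", sum(zeroVar))),
                          stringsAsFactors = FALSE)
    if (any(zeroVar))
        warning(sum(zeroVar), " network gene(s) with zero variance dropped: ",
                paste(present$gene[zeroVar], collapse = ", "))
    keep <- present[!zeroVar, , drop = FALSE]
    if (nrow(keep) == 0L)
        stop("no informative network genes")
    z <- (sub[keep$gene, , drop = FALSE] - mu[keep$gene]) / sdp[keep$gene]
    scores <- as.numeric(crossprod(z, keep$direction * keep$weight)) /
        sum(keep$weight)
    new("CmaScoreResult",
        scores = stats::setNames(scores, colnames(mat)),
        genesUsed = keep$gene,
        genesDropped = dropped)
}

#' Group summaries and two-group comparison of CMA scores
#'
#' Computes per-group mean and s.e.m. of the per-sample scores, and — when
#' exactly two groups with at least two samples each are present — a
#' two-sided unpaired Student's t-test on the group difference.
#'
#' @param x a [CmaScoreResult-class] or named numeric vector of scores.
#' @param groups named character/factor mapping every scored sample to a
#'   group label; samples without a label raise an error.
#' @return A list with \code{groups} (data.frame: group, n, mean, sem) and
#'   \code{comparison} (list: groupA, groupB, difference = meanA - meanB,
#'   t, df, pValue; \code{NULL} unless exactly two groups qualify).
#' @export
scoreGroups <- function(x, groups) {
    scores <- if (methods::is(x, "CmaScoreResult")) cmaScores(x) else x
    .stopIfNot(is.numeric(scores) && !is.null(names(scores)),
               "'x' must be a CmaScoreResult or named numeric vector")
    groups <- stats::setNames(as.character(groups), names(groups))
    missing <- setdiff(names(scores), names(groups))
    if (length(missing))
        stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    g <- groups[names(scores)]
    lv <- unique(g)
    stats <- do.call(rbind, lapply(lv, function(l) {
        v <- scores[g == l]
        data.frame(group = l, n = length(v), mean = mean(v),
                   sem = stats::sd(v) / sqrt(length(v)),
                   stringsAsFactors = FALSE)
    }))
    comparison <- NULL
    if (length(lv) == 2L && all(stats$n >= 2L)) {
        a <- scores[g == lv[1]]; b <- scores[g == lv[2]]
        n1 <- length(a); n2 <- length(b)
        sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
            (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
        tt <- .safeT(mean(a) - mean(b), se, df)
        comparison <- list(groupA = lv[1], groupB = lv[2],
                           difference = mean(a) - mean(b),
                           t = tt$t, df = df, pValue = tt$p)
    }
    list(groups = stats, comparison = comparison)
}
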