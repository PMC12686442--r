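## Rank-based (GSEA-style) enrichment and hypergeometric over-representation.

# Running-sum enrichment score for a sorted score vector and hit indicator.
.esCore <- function(sortedScores, hit, exponent) {
    N <- length(sortedScores)
    Nh <- sum(hit)
    w <- abs(sortedScores)^exponent
    wh <- sum(w[hit])
    inc <- numeric(N)
    inc[hit] <- if (wh > 0) w[hit] / wh else 1 / Nh
    inc[!hit] <- -1 / (N - Nh)
    run <- cumsum(inc)
    maxP <- max(run)
    minP <- min(run)
    # magnitude ties (to within rounding) define ES = 0, keeping the
    # statistic antisymmetric under ranking reversal
    tol <- 1e-12 * max(maxP, -minP, 1)
    if (maxP + minP > tol) {
        es <- maxP; peak <- which.max(run)
    } else if (maxP + minP < -tol) {
        es <- minP; peak <- which.min(run)
    } else {
        es <- 0; peak <- which.max(run)
    }
    list(es = es, runningSum = run, peak = peak)
}

#' Weighted running-sum enrichment score
#'
#' The weighted Kolmogorov-Smirnov-like statistic of gene set enrichment
#' analysis: items are ranked by score (descending; ties broken stably by
#' input position), the running sum increments by |score|^exponent
#' (normalised over in-set members) at set hits and decrements by
#' 1/(N - set size) at misses; the enrichment score (ES) is the signed
#' maximum deviation from zero (when the largest positive and negative
#' deviations tie in magnitude, to within rounding, the ES is defined as 0,
#' which keeps the statistic antisymmetric under ranking reversal). ES
#' always lies in [-1, +1].
#'
#' @param scores named numeric ranking scores (e.g. signed log2 fold
#'   changes); names are the identifiers.
#' @param geneSet character vector of set members.
#' @param exponent weighting exponent (0 = classic Kolmogorov-Smirnov,
#'   1 = weighted; default 1).
#' @return A list: \code{es}, \code{runningSum} (length N, in ranked
#'   order), \code{order} (identifiers in ranked order),
#'   \code{leadingEdge} (set members at or before/after the ES peak,
#'   depending on sign).
#' @examples
#' s <- setNames(10:1, paste0("g", 1:10))
#' enrichmentScore(s, c("g1", "g2", "g3"), exponent = 0)$es  # +1
#' @export
enrichmentScore <- function(scores, geneSet, exponent = 1) {
    .stopIfNot(is.numeric(scores) && !is.null(names(scores)),
               "'scores' must be a named numeric vector")
    .stopIfNot(!anyDuplicated(names(scores)), "identifiers must be unique")
    .stopIfNot(all(is.finite(scores)), "scores must be finite")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    ids <- names(s)
    hit <- ids %in% geneSet
    if (!any(hit))
        stop("empty intersection: no gene-set member in the ranked list")
    core <- .esCore(s, hit, exponent)
    leading <- if (core$es >= 0) ids[hit & seq_along(ids) <= core$peak]
               else ids[hit & seq_along(ids) >= core$peak]
    list(es = core$es, runningSum = core$runningSum, order = ids,
         leadingEdge = leading)
}

#' Gene-set permutation test for the enrichment score
#'
#' Builds a null ES distribution from random same-size member sets drawn
#' from the ranked universe (gene-set permutation), normalises ES by the
#' mean |null ES| of matching sign (NES), and reports an empirical p-value
#' with add-one smoothing, so p >= 1/(nPerm + 1). Reproducible under a
#' fixed seed.
#'
#' @inheritParams enrichmentScore
#' @param nPerm number of permutations (default 1000).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return A list: \code{es}, \code{nes}, \code{pValue}, \code{nPerm},
#'   \code{setSize}, \code{leadingEdge}.
#' @export
permutationTest <- function(scores, geneSet, nPerm = 1000, exponent = 1,
                            seed = NULL) {
    .stopIfNot(is.numeric(nPerm) && nPerm >= 1, "'nPerm' must be >= 1")
    obs <- enrichmentScore(scores, geneSet, exponent)
    N <- length(scores)
    k <- sum(names(scores) %in% geneSet)
    if (k >= N)
        stop("gene set must be smaller than the ranked list")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    nullEs <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
        hit <- logical(N)
        hit[sample.int(N, k)] <- TRUE
        .esCore(s, hit, exponent)$es
    }, numeric(1)))
    obsSign <- if (obs$es >= 0) 1 else -1
    sameSign <- ifelse(nullEs >= 0, 1, -1) == obsSign
    nes <- if (any(sameSign)) obs$es / mean(abs(nullEs[sameSign])) else NA_real_
    p <- (1 + sum(sameSign & abs(nullEs) >= abs(obs$es))) / (nPerm + 1)
    list(es = obs$es, nes = nes, pValue = p, nPerm = as.integer(nPerm),
         setSize = k, leadingEdge = obs$leadingEdge)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set in the collection (intersected with the background
#' first), tests whether the query over-represents the set via the
#' hypergeometric upper tail P(X >= overlap), with Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param query character vector of hit identifiers; must be a subset of
#'   \code{background}.
#' @param background character vector: the tested universe.
#' @param collection named list of character vectors (see [readGmt()]).
#' @param minSetSize sets with fewer in-background members are skipped
#'   (default 1).
#' @return data.frame, one row per tested set: \code{set},
#'   \code{setSize} (in background), \code{overlap}, \code{expected},
#'   \code{pValue}, \code{qValue}, \code{overlapIds}
#'   (comma-separated).
#' @examples
#' bg <- paste0("p", 1:10)
#' ora(bg[1:5], bg, list(myset = bg[1:4]))
#' @export
ora <- function(query, background, collection, minSetSize = 1L) {
    query <- unique(as.character(query))
    background <- unique(as.character(background))
    bad <- setdiff(query, background)
    if (length(bad))
        stop("query identifiers missing from background: ",
             paste(utils::head(bad, 10), collapse = ", "),
             if (length(bad) > 10) " ..." else "")
    .stopIfNot(is.list(collection) && !is.null(names(collection)),
               "'collection' must be a named list of identifier vectors")
    N <- length(background)
    nq <- length(query)
    rows <- lapply(names(collection), function(nm) {
        s <- intersect(unique(collection[[nm]]), background)
        if (length(s) < minSetSize) return(NULL)
        k <- length(intersect(query, s))
        p <- stats::phyper(k - 1, length(s), N - length(s), nq,
                           lower.tail = FALSE)
        data.frame(set = nm, setSize = length(s), overlap = k,
                   expected = length(s) * nq / N, pValue = p,
                   overlapIds = paste(intersect(query, s), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (is.null(res))
        return(data.frame(set = character(), setSize = integer(),
                          overlap = integer(), expected = numeric(),
                          pValue = numeric(), qValue = numeric(),
                          overlapIds = character(), stringsAsFactors = FALSE))
    res$qValue <- stats::p.adjust(res$pValue, method = "BH")
    res[c("set", "setSize", "overlap", "expected", "pValue", "qValue",
          "overlapIds")]
}

#' Jaccard similarity edges between gene sets
#'
#' Returns all pairs of sets whose member-set Jaccard index reaches
#' \code{jaccardMin} — the edge-filtering step of enrichment-map style
#' network summaries (default threshold 0.25).
#'
#' @param sets named list of character vectors (e.g. the member sets behind
#'   enrichment results).
#' @param jaccardMin minimum Jaccard index for an edge.
#' @return data.frame with columns \code{setA}, \code{setB},
#'   \code{jaccard}; zero rows when no pair qualifies.
#' @export
setSimilarityFilter <- function(sets, jaccardMin = 0.25) {
    .stopIfNot(is.list(sets) && !is.null(names(sets)),
               "'sets' must be a named list")
    nms <- names(sets)
    out <- list()
    if (length(sets) >= 2L) {
        cmb <- utils::combn(length(sets), 2)
        for (j in seq_len(ncol(cmb))) {
            a <- cmb[1, j]; b <- cmb[2, j]
            jc <- .jaccard(sets[[a]], sets[[b]])
            if (jc >= jaccardMin)
                out[[length(out) + 1L]] <- data.frame(
                    setA = nms[a], setB = nms[b], jaccard = jc,
                    stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(setA = character(), setB = character(),
                    jaccard = numeric(), stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT: set name, description, then members. Descriptions are
#' kept in the \code{"descriptions"} attribute.
#'
#' @param path GMT file.
#' @return Named list of unique member vectors with a \code{descriptions}
#'   attribute.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
    nms <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(nms))
        stop("duplicate set names in ", path)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- nms
    attr(sets, "descriptions") <- stats::setNames(
        vapply(parts, `[[`, "", 2L), nms)
    sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of member vectors.
#' @param path output file.
#' @param descriptions optional named descriptions; defaults to the
#'   \code{descriptions} attribute of \code{sets}, else "NA".
#' @return The path, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    .stopIfNot(is.list(sets) && !is.null(names(sets)),
               "'sets' must be a named list")
    if (is.null(descriptions))
        descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("NA", length(sets)), names(sets))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
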