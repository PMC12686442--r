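## KFERQ-like motif scanning: window classification, protein scanning,
## collection summaries and enrichment against a reference proteome.

# Split 5-mer windows into an n x 5 residue matrix.
.windowMatrix <- function(windows) {
    n <- length(windows)
    m <- vapply(1:5, function(i) substr(windows, i, i), character(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    m
}

# Vectorised classification of 5-residue windows. Returns one row per
# admitted classification: idx (window index), motifClass, anchorTerminus,
# ptmPos0 (0-based position of the PTM-substituted residue, NA for
# canonical). Windows containing letters outside the standard 20-letter
# alphabet admit nothing; their count is returned in attr "nAmbiguous".
.classifyWindows <- function(windows, rules) {
    empty <- data.frame(idx = integer(), motifClass = character(),
                        anchorTerminus = character(), ptmPos0 = integer(),
                        stringsAsFactors = FALSE)
    n <- length(windows)
    if (n == 0L) {
        attr(empty, "nAmbiguous") <- 0L
        return(empty)
    }
    m <- .windowMatrix(windows)
    H <- matrix(m %in% rules@hydrophobic, n)
    P <- matrix(m %in% rules@positive, n)
    Ng <- matrix(m %in% rules@negative, n)
    S <- matrix(m %in% rules@phosphoMimics, n)
    Q <- m == rules@anchor
    K <- m == rules@acetylAnchorMimic
    valid <- rowSums(matrix(m %in% .STANDARD_AA, n)) == 5L

    hr <- rules@hydrophobicRange
    pr <- rules@positiveRange
    nc <- rules@negativeCount
    out <- vector("list", 6L)
    k <- 0L
    for (side in c("left", "right")) {
        anchorCol <- if (side == "left") 1L else 5L
        restCols <- if (side == "left") 2:5 else 1:4
        nH <- rowSums(H[, restCols, drop = FALSE])
        nP <- rowSums(P[, restCols, drop = FALSE])
        nN <- rowSums(Ng[, restCols, drop = FALSE])
        nS <- rowSums(S[, restCols, drop = FALSE])
        okHP <- nH >= hr[1] & nH <= hr[2] & nP >= pr[1] & nP <= pr[2]

        canon <- valid & Q[, anchorCol] & okHP & nN == nc & (nH + nP + nN) == 4L
        # One phospho-mimic recounted as the (missing) negative residue turns
        # an otherwise non-canonical window canonical; the remaining three
        # residues must already be fully classed.
        phos <- valid & Q[, anchorCol] & !canon & okHP &
            nN == nc - 1L & nS == 1L & (nH + nP + nN + nS) == 4L
        # Terminal lysine recounted as the anchor; the other four residues
        # must satisfy canonical composition as-is.
        acet <- valid & K[, anchorCol] & okHP & nN == nc & (nH + nP + nN) == 4L

        if (any(canon)) {
            k <- k + 1L
            out[[k]] <- data.frame(idx = which(canon),
                                   motifClass = "canonical",
                                   anchorTerminus = side,
                                   ptmPos0 = NA_integer_,
                                   stringsAsFactors = FALSE)
        }
        if (any(phos)) {
            Ssub <- S[, restCols, drop = FALSE]
            pos <- as.integer(Ssub %*% seq_along(restCols))
            k <- k + 1L
            w <- which(phos)
            out[[k]] <- data.frame(idx = w,
                                   motifClass = "phospho_generated",
                                   anchorTerminus = side,
                                   ptmPos0 = restCols[pos[w]] - 1L,
                                   stringsAsFactors = FALSE)
        }
        if (any(acet)) {
            k <- k + 1L
            out[[k]] <- data.frame(idx = which(acet),
                                   motifClass = "acetyl_generated",
                                   anchorTerminus = side,
                                   ptmPos0 = anchorCol - 1L,
                                   stringsAsFactors = FALSE)
        }
    }
    res <- if (k) do.call(rbind, out[seq_len(k)]) else empty
    if (nrow(res)) {
        prio <- match(res$motifClass, MOTIF_CLASSES)
        term <- match(res$anchorTerminus, c("left", "right"))
        res <- res[order(res$idx, prio, term), , drop = FALSE]
        rownames(res) <- NULL
    }
    attr(res, "nAmbiguous") <- sum(!valid)
    res
}

#' Classify a single 5-residue window
#'
#' Tests a pentapeptide against the canonical rule and both
#' post-translational extensions, reporting every classification the window
#' admits. A window already canonical at an anchor is not additionally
#' reported as PTM-generated for that anchor.
#'
#' @param window a 5-letter amino-acid string (case-insensitive).
#' @param rules a [MotifRuleSet-class]; defaults to the standard dialect.
#' @return A data.frame with zero or more rows and columns
#'   \code{motifClass}, \code{anchorTerminus} ("left"/"right") and
#'   \code{ptmPosition} (0-based index of the substituted residue within the
#'   window; \code{NA} for canonical). Windows containing ambiguity letters
#'   (X, B, Z, U, O, J, *) classify as no motif with a logged notice.
#' @examples
#' classifyWindow("KFERQ")  # the eponymous canonical motif
#' classifyWindow("QKILS")  # phosphorylation-generated, left anchor
#' @export
classifyWindow <- function(window, rules = MotifRuleSet()) {
    .stopIfNot(is.character(window) && length(window) == 1L,
               "'window' must be a single string")
    window <- toupper(window)
    if (nchar(window) != 5L)
        stop("'window' must be exactly 5 residues, got ", nchar(window))
    res <- .classifyWindows(window, rules)
    if (attr(res, "nAmbiguous") > 0L)
        message("window '", window,
                "' contains non-standard letters; classified as no motif")
    data.frame(motifClass = res$motifClass,
               anchorTerminus = res$anchorTerminus,
               ptmPosition = res$ptmPos0,
               stringsAsFactors = FALSE)
}

.asSequences <- function(x) {
    if (methods::is(x, "XStringSet")) {
        seqs <- as.character(x)
    } else if (is.character(x)) {
        seqs <- x
    } else {
        stop("'x' must be an AAStringSet or a named character vector")
    }
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("all sequences must carry non-empty ids (names)")
    # FASTA description: keep only the token before the first whitespace
    ids <- sub("\\s.*$", "", ids)
    if (anyDuplicated(ids))
        stop("duplicate protein ids in collection: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(seqs) <- ids
    toupper(seqs)
}

#' Scan protein sequences for KFERQ-like motifs
#'
#' Slides a 5-residue window over every sequence and reports all motif
#' classifications of all windows, including overlapping hits. Sequences
#' shorter than 5 residues yield no hits.
#'
#' @param x an [Biostrings::AAStringSet] or named character vector of
#'   protein sequences; ids are taken from names (text after the first
#'   whitespace is dropped) and must be unique.
#' @param rules a [MotifRuleSet-class].
#' @return An [S4Vectors::DataFrame] with one row per hit, in ascending
#'   start order per protein: \code{proteinId}, \code{start} (0-based),
#'   \code{end} (exclusive, start + 5), \code{window}, \code{motifClass},
#'   \code{anchorTerminus}, \code{ptmPosition} (0-based within the window,
#'   \code{NA} for canonical).
#' @seealso [classifyWindow()], [summarizeMotifs()], [writeMotifHits()]
#' @examples
#' hits <- scanProteins(c(P1 = "KFERQKFERQ", P2 = "AAAAAAA"))
#' hits
#' @export
scanProteins <- function(x, rules = MotifRuleSet()) {
    seqs <- .asSequences(x)
    lens <- nchar(seqs)
    nw <- pmax(lens - 4L, 0L)
    emptyHits <- S4Vectors::DataFrame(
        proteinId = character(), start = integer(), end = integer(),
        window = character(), motifClass = character(),
        anchorTerminus = character(), ptmPosition = integer())
    if (sum(nw) == 0L)
        return(emptyHits)
    idxSeq <- rep.int(seq_along(seqs), nw)
    starts <- sequence(nw)
    windows <- substring(seqs[idxSeq], starts, starts + 4L)
    cls <- .classifyWindows(windows, rules)
    nAmb <- attr(cls, "nAmbiguous")
    if (nAmb > 0L)
        message(nAmb, " window(s) containing non-standard letters classified as no motif")
    if (nrow(cls) == 0L)
        return(emptyHits)
    i <- cls$idx
    S4Vectors::DataFrame(
        proteinId = names(seqs)[idxSeq[i]],
        start = starts[i] - 1L,
        end = starts[i] + 4L,
        window = unname(windows[i]),
        motifClass = cls$motifClass,
        anchorTerminus = cls$anchorTerminus,
        ptmPosition = cls$ptmPos0)
}

#' Summarise motif-class abundance over a protein collection
#'
#' Counts proteins containing at least one motif of each class. Inclusive
#' counting (the default) counts a protein towards every class it contains;
#' exclusive counting assigns each protein to a single class by the priority
#' canonical > phosphorylation-generated > acetylation-generated > none.
#'
#' @param x sequences as in [scanProteins()].
#' @param rules a [MotifRuleSet-class].
#' @param mode "inclusive" or "exclusive".
#' @return A [MotifSummary-class].
#' @examples
#' summarizeMotifs(c(A = "KFERQ", B = "AAAAAAA"))
#' @export
summarizeMotifs <- function(x, rules = MotifRuleSet(),
                            mode = c("inclusive", "exclusive")) {
    mode <- match.arg(mode)
    seqs <- .asSequences(x)
    if (length(seqs) == 0L)
        stop("empty protein collection")
    hits <- scanProteins(seqs, rules)
    counts <- stats::setNames(integer(length(MOTIF_CLASSES)), MOTIF_CLASSES)
    if (mode == "inclusive") {
        for (cl in MOTIF_CLASSES)
            counts[cl] <- length(unique(hits$proteinId[hits$motifClass == cl]))
    } else {
        assigned <- character(0)
        for (cl in MOTIF_CLASSES) {
            ids <- setdiff(unique(hits$proteinId[hits$motifClass == cl]),
                           assigned)
            counts[cl] <- length(ids)
            assigned <- c(assigned, ids)
        }
    }
    new("MotifSummary",
        nProteins = length(seqs),
        mode = mode,
        counts = counts,
        fractions = counts / length(seqs))
}

#' Compare motif abundance between two proteomes
#'
#' For each motif class, builds the 2x2 contingency table
#' (contains / does not contain) x (query / reference) and applies a
#' two-sided exact conditional test (Fisher), with Benjamini-Hochberg
#' adjustment across classes. This is the statistic behind bar-chart style
#' comparisons of a disease proteome against the reference human proteome.
#'
#' @param query,reference [MotifSummary-class] objects over the same motif
#'   classes (inclusive counting recommended).
#' @return data.frame with one row per class: counts, totals, odds ratio
#'   (sample estimate; Haldane 0.5 continuity correction flagged when a cell
#'   is zero), two-sided exact p and BH-adjusted p.
#' @examples
#' q <- summarizeMotifs(c(A = "KFERQAA", B = "KFERQGG", C = "GGGGGGG"))
#' r <- summarizeMotifs(c(D = "KFERQAA", E = "GGGGGGG", F = "PPPPPPP"))
#' compareToReference(q, r)
#' @export
compareToReference <- function(query, reference) {
    .stopIfNot(methods::is(query, "MotifSummary") &&
               methods::is(reference, "MotifSummary"),
               "'query' and 'reference' must be MotifSummary objects")
    if (query@nProteins <= 0L || reference@nProteins <= 0L)
        stop("both summaries must have positive protein totals")
    .stopIfNot(identical(names(query@counts), names(reference@counts)),
               "summaries must cover matching motif class sets")
    res <- lapply(MOTIF_CLASSES, function(cl) {
        a <- query@counts[[cl]]; b <- query@nProteins - a
        c_ <- reference@counts[[cl]]; d <- reference@nProteins - c_
        tab <- matrix(c(a, b, c_, d), nrow = 2)
        p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
        zero <- any(tab == 0)
        if (zero) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
        data.frame(motifClass = cl,
                   queryCount = query@counts[[cl]],
                   queryTotal = query@nProteins,
                   referenceCount = reference@counts[[cl]],
                   referenceTotal = reference@nProteins,
                   oddsRatio = (a / b) / (c_ / d),
                   continuityCorrected = zero,
                   pValue = p,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$pAdjusted <- stats::p.adjust(res$pValue, method = "BH")
    res
}

#' Exact frequency of canonical motif windows
#'
#' Enumerates all 20^5 standard-residue pentapeptides once and returns the
#' fraction classifying as canonical under \code{rules}. The value is cached
#' per rule set within the session, so repeated calls are cheap. Useful as a
#' null expectation for random-sequence backgrounds.
#'
#' @param rules a [MotifRuleSet-class].
#' @return A single numeric fraction in [0, 1].
#' @export
canonicalWindowFraction <- function(rules = MotifRuleSet()) {
    key <- paste(c(rules@hydrophobic, "|", rules@positive, "|",
                   rules@negative, "|", rules@anchor, "|",
                   rules@hydrophobicRange, rules@positiveRange,
                   rules@negativeCount), collapse = "")
    cached <- .cmafluxCache[[key]]
    if (!is.null(cached))
        return(cached)
    aa <- .STANDARD_AA
    g <- expand.grid(aa, aa, aa, aa, aa,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    windows <- do.call(paste0, g)
    cls <- .classifyWindows(windows, rules)
    nCanon <- length(unique(cls$idx[cls$motifClass == "canonical"]))
    frac <- nCanon / length(windows)
    .cmafluxCache[[key]] <- frac
    frac
}

.cmafluxCache <- new.env(parent = emptyenv())

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that trims ids at the
#' first whitespace and enforces uniqueness.
#'
#' @param path FASTA file.
#' @return An [Biostrings::AAStringSet] with unique names.
#' @export
readProteins <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate protein ids in ", path)
    seqs
}

#' Write motif hits as TSV
#'
#' Coordinates are written 1-based and closed (\code{start_1based},
#' \code{end_1based}, \code{ptm_position_1based}), the conventional report
#' format; the in-memory representation stays 0-based half-open.
#'
#' @param hits output of [scanProteins()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeMotifHits <- function(hits, path) {
    df <- as.data.frame(hits)
    out <- data.frame(protein_id = df$proteinId,
                      start_1based = df$start + 1L,
                      end_1based = df$end,
                      window = df$window,
                      class = df$motifClass,
                      anchor = df$anchorTerminus,
                      ptm_position_1based = df$ptmPosition + 1L)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
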