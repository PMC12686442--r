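# Independent brute-force oracles for the motif rules and the enrichment
# running sum. Deliberately written as plain per-residue loops, sharing no
# code with the package internals.

ORACLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracleResidueClass <- function(ch) {
    if (ch %in% c("F", "I", "L", "V")) return("H")
    if (ch %in% c("K", "R")) return("P")
    if (ch %in% c("E", "D")) return("N")
    if (ch %in% c("S", "T", "Y")) return("S")
    "O"
}

oracleCanonicalComp <- function(cls4) {
    nH <- sum(cls4 == "H"); nP <- sum(cls4 == "P"); nN <- sum(cls4 == "N")
    nH >= 1 && nH <= 2 && nP >= 1 && nP <= 2 && nN == 1 &&
        (nH + nP + nN) == 4
}

# All classifications a 5-mer admits, as a data.frame (possibly 0 rows) of
# motifClass / anchorTerminus / ptmPosition (0-based, NA for canonical).
oracleClassifyWindow <- function(w) {
    out <- data.frame(motifClass = character(), anchorTerminus = character(),
                      ptmPosition = integer(), stringsAsFactors = FALSE)
    ch <- strsplit(toupper(w), "")[[1]]
    stopifnot(length(ch) == 5)
    if (any(!ch %in% ORACLE_AA))
        return(out)
    add <- function(cls, side, ptm)
        rbind(out, data.frame(motifClass = cls, anchorTerminus = side,
                              ptmPosition = ptm, stringsAsFactors = FALSE))
    for (side in c("left", "right")) {
        a <- if (side == "left") 1L else 5L
        rest <- if (side == "left") 2:5 else 1:4
        restCls <- vapply(ch[rest], oracleResidueClass, "")
        canonical <- ch[a] == "Q" && oracleCanonicalComp(restCls)
        if (canonical)
            out <- add("canonical", side, NA_integer_)
        if (!canonical && ch[a] == "Q") {
            for (j in seq_along(rest)) {
                if (restCls[j] == "S") {
                    mod <- restCls
                    mod[j] <- "N"
                    if (oracleCanonicalComp(mod))
                        out <- add("phospho_generated", side, rest[j] - 1L)
                }
            }
        }
        if (ch[a] == "K" && oracleCanonicalComp(restCls))
            out <- add("acetyl_generated", side, a - 1L)
    }
    out
}

# Window-by-window oracle scan of a whole sequence; rows carry start (0-based).
oracleScanProtein <- function(seq) {
    seq <- toupper(seq)
    len <- nchar(seq)
    rows <- list()
    if (len >= 5) {
        for (st in seq_len(len - 4L)) {
            w <- substr(seq, st, st + 4L)
            cls <- oracleClassifyWindow(w)
            if (nrow(cls))
                rows[[length(rows) + 1L]] <-
                    cbind(data.frame(start = st - 1L, window = w,
                                     stringsAsFactors = FALSE), cls)
        }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(start = integer(), window = character(),
                    motifClass = character(), anchorTerminus = character(),
                    ptmPosition = integer(), stringsAsFactors = FALSE)
}

# Canonical hit rows as sortable strings, for set comparison.
hitKeys <- function(df) {
    sort(paste(df$start, df$motifClass, df$anchorTerminus,
               ifelse(is.na(df$ptmPosition), "-", df$ptmPosition),
               sep = "|"))
}

# Closed-form count of canonical 5-mers over the 20-letter alphabet:
# anchor Q at one terminus; the other four positions hold h hydrophobic
# (4 letters), p positive (2), 1 negative (2) with (h, p) in {(2,1),(1,2)}.
# Both-terminus canonical windows would need Q (unclassed) among the four
# non-anchor residues of each side, so the inclusion-exclusion term is 0.
oracleCanonicalWindowCount <- function() {
    arr <- function(h, p) factorial(4) /
        (factorial(h) * factorial(p) * factorial(1)) * 4^h * 2^p * 2^1
    2 * (arr(2, 1) + arr(1, 2))
}

# Random protein sequences over the uniform 20-letter alphabet.
randomProteins <- function(n, maxLen = 60, minLen = 5) {
    lens <- sample(seq(minLen, maxLen), n, replace = TRUE)
    seqs <- vapply(lens, function(l)
        paste(sample(ORACLE_AA, l, replace = TRUE), collapse = ""), "")
    names(seqs) <- sprintf("R%05d", seq_len(n))
    seqs
}

# Literal transcription of the weighted running-sum definition, evaluated
# position by position: ES is the larger in magnitude of the maximum and
# minimum deviation, 0 on an exact magnitude tie.
oracleEnrichmentScore <- function(scores, geneSet, exponent) {
    ord <- order(scores, decreasing = TRUE)
    ids <- names(scores)[ord]
    s <- unname(scores[ord])
    N <- length(s)
    hit <- ids %in% geneSet
    Nh <- sum(hit)
    nr <- sum(abs(s[hit])^exponent)
    run <- 0
    top <- 0
    bottom <- 0
    for (i in seq_len(N)) {
        run <- run + if (hit[i]) abs(s[i])^exponent / nr else -1 / (N - Nh)
        if (run > top) top <- run
        if (run < bottom) bottom <- run
    }
    tol <- 1e-12 * max(top, -bottom, 1)
    if (top + bottom > tol) top else if (top + bottom < -tol) bottom else 0
}
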