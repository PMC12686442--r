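test_that("window classification reproduces the rule examples", {
    # the eponymous canonical motif: 2 positive, 1 hydrophobic, 1 negative, Q
    kferq <- classifyWindow("KFERQ")
    expect_equal(nrow(kferq), 1L)
    expect_equal(kferq$motifClass, "canonical")
    expect_equal(kferq$anchorTerminus, "right")
    expect_true(is.na(kferq$ptmPosition))

    # no anchor, no classed residues
    expect_equal(nrow(classifyWindow("AAAAA")), 0L)

    # S recounted as the negative residue completes the composition
    qkils <- classifyWindow("QKILS")
    expect_equal(qkils$motifClass, "phospho_generated")
    expect_equal(qkils$anchorTerminus, "left")
    expect_equal(qkils$ptmPosition, 4L)

    # terminal K as Q-mimic; both termini qualify here per the oracle
    kferk <- classifyWindow("KFERK")
    orc <- oracleClassifyWindow("KFERK")
    expect_setequal(paste(kferk$motifClass, kferk$anchorTerminus,
                          kferk$ptmPosition),
                    paste(orc$motifClass, orc$anchorTerminus,
                          orc$ptmPosition))
    expect_true(all(kferk$motifClass == "acetyl_generated"))

    expect_error(classifyWindow("KFER"), "exactly 5")
    expect_error(classifyWindow("KFERQA"), "exactly 5")
    expect_message(res <- classifyWindow("KFXRQ"), "non-standard")
    expect_equal(nrow(res), 0L)
    # lower-case input is accepted
    expect_equal(classifyWindow("kferq")$motifClass, "canonical")
})

test_that("protein scanning enumerates every window in ascending order", {
    h1 <- scanProteins(c(P = "KFERQ"))
    expect_equal(nrow(h1), 1L)
    expect_equal(h1$start, 0L)
    expect_equal(h1$end, 5L)

    expect_equal(nrow(scanProteins(c(P = "KFE"))), 0L)
    expect_equal(nrow(scanProteins(c(P = ""))), 0L)

    h2 <- as.data.frame(scanProteins(c(P = "KFERQKFERQ")))
    orc <- oracleScanProtein("KFERQKFERQ")
    expect_setequal(hitKeys(h2), hitKeys(orc))
    expect_true(all(c(0L, 5L) %in% h2$start[h2$motifClass == "canonical"]))
    expect_false(is.unsorted(h2$start))

    expect_error(scanProteins(c(P = "KFERQ", P = "AAAAA")), "duplicate")
    expect_error(scanProteins(stats::setNames("KFERQ", "")), "non-empty")
})

test_that("scanner output equals the brute-force oracle on random sequences", {
    set.seed(42)
    seqs <- randomProteins(300, maxLen = 60)
    hits <- as.data.frame(scanProteins(seqs))
    for (id in names(seqs)) {
        mine <- hits[hits$proteinId == id, , drop = FALSE]
        orc <- oracleScanProtein(seqs[[id]])
        expect_identical(hitKeys(mine), hitKeys(orc))
    }
})

test_that("concatenation only creates new hits near the junction", {
    set.seed(7)
    for (i in 1:50) {
        a <- paste(sample(ORACLE_AA, sample(5:30, 1), TRUE), collapse = "")
        b <- paste(sample(ORACLE_AA, sample(5:30, 1), TRUE), collapse = "")
        ha <- as.data.frame(scanProteins(c(X = a)))
        hb <- as.data.frame(scanProteins(c(X = b)))
        hb$start <- hb$start + nchar(a)
        hab <- as.data.frame(scanProteins(c(X = paste0(a, b))))
        old <- union(hitKeys(ha), hitKeys(hb))
        expect_true(all(old %in% hitKeys(hab)))
        new <- setdiff(hitKeys(hab), old)
        if (length(new)) {
            newStarts <- as.integer(sub("\\|.*", "", new))
            expect_true(all(newStarts > nchar(a) - 5 &
                            newStarts < nchar(a) + 1))
        }
    }
})

test_that("class logic: PTM classes never coincide with canonical at an anchor", {
    set.seed(11)
    windows <- vapply(1:2000, function(i)
        paste(sample(c("F", "K", "R", "E", "Q", "S", "A", "L"), 5, TRUE),
              collapse = ""), "")
    for (w in unique(windows)) {
        cls <- classifyWindow(w)
        if (!nrow(cls)) next
        # canonical and phospho are mutually exclusive per anchor
        for (side in c("left", "right")) {
            sub <- cls$motifClass[cls$anchorTerminus == side]
            expect_false(all(c("canonical", "phospho_generated") %in% sub))
        }
        # acetyl anchors carry K, never Q
        ac <- cls[cls$motifClass == "acetyl_generated", , drop = FALSE]
        if (nrow(ac)) {
            term <- ifelse(ac$anchorTerminus == "left",
                           substr(w, 1, 1), substr(w, 5, 5))
            expect_true(all(term == "K"))
        }
    }
})

test_that("collection summaries count inclusively and exclusively", {
    s <- summarizeMotifs(c(A = "KFERQ", B = "AAAAAAA"))
    expect_equal(unname(motifFractions(s)), c(0.5, 0, 0))

    s2 <- summarizeMotifs(c(A = "KFERQ", B = "QKILS"))
    expect_equal(unname(motifFractions(s2)), c(0.5, 0.5, 0))

    # one protein holding both a canonical and a phospho window
    mixed <- "KFERQAAQKILS"
    inc <- summarizeMotifs(c(A = mixed), mode = "inclusive")
    exc <- summarizeMotifs(c(A = mixed), mode = "exclusive")
    expect_equal(unname(motifCounts(inc))[1:2], c(1L, 1L))
    expect_equal(unname(motifCounts(exc)), c(1L, 0L, 0L))
    # inclusive count per class >= exclusive count
    expect_true(all(motifCounts(inc) >= motifCounts(exc)))

    expect_error(summarizeMotifs(character(0)), "empty")
})

test_that("reference comparison applies an exact two-sided test with BH", {
    eq <- compareToReference(makeSummary(50, 100), makeSummary(50, 100))
    expect_equal(eq$oddsRatio[1], 1)
    expect_equal(eq$pValue[1], 1)

    # 9/10 vs 1/10: two-sided Fisher p by full enumeration of the
    # conditional table set (row sums 10/10, column sums 10/10)
    res <- compareToReference(makeSummary(9, 10), makeSummary(1, 10))
    probs <- dhyper(0:10, 10, 10, 10)
    pExact <- sum(probs[probs <= dhyper(9, 10, 10, 10) * (1 + 1e-7)])
    expect_equal(res$pValue[1], pExact, tolerance = 1e-12)
    expect_gt(res$oddsRatio[1], 1)

    # monotonicity: larger query fraction -> OR > 1
    mono <- compareToReference(makeSummary(60, 100), makeSummary(40, 100))
    expect_gt(mono$oddsRatio[1], 1)
    # adjusted p present for every class
    expect_equal(length(res$pAdjusted), 3L)
    # a zero-total summary is unrepresentable: validity rejects it outright
    expect_error(makeSummary(0, 0), "fractions")
})
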