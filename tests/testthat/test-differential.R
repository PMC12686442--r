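test_that("unpaired testing equals a per-row Welch t-test oracle", {
    mat <- rbind(P1 = c(10.0, 10.1, 9.9, 11.0, 11.1, 10.9))
    colnames(mat) <- paste0("s", 1:6)
    cd <- data.frame(condition = rep(c("control", "NL"), each = 3))
    res <- rowwiseTest(mat, cd, design = "unpaired")
    ref <- t.test(mat[1, 4:6], mat[1, 1:3])
    expect_equal(res$log2FC, 1.0, tolerance = 1e-12)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$pValue, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-12)

    set.seed(5)
    big <- matrix(rnorm(50 * 7, mean = 12), 50, 7,
                  dimnames = list(sprintf("Q%02d", 1:50), paste0("s", 1:7)))
    cd2 <- data.frame(condition = rep(c("control", "NL"), c(3, 4)))
    res2 <- rowwiseTest(big, cd2, design = "unpaired")
    for (i in 1:50) {
        ref <- t.test(big[i, 4:7], big[i, 1:3])
        expect_equal(res2$t[i], unname(ref$statistic), tolerance = 1e-12)
        expect_equal(res2$pValue[i], ref$p.value, tolerance = 1e-12)
    }
})

test_that("paired testing equals a per-row one-sample t-test on donor differences", {
    set.seed(6)
    nd <- 4
    mat <- matrix(rnorm(40 * 2 * nd, mean = 10), 40, 2 * nd,
                  dimnames = list(sprintf("Q%02d", 1:40),
                                  paste0("s", 1:(2 * nd))))
    cd <- data.frame(condition = rep(c("control", "NL"), nd),
                     donor = rep(paste0("D", 1:nd), each = 2))
    res <- rowwiseTest(mat, cd)   # auto -> paired
    for (i in 1:40) {
        d <- mat[i, cd$condition == "NL"] - mat[i, cd$condition == "control"]
        ref <- t.test(d)
        expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-12)
        expect_equal(res$pValue[i], ref$p.value, tolerance = 1e-12)
        expect_equal(res$log2FC[i], mean(d), tolerance = 1e-12)
    }
    expect_true(all(res$nPairs == nd))
})

test_that("identical groups and degenerate variances follow the edge contract", {
    mat <- rbind(SAME = c(5, 6, 7, 5, 6, 7),
                 DEGEN = c(1, 1, 1, 2, 2, 2),
                 FLAT = c(3, 3, 3, 3, 3, 3))
    colnames(mat) <- paste0("s", 1:6)
    cd <- data.frame(condition = rep(c("control", "NL"), each = 3))
    res <- rowwiseTest(mat, cd, design = "unpaired")
    expect_equal(res$log2FC[1], 0)
    expect_equal(res$t[1], 0)
    expect_equal(res$pValue[1], 1)
    # zero within-group variance, unequal means: limiting p = 0, flagged
    expect_equal(res$pValue[2], 0)
    expect_true(is.infinite(res$t[2]))
    expect_equal(res$flag[2], "degenerate_variance")
    # zero variance, equal means: t = 0, p = 1
    expect_equal(res$pValue[3], 1)
})

test_that("missing-data rules flag untestable proteins", {
    mat <- rbind(OK   = c(10, 11, 10, 12, 12, 13),
                 ONE  = c(NA, NA, NA, 12, 12, 13),
                 THIN = c(10, NA, NA, 12, 12, 13))
    colnames(mat) <- paste0("s", 1:6)
    cd <- data.frame(condition = rep(c("control", "NL"), each = 3))
    res <- rowwiseTest(mat, cd, design = "unpaired")
    expect_equal(res$flag, c("ok", "one_condition_only", "insufficient_n"))
    expect_true(is.na(res$pValue[2]) && is.na(res$pValue[3]))
    expect_true(is.na(res$log2FC[2]))
    # raw-scale input is log2-transformed: 2-fold accumulation -> log2FC = 1
    raw <- rbind(A = c(100, 100, 200, 200), B = c(400, 400, 800, 800))
    colnames(raw) <- paste0("s", 1:4)
    cdr <- data.frame(condition = rep(c("control", "NL"), each = 2))
    rr <- rowwiseTest(raw, cdr, design = "unpaired", scale = "raw",
                      normalize = FALSE)
    expect_equal(rr$log2FC, c(1, 1), tolerance = 1e-12)
    # median-centring removes a per-sample loading offset
    loaded <- raw
    loaded[, 1] <- loaded[, 1] * 10
    rn <- rowwiseTest(loaded, cdr, design = "unpaired", scale = "raw")
    r0 <- rowwiseTest(raw, cdr, design = "unpaired", scale = "raw")
    expect_equal(rn$log2FC, r0$log2FC, tolerance = 1e-12)
})

test_that("substrate filter applies FC, p and motif gates exactly", {
    d <- makeDiff(paste0("P", 1:4),
                  log2FC = log2(c(1.5, 1.5, 1.2, 1.5)),
                  pValue = c(0.001, 0.02, 0.001, 0.001))
    motifs <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE), paste0("P", 1:4))
    set <- callSubstrates(d, motifs)
    expect_equal(substrateIds(set), "P1")

    # filter identity: thresholds at the boundary call every enriched protein
    all <- callSubstrates(d, motifs, fcMin = 1.0, pMax = 1.0,
                          requireMotif = FALSE)
    expect_setequal(substrateIds(all), paste0("P", 1:4))

    expect_error(callSubstrates(d, motifs, fcMin = -1), "positive")
    expect_error(callSubstrates(d, motifs, pMax = 0), "0, 1")
    expect_error(callSubstrates(d, motifs, pMax = 1.5), "0, 1")
})

test_that("relaxing thresholds never removes a called protein", {
    set.seed(8)
    d <- makeDiff(sprintf("P%03d", 1:200),
                  log2FC = rnorm(200, 0.2, 0.5),
                  pValue = runif(200)^2)
    motifs <- stats::setNames(runif(200) < 0.5, sprintf("P%03d", 1:200))
    strict <- substrateIds(callSubstrates(d, motifs, fcMin = 1.5,
                                          pMax = 0.01))
    for (fc in c(1.4, 1.25, 1.1)) {
        for (p in c(0.02, 0.05, 0.2)) {
            loose <- substrateIds(callSubstrates(d, motifs, fcMin = fc,
                                                 pMax = p))
            expect_true(all(strict %in% loose))
        }
    }
    # dropping the motif gate enlarges or preserves the set
    gated <- substrateIds(callSubstrates(d, motifs))
    ungated <- substrateIds(callSubstrates(d, motifs, requireMotif = FALSE))
    expect_true(all(gated %in% ungated))
})

test_that("set overlap satisfies the union identity and symmetry", {
    a <- paste0("P", 1:5)
    expect_equal(overlapSets(a, a)$jaccard, 1)
    expect_equal(overlapSets(a, paste0("Q", 1:5))$jaccard, 0)
    b <- c(a[1:3], "X1", "X2", "X3", "X4")
    ab <- overlapSets(a, b)
    ba <- overlapSets(b, a)
    expect_equal(ab$unionSize, ab$sizeA + ab$sizeB - ab$intersectionSize)
    expect_equal(ab$jaccard, ba$jaccard)
    expect_message(z <- overlapSets(character(0), character(0)), "empty")
    expect_equal(z$jaccard, 0)
})

test_that("null experiments call substrates at most at the nominal rate", {
    # no planted signal (FC = 1): among tested motif+ proteins, the called
    # fraction is bounded by the raw-p cut times the FC-pass fraction
    called <- 0L
    tested <- 0L
    for (r in 1:200) {
        sim <- simulateNlExperiment(nProteins = 150, fracSubstrates = 0,
                                    accumulationFC = 1, noiseSd = 0.1,
                                    nDonors = 5, seed = 9000 + r)
        d <- rowwiseTest(sim$quant)
        set <- callSubstrates(d, sim$motifs)
        ok <- d$flag == "ok" & sim$motifs[d$proteinId]
        tested <- tested + sum(ok)
        called <- called + length(substrateIds(set))
    }
    expect_lte(called / tested, 0.01)
})
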