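test_that("score fixtures match the hand-computed weighted z-average", {
    # single +1/weight-1 gene over two samples: population-SD z forces -1/+1
    net <- CmaNetwork("G1", "effector")
    expr <- matrix(c(0, 2), 1, dimnames = list("G1", c("s1", "s2")))
    expect_equal(unname(cmaScores(computeCmaScore(expr, net))),
                 c(-1, 1), tolerance = 1e-12)

    # LAMP2 (w=2, d=+1) and a negative modulator (w=1, d=-1):
    # z_LAMP2 = (+1,-1), z_NEG = (-1,+1);
    # scores = ((2*1*1 + 1*(-1)*(-1))/3, (2*1*(-1) + 1*(-1)*(+1))/3) = (1,-1)
    net2 <- CmaNetwork(c("LAMP2", "GENE_NEG"),
                       c("effector", "negative_modulator"))
    expr2 <- rbind(LAMP2 = c(2, 0), GENE_NEG = c(0, 2))
    colnames(expr2) <- c("s1", "s2")
    expect_equal(unname(cmaScores(computeCmaScore(expr2, net2))),
                 c(1, -1), tolerance = 1e-12)

    # raw counts go through log2(x + 1): raw (0, 3) == log (0, 2)
    raw <- matrix(c(0, 3), 1, dimnames = list("G1", c("s1", "s2")))
    expect_equal(cmaScores(computeCmaScore(raw, net, scale = "raw_counts")),
                 cmaScores(computeCmaScore(expr, net)), tolerance = 1e-12)
})

test_that("score matches the stated formula on random fixtures", {
    set.seed(1)
    genes <- c("LAMP2", "GP", "GN1", "GN2")
    net <- CmaNetwork(genes, c("effector", "positive_modulator",
                               "negative_modulator", "negative_modulator"))
    tb <- networkTable(net)
    for (i in 1:20) {
        expr <- matrix(rnorm(4 * 6), 4, 6,
                       dimnames = list(genes, paste0("s", 1:6)))
        got <- cmaScores(computeCmaScore(expr, net))
        mu <- rowMeans(expr)
        sdp <- sqrt(rowMeans((expr - mu)^2))
        z <- (expr - mu) / sdp
        want <- colSums(z * tb$direction * tb$weight) / sum(tb$weight)
        expect_equal(got, want, tolerance = 1e-12)
        # LAMP2's weight-2 coefficient is exactly twice a weight-1 gene's
        expect_equal(tb$weight[tb$gene == "LAMP2"], 2)
    }
})

test_that("score invariances: location, scale, direction flip, zero mean", {
    set.seed(2)
    genes <- c("EFF1", "GA", "GB", "GN")
    net <- CmaNetwork(genes, c("effector", "effector", "positive_modulator",
                               "negative_modulator"),
                      weight = c(2, 1, 1, 1))
    flipped <- CmaNetwork(genes,
                          c("negative_modulator", "negative_modulator",
                            "negative_modulator", "effector"),
                          direction = c(-1, -1, -1, 1),
                          weight = c(2, 1, 1, 1))
    for (i in 1:100) {
        expr <- matrix(rnorm(4 * 5, sd = 2), 4, 5,
                       dimnames = list(genes, paste0("s", 1:5)))
        base <- cmaScores(computeCmaScore(expr, net))
        # all genes used -> scores average to zero across samples
        expect_equal(mean(base), 0, tolerance = 1e-12)
        # adding a constant to one gene changes nothing
        shifted <- expr; shifted["GA", ] <- shifted["GA", ] + 100
        expect_equal(cmaScores(computeCmaScore(shifted, net)), base,
                     tolerance = 1e-12)
        # positive rescaling of one gene changes nothing
        scaled <- expr; scaled["GN", ] <- scaled["GN", ] * 7
        expect_equal(cmaScores(computeCmaScore(scaled, net)), base,
                     tolerance = 1e-12)
        # flipping every direction negates every score
        expect_equal(cmaScores(computeCmaScore(expr, flipped)), -base,
                     tolerance = 1e-12)
    }
})

test_that("gene dropping and degenerate inputs follow the contract", {
    net <- CmaNetwork(c("G1", "G2", "G3"),
                      c("effector", "effector", "negative_modulator"))
    expr <- rbind(G1 = c(0, 2, 1), G2 = c(5, 5, 5))
    colnames(expr) <- paste0("s", 1:3)
    expect_warning(res <- computeCmaScore(expr, net), "zero variance")
    expect_equal(genesUsed(res), "G1")
    dropped <- genesDropped(res)
    expect_setequal(dropped$gene, c("G2", "G3"))
    expect_equal(dropped$reason[dropped$gene == "G3"], "absent")
    expect_equal(dropped$reason[dropped$gene == "G2"], "zero_variance")
    # used + dropped partition the network genes
    expect_setequal(c(genesUsed(res), dropped$gene), networkGenes(net))

    flat <- rbind(G1 = c(1, 1), G2 = c(2, 2))
    colnames(flat) <- c("s1", "s2")
    expect_error(suppressWarnings(computeCmaScore(flat, net)),
                 "no informative")
    expect_error(computeCmaScore(expr[, 1, drop = FALSE], net),
                 "2 samples")
})

test_that("group comparison reports means, sem and the two-sample t", {
    scores <- stats::setNames(c(-1, -1, 1, 1), paste0("s", 1:4))
    g <- stats::setNames(c("a", "a", "b", "b"), paste0("s", 1:4))
    res <- scoreGroups(scores, g)
    expect_equal(res$comparison$difference, -2)
    # identical groups -> t = 0, p = 1
    same <- scoreGroups(stats::setNames(c(1, 2, 1, 2), paste0("s", 1:4)), g)
    expect_equal(same$comparison$t, 0)
    expect_equal(same$comparison$pValue, 1)
    # agrees with the classical equal-variance t-test
    set.seed(3)
    x <- stats::setNames(rnorm(10), paste0("s", 1:10))
    g2 <- stats::setNames(rep(c("a", "b"), each = 5), paste0("s", 1:10))
    ref <- t.test(x[1:5], x[6:10], var.equal = TRUE)
    got <- scoreGroups(x, g2)$comparison
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$pValue, ref$p.value, tolerance = 1e-12)
    expect_error(scoreGroups(scores, g[1:2]), "no group label")
})

test_that("a planted network down-shift lowers the scored group", {
    sim <- simulateExpression(delta = 1, seed = 101)
    sc <- computeCmaScore(sim$expr)
    res <- scoreGroups(sc, sim$groups)
    m <- stats::setNames(res$groups$mean, res$groups$group)
    expect_gt(m[["healthy"]], m[["amd_like"]])
})
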