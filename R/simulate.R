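## Seeded generators of synthetic inputs with known ground truth: motif-
## bearing proteomes, CMA-network-shifted expression matrices, and paired
## control vs N/L flux-proteomics experiments with planted substrates.

# One background sequence guaranteed free of motifs of any class.
.motifFreeSeq <- function(len, rules, maxIter = 1000L) {
    for (i in seq_len(maxIter)) {
        s <- paste(sample(.STANDARD_AA, len, replace = TRUE), collapse = "")
        if (len < 5L)
            return(s)
        starts <- seq_len(len - 4L)
        windows <- substring(s, starts, starts + 4L)
        if (nrow(.classifyWindows(windows, rules)) == 0L)
            return(s)
    }
    stop("rejection sampling cap exceeded; try shorter sequences")
}

# Random pentapeptide of the requested motif class under `rules`.
.makeMotifPeptide <- function(class, rules) {
    comp <- if (stats::runif(1) < 0.5) c(2L, 1L) else c(1L, 2L)  # (nH, nP)
    side <- if (stats::runif(1) < 0.5) "left" else "right"
    res <- switch(class,
        canonical = c(sample(rules@hydrophobic, comp[1], replace = TRUE),
                      sample(rules@positive, comp[2], replace = TRUE),
                      sample(rules@negative, 1)),
        phospho_generated = {
            hp <- if (stats::runif(1) < 0.5) c(2L, 1L) else c(1L, 2L)
            c(sample(rules@hydrophobic, hp[1], replace = TRUE),
              sample(rules@positive, hp[2], replace = TRUE),
              sample(rules@phosphoMimics, 1))
        },
        acetyl_generated = c(sample(rules@hydrophobic, comp[1], replace = TRUE),
                             sample(rules@positive, comp[2], replace = TRUE),
                             sample(rules@negative, 1)),
        stop("unknown motif class: ", class))
    res <- sample(res)  # random arrangement of the four classed residues
    anchor <- if (class == "acetyl_generated") rules@acetylAnchorMimic
              else rules@anchor
    if (side == "left") paste(c(anchor, res), collapse = "")
    else paste(c(res, anchor), collapse = "")
}

# Inclusive class set a full protein admits.
.proteinClasses <- function(seq, rules) {
    len <- nchar(seq)
    if (len < 5L) return(character(0))
    starts <- seq_len(len - 4L)
    cls <- .classifyWindows(substring(seq, starts, starts + 4L), rules)
    unique(cls$motifClass)
}

#' Simulate a proteome with planted KFERQ-like motifs
#'
#' Background sequences are rejection-sampled from the uniform 20-letter
#' alphabet until they contain no motif of any class; planted sequences
#' additionally receive one pentapeptide of their assigned class inserted at
#' a random interior position, and are re-drawn until the scanner recovers
#' exactly the assigned class (insertion junctions can otherwise create
#' extra motifs). Planted fractions are therefore recovered exactly by
#' [summarizeMotifs()]. Generation is a pure function of the configuration
#' and seed.
#'
#' @param nProteins number of proteins.
#' @param lengthRange final sequence length range (uniform; min >= 12).
#' @param fracCanonical,fracPhospho,fracAcetyl planted fractions per class
#'   (must sum to <= 1; counts are rounded).
#' @param rules a [MotifRuleSet-class].
#' @param seed optional integer seed.
#' @param maxIter rejection-sampling cap per sequence.
#' @return A list: \code{proteins} ([Biostrings::AAStringSet]) and
#'   \code{truth} (data.frame: proteinId, plantedClass, insertStart0 —
#'   0-based insertion offset, NA for background).
#' @export
simulateProteome <- function(nProteins = 1000, lengthRange = c(30, 60),
                             fracCanonical = 0.1, fracPhospho = 0.05,
                             fracAcetyl = 0.05, rules = MotifRuleSet(),
                             seed = NULL, maxIter = 1000L) {
    fracs <- c(fracCanonical, fracPhospho, fracAcetyl)
    .stopIfNot(all(fracs >= 0) && sum(fracs) <= 1,
               "planted fractions must be in [0, 1] and sum to <= 1")
    .stopIfNot(nProteins >= 1, "'nProteins' must be positive")
    .stopIfNot(lengthRange[1] >= 12, "minimum length must be >= 12")
    nPer <- round(nProteins * fracs)
    classVec <- rep(c(MOTIF_CLASSES, "none"),
                    c(nPer, nProteins - sum(nPer)))
    .withSeed(seed, {
        seqs <- character(nProteins)
        insertAt <- rep(NA_integer_, nProteins)
        lens <- sample(seq(lengthRange[1], lengthRange[2]), nProteins,
                       replace = TRUE)
        for (i in seq_len(nProteins)) {
            cl <- classVec[i]
            if (cl == "none") {
                seqs[i] <- .motifFreeSeq(lens[i], rules, maxIter)
            } else {
                for (att in seq_len(maxIter)) {
                    core <- .motifFreeSeq(lens[i] - 5L, rules, maxIter)
                    pos <- sample.int(nchar(core) - 1L, 1L)  # interior
                    cand <- paste0(substr(core, 1L, pos),
                                   .makeMotifPeptide(cl, rules),
                                   substr(core, pos + 1L, nchar(core)))
                    if (identical(.proteinClasses(cand, rules), cl)) {
                        seqs[i] <- cand
                        insertAt[i] <- pos
                        break
                    }
                    if (att == maxIter)
                        stop("rejection sampling cap exceeded; try shorter sequences")
                }
            }
        }
        ids <- sprintf("SYN%05d", seq_len(nProteins))
        proteins <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
        list(proteins = proteins,
             truth = data.frame(proteinId = ids, plantedClass = classVec,
                                insertStart0 = insertAt,
                                stringsAsFactors = FALSE))
    })
}

#' Simulate an expression matrix with a planted CMA-network shift
#'
#' Baseline log2 expression is Normal(mu_g, noiseSd) with per-gene means
#' drawn uniformly from \code{baselineRange}. In the second ("AMD-like")
#' group every network gene g is shifted by \code{-direction_g * delta}, so
#' the planted CMA-score difference (first group minus second) is positive
#' for delta > 0.
#'
#' @param network a [CmaNetwork-class]; its genes are embedded in the
#'   matrix alongside filler genes.
#' @param nGenes total gene count (>= network size).
#' @param nPerGroup samples per group.
#' @param delta planted shift in log2 units.
#' @param noiseSd residual SD in log2 units.
#' @param baselineRange range of per-gene baseline means (log2 units).
#' @param groupNames two group labels.
#' @param seed optional integer seed.
#' @return A list: \code{expr} (genes x samples log-normalised matrix),
#'   \code{groups} (named character: sample -> group), \code{truth}
#'   (list: delta, shiftedGenes data.frame(gene, shift)).
#' @export
simulateExpression <- function(network = defaultCmaNetwork(), nGenes = 200,
                               nPerGroup = 10, delta = 1, noiseSd = 0.5,
                               baselineRange = c(4, 10),
                               groupNames = c("healthy", "amd_like"),
                               seed = NULL) {
    tb <- networkTable(network)
    .stopIfNot(nGenes >= nrow(tb), "'nGenes' must cover the network genes")
    .stopIfNot(nPerGroup >= 1, "'nPerGroup' must be positive")
    .stopIfNot(length(groupNames) == 2L, "exactly two group names required")
    .withSeed(seed, {
        nFill <- nGenes - nrow(tb)
        genes <- c(tb$gene, sprintf("FILLER%04d", seq_len(nFill)))
        samples <- c(sprintf("%s_%02d", groupNames[1], seq_len(nPerGroup)),
                     sprintf("%s_%02d", groupNames[2], seq_len(nPerGroup)))
        groups <- stats::setNames(rep(groupNames, each = nPerGroup), samples)
        mu <- stats::runif(nGenes, baselineRange[1], baselineRange[2])
        mat <- matrix(stats::rnorm(nGenes * 2 * nPerGroup, mean = mu,
                                   sd = noiseSd),
                      nrow = nGenes, dimnames = list(genes, samples))
        shift <- stats::setNames(-tb$direction * delta, tb$gene)
        second <- groups[colnames(mat)] == groupNames[2]
        mat[tb$gene, second] <- mat[tb$gene, second] + shift
        list(expr = mat, groups = groups,
             truth = list(delta = delta,
                          shiftedGenes = data.frame(gene = tb$gene,
                                                    shift = unname(shift),
                                                    stringsAsFactors = FALSE)))
    })
}

#' Simulate a paired control vs N/L flux-proteomics experiment
#'
#' Emulates lysosomal-proteolysis inhibition (NH4Cl + leupeptin): per donor,
#' control log2 intensity is Normal(mu_p, noiseSd) plus a donor offset
#' (log-normal intensity noise with additive log2 effects); the N/L sample
#' adds log2(accumulationFC) to planted substrate proteins only. Planted
#' substrates are all motif-positive in the companion annotation;
#' non-substrates are motif-positive at \code{motifBackgroundRate}.
#' Missingness is applied completely at random.
#'
#' @param nProteins number of proteins.
#' @param fracSubstrates fraction of proteins planted as substrates.
#' @param accumulationFC linear fold accumulation under N/L (>= 1; 1 = null
#'   experiment).
#' @param noiseSd residual SD in log2 units.
#' @param nDonors number of donors (>= 2); one control and one N/L sample
#'   each.
#' @param missingness fraction of intensities set missing at random.
#' @param donorSd SD of the per-donor log2 offset.
#' @param baselineRange range of per-protein baseline means (log2 units).
#' @param motifBackgroundRate motif-positive probability for
#'   non-substrates (default 0.45, the approximate canonical-motif
#'   prevalence of the human proteome).
#' @param seed optional integer seed.
#' @return A list: \code{quant}
#'   ([SummarizedExperiment::SummarizedExperiment], log2 assay, colData
#'   condition/donor, \code{metadata(.)$scale = "log2"}), \code{motifs}
#'   (named logical), \code{truth} (list: substrates, accumulationFC).
#' @export
simulateNlExperiment <- function(nProteins = 500, fracSubstrates = 0.1,
                                 accumulationFC = 2, noiseSd = 0.1,
                                 nDonors = 5, missingness = 0,
                                 donorSd = 0.3, baselineRange = c(8, 14),
                                 motifBackgroundRate = 0.45, seed = NULL) {
    .stopIfNot(fracSubstrates >= 0 && fracSubstrates <= 1,
               "'fracSubstrates' must lie in [0, 1]")
    .stopIfNot(accumulationFC >= 1, "'accumulationFC' must be >= 1")
    .stopIfNot(nDonors >= 2, "'nDonors' must be >= 2")
    .stopIfNot(missingness >= 0 && missingness < 1,
               "'missingness' must lie in [0, 1)")
    .withSeed(seed, {
        ids <- sprintf("PROT%05d", seq_len(nProteins))
        nSub <- round(nProteins * fracSubstrates)
        substrates <- sort(sample(ids, nSub))
        isSub <- ids %in% substrates
        donors <- sprintf("D%02d", seq_len(nDonors))
        samples <- as.vector(t(outer(donors, c("control", "NL"),
                                     paste, sep = "_")))
        condition <- rep(c("control", "NL"), times = nDonors)
        donor <- rep(donors, each = 2L)
        mu <- stats::runif(nProteins, baselineRange[1], baselineRange[2])
        offs <- stats::setNames(stats::rnorm(nDonors, 0, donorSd), donors)
        mat <- matrix(NA_real_, nProteins, 2L * nDonors,
                      dimnames = list(ids, samples))
        for (j in seq_along(samples)) {
            eff <- if (condition[j] == "NL")
                isSub * log2(accumulationFC) else 0
            mat[, j] <- mu + offs[donor[j]] + eff +
                stats::rnorm(nProteins, 0, noiseSd)
        }
        if (missingness > 0) {
            drop <- stats::runif(length(mat)) < missingness
            mat[drop] <- NA_real_
        }
        motifs <- stats::setNames(
            isSub | stats::runif(nProteins) < motifBackgroundRate, ids)
        motifs[isSub] <- TRUE
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(log2intensity = mat),
            colData = S4Vectors::DataFrame(condition = condition,
                                           donor = donor,
                                           row.names = samples))
        S4Vectors::metadata(se)$scale <- "log2"
        list(quant = se, motifs = motifs,
             truth = list(substrates = substrates,
                          accumulationFC = accumulationFC))
    })
}
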