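## End-to-end orchestration of the flux-proteomics substrate-discovery flow:
## (simulate ->) scan -> differential test -> motif-gated substrate call ->
## over-representation, with a reproducible JSON manifest.

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeTsv <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.readMotifTsv <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    .stopIfNot(all(c("protein_id", "has_motif") %in% names(df)),
               "motif TSV needs columns protein_id, has_motif")
    stats::setNames(as.logical(df$has_motif), df$protein_id)
}

.readQuantTsv <- function(quantPath, annotPath, scale) {
    qdf <- utils::read.table(quantPath, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as.matrix(qdf[, -1, drop = FALSE])
    rownames(mat) <- qdf[[1]]
    cd <- utils::read.table(annotPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    .stopIfNot("sample" %in% names(cd),
               "annotation TSV needs a 'sample' column")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = mat[, cd$sample, drop = FALSE]),
        colData = S4Vectors::DataFrame(cd[setdiff(names(cd), "sample")],
                                       row.names = cd$sample))
    S4Vectors::metadata(se)$scale <- scale
    se
}

#' Run the substrate-discovery pipeline
#'
#' Executes the requested stages in dependency order on either simulated or
#' file-based inputs, writes every intermediate as plain TSV/JSON, and
#' records a manifest (parameters, seed, input and output MD5 checksums).
#' Re-running with an identical configuration and seed reproduces all
#' outputs byte-identically. A failing stage halts the run with the stage
#' named and leaves a \code{FAILED} marker next to any partial outputs.
#'
#' Configuration (YAML file or nested list):
#' \describe{
#'   \item{seed}{integer seed used for every stochastic stage.}
#'   \item{output_dir}{output directory (created if needed).}
#'   \item{simulate}{optional; \code{nl} and/or \code{proteome} entries with
#'     arguments for [simulateNlExperiment()] / [simulateProteome()]
#'     (snake_case keys, e.g. \code{n_proteins}, \code{frac_substrates},
#'     \code{accumulation_fc}, \code{noise_sd}, \code{n_donors}).}
#'   \item{scan}{optional; \code{fasta} path (or \code{"simulated"}) and
#'     \code{mode} ("inclusive"/"exclusive").}
#'   \item{differential}{\code{quant} and \code{annotation} TSV paths when
#'     not simulating; optional \code{design}, \code{scale},
#'     \code{normalize}.}
#'   \item{call_substrates}{\code{fc_min} (default 1.25), \code{p_max}
#'     (default 0.01), \code{motif_gate} (default TRUE), optional
#'     \code{motifs} TSV (protein_id, has_motif), \code{label}.}
#'   \item{ora}{optional; \code{gmt} path. Query = called substrates,
#'     background = all tested proteins.}
#' }
#'
#' @param config YAML path or list as described above.
#' @param outputDir overrides \code{config$output_dir}.
#' @return Invisibly, a list with \code{manifest}, \code{manifestPath},
#'   \code{differential}, \code{substrates} and the written \code{paths}.
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    .stopIfNot(is.list(config), "'config' must be a list or a YAML path")
    outDir <- if (!is.null(outputDir)) outputDir else config$output_dir
    .stopIfNot(!is.null(outDir), "an output directory is required")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- config$seed

    state <- new.env(parent = emptyenv())
    state$paths <- character()
    state$inputs <- character()
    stage <- function(name, fun) {
        tryCatch(fun(), error = function(e) {
            writeLines(paste0("stage '", name, "' failed: ",
                              conditionMessage(e)),
                       file.path(outDir, "FAILED"))
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    }
    addPath <- function(name, path) state$paths[name] <- path
    addInput <- function(path) state$inputs <- c(state$inputs, path)

    ## --- inputs: simulated or file-based -------------------------------
    quant <- NULL; motifs <- NULL; proteins <- NULL
    sim <- config$simulate
    if (!is.null(sim$nl)) {
        quantSim <- stage("simulate_nl", function() {
            a <- sim$nl
            simulateNlExperiment(
                nProteins = a$n_proteins %||% 500,
                fracSubstrates = a$frac_substrates %||% 0.1,
                accumulationFC = a$accumulation_fc %||% 2,
                noiseSd = a$noise_sd %||% 0.1,
                nDonors = a$n_donors %||% 5,
                missingness = a$missingness %||% 0,
                motifBackgroundRate = a$motif_background_rate %||% 0.45,
                seed = seed)
        })
        quant <- quantSim$quant
        motifs <- quantSim$motifs
        mat <- SummarizedExperiment::assay(quant)
        cd <- as.data.frame(SummarizedExperiment::colData(quant))
        addPath("quant", .writeTsv(
            data.frame(protein_id = rownames(mat), mat, check.names = FALSE),
            file.path(outDir, "quant.tsv")))
        addPath("samples", .writeTsv(
            data.frame(sample = rownames(cd), cd),
            file.path(outDir, "samples.tsv")))
        addPath("motifs", .writeTsv(
            data.frame(protein_id = names(motifs), has_motif = motifs),
            file.path(outDir, "motifs.tsv")))
        truthPath <- file.path(outDir, "truth.json")
        jsonlite::write_json(quantSim$truth, truthPath,
                             auto_unbox = TRUE, digits = NA)
        addPath("truth", truthPath)
    }
    if (!is.null(sim$proteome)) {
        protSim <- stage("simulate_proteome", function() {
            a <- sim$proteome
            simulateProteome(
                nProteins = a$n_proteins %||% 200,
                fracCanonical = a$frac_canonical %||% 0.1,
                fracPhospho = a$frac_phospho %||% 0.05,
                fracAcetyl = a$frac_acetyl %||% 0.05,
                seed = seed)
        })
        proteins <- protSim$proteins
        faPath <- file.path(outDir, "proteome.fasta")
        Biostrings::writeXStringSet(protSim$proteins, faPath)
        addPath("proteome", faPath)
        addPath("proteome_truth", .writeTsv(
            protSim$truth, file.path(outDir, "proteome_truth.tsv")))
    }
    if (is.null(quant) && !is.null(config$differential$quant)) {
        quant <- stage("read_quant", function() {
            qp <- config$differential$quant
            ap <- config$differential$annotation
            .stopIfNot(file.exists(qp %||% ""), "quant file not found")
            .stopIfNot(file.exists(ap %||% ""), "annotation file not found")
            addInput(qp); addInput(ap)
            .readQuantTsv(qp, ap, config$differential$scale %||% "log2")
        })
    }
    ## --- scan ----------------------------------------------------------
    if (!is.null(config$scan)) {
        scanned <- stage("scan", function() {
            fa <- config$scan$fasta %||% "simulated"
            seqs <- if (identical(fa, "simulated")) {
                .stopIfNot(!is.null(proteins),
                           "scan.fasta = 'simulated' requires simulate.proteome")
                proteins
            } else {
                .stopIfNot(file.exists(fa), "FASTA not found: ", fa)
                addInput(fa)
                readProteins(fa)
            }
            h <- scanProteins(seqs)
            hitsPath <- file.path(outDir, "motif_hits.tsv")
            writeMotifHits(h, hitsPath)
            addPath("motif_hits", hitsPath)
            summ <- summarizeMotifs(seqs,
                                    mode = config$scan$mode %||% "inclusive")
            summPath <- file.path(outDir, "motif_summary.json")
            jsonlite::write_json(
                list(nProteins = summ@nProteins, mode = summ@mode,
                     counts = as.list(motifCounts(summ)),
                     fractions = as.list(motifFractions(summ))),
                summPath, auto_unbox = TRUE, digits = NA)
            addPath("motif_summary", summPath)
            list(hits = h, ids = names(seqs))
        })
        if (is.null(motifs))
            motifs <- stats::setNames(
                scanned$ids %in% scanned$hits$proteinId, scanned$ids)
    }
    ## --- differential + substrate call ---------------------------------
    diffRes <- NULL; callSet <- NULL
    if (!is.null(quant)) {
        diffRes <- stage("differential", function() {
            d <- rowwiseTest(quant,
                             design = config$differential$design %||% "auto",
                             normalize = config$differential$normalize %||% TRUE)
            addPath("differential",
                    .writeTsv(d, file.path(outDir, "differential.tsv")))
            d
        })
        cs <- config$call_substrates
        callSet <- stage("call_substrates", function() {
            if (!is.null(cs$motifs)) {
                .stopIfNot(file.exists(cs$motifs),
                           "motif TSV not found: ", cs$motifs)
                addInput(cs$motifs)
                motifs <- .readMotifTsv(cs$motifs)
            }
            gate <- cs$motif_gate %||% TRUE
            .stopIfNot(!gate || !is.null(motifs),
                       "motif gate requires a motif annotation (simulate, scan or motifs TSV)")
            set <- callSubstrates(diffRes, motifs = motifs %||% character(),
                                  fcMin = cs$fc_min %||% 1.25,
                                  pMax = cs$p_max %||% 0.01,
                                  requireMotif = gate,
                                  label = cs$label %||% "")
            addPath("substrates", .writeTsv(
                data.frame(protein_id = substrateIds(set)),
                file.path(outDir, "substrates.tsv")))
            set
        })
    }
    ## --- over-representation -------------------------------------------
    if (!is.null(config$ora) && !is.null(callSet)) {
        stage("ora", function() {
            gp <- config$ora$gmt
            .stopIfNot(file.exists(gp %||% ""), "ora.gmt file not found")
            addInput(gp)
            bg <- diffRes$proteinId[diffRes$flag == "ok"]
            res <- ora(intersect(substrateIds(callSet), bg), bg, readGmt(gp))
            addPath("ora", .writeTsv(res, file.path(outDir, "ora.tsv")))
        })
    }
    ## --- manifest -------------------------------------------------------
    manifest <- list(
        package = "cmaflux",
        version = as.character(utils::packageVersion("cmaflux")),
        seed = seed,
        config = config,
        inputChecksums = as.list(stats::setNames(
            tools::md5sum(unique(state$inputs)),
            basename(unique(state$inputs)))),
        outputChecksums = as.list(stats::setNames(
            tools::md5sum(unname(state$paths)),
            basename(unname(state$paths)))))
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    invisible(list(manifest = manifest, manifestPath = manifestPath,
                   differential = diffRes, substrates = callSet,
                   paths = state$paths))
}
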