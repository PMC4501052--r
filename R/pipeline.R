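## End-to-end study orchestration: parse -> coverage -> normalize ->
## selected analyses -> reporting -> optional aggregation record.
## A study is persisted as a directory with tables/, figures/, a run log,
## a machine-readable parameter echo and a manifest, so a finished study
## can be revisited or re-bundled without re-uploading anything.

#' Run parameters for a full study
#'
#' @param arfFiles named character vector (sample id -> arf path), or a
#'   directory containing \code{<sample>.arf} files.
#' @param gffFile miRBase-dialect GFF3 annotation.
#' @param designFile two-column sample/class table.
#' @param outDir study output directory.
#' @param totalsFile two-column sample/total-reads table (required
#'   unless \code{normalizationMode = "none"}).
#' @param hairpinFasta optional hairpin FASTA (enables sequence pileups
#'   and window motifs).
#' @param matureFasta optional miRBase mature.fa (sequences are loaded
#'   and echoed; coordinates come from the GFF).
#' @param caseLabel,controlLabel class labels; default: label of the
#'   first design row is case.
#' @param normalizationMode "total_run", "genome_mapped" or "none".
#' @param organismPrefix annotation organism filter (default "hsa").
#' @param config a \code{\linkS4class{TestConfig}}.
#' @param analyses subset of c("expression", "mature", "ratio",
#'   "per_base", "window", "novel") to run.
#' @param storePath aggregation store path (used when
#'   \code{config@aggregate} is TRUE).
#' @param makeFigures draw per-precursor figures (TSV tables are always
#'   written).
#' @return validated parameter list ("RunParameters").
#' @export
runParameters <- function(arfFiles, gffFile, designFile, outDir,
                          totalsFile = NULL, hairpinFasta = NULL,
                          matureFasta = NULL, caseLabel = NULL,
                          controlLabel = NULL,
                          normalizationMode = c("total_run",
                                                "genome_mapped", "none"),
                          organismPrefix = "hsa",
                          config = testConfig(),
                          analyses = c("expression", "mature", "ratio",
                                       "per_base", "window", "novel"),
                          storePath = NULL, makeFigures = TRUE) {
    normalizationMode <- match.arg(normalizationMode)
    if (length(arfFiles) == 1L && dir.exists(arfFiles)) {
        paths <- sort(list.files(arfFiles, pattern = "\\.arf$",
                                 full.names = TRUE))
        arfFiles <- stats::setNames(paths, sub("\\.arf$", "",
                                               basename(paths)))
    }
    if (is.null(names(arfFiles)) || any(!nzchar(names(arfFiles))))
        stop("arfFiles must be named by sample id")
    missing <- c(arfFiles, gffFile, designFile)
    if (normalizationMode != "none") {
        if (is.null(totalsFile))
            stop("normalization mode '", normalizationMode,
                 "' requires a totals file")
        missing <- c(missing, totalsFile)
    }
    missing <- missing[!file.exists(missing)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
    analyses <- if (length(analyses))
        match.arg(analyses, several.ok = TRUE) else character(0)
    structure(list(arfFiles = arfFiles, gffFile = gffFile,
                   designFile = designFile, totalsFile = totalsFile,
                   hairpinFasta = hairpinFasta, matureFasta = matureFasta,
                   caseLabel = caseLabel, controlLabel = controlLabel,
                   normalizationMode = normalizationMode,
                   organismPrefix = organismPrefix, config = config,
                   analyses = analyses, outDir = outDir,
                   storePath = storePath, makeFigures = isTRUE(makeFigures)),
              class = "RunParameters")
}

#' Load study inputs into an RPM-normalized CoverageSet
#'
#' Parses the annotation, all arf files, design and totals, builds raw
#' coverage and normalizes it.
#'
#' @param params a \code{\link{runParameters}} list.
#' @return an RPM-normalized \code{\linkS4class{CoverageSet}}.
#' @export
loadStudy <- function(params) {
    annotation <- readMirbaseGff(params$gffFile, params$organismPrefix,
                                 hairpinFasta = params$hairpinFasta)
    design <- readDesign(params$designFile, params$caseLabel,
                         params$controlLabel)
    records <- lapply(params$arfFiles, readArf)
    cov <- buildCoverage(records, annotation, design)
    table <- if (params$normalizationMode == "none")
        normalizationTable(mode = "none")
    else
        readTotals(params$totalsFile, params$normalizationMode)
    normalizeRpm(cov, table)
}

#' Run a complete study
#'
#' Executes parsing, coverage building, RPM normalization, the selected
#' analyses, reporting (tables always; figures when requested) and the
#' optional aggregation record, in that order. Results land under
#' \code{params$outDir}: \code{tables/} (tab-delimited, sortable in any
#' spreadsheet tool), \code{figures/}, \code{coverage/}, a run log, a
#' machine-readable parameter echo (params.json) and \code{bundle.tar.gz}
#' with a manifest. A stage failure preserves partial results and names
#' the failed stage in the log and the error.
#'
#' @param params a \code{\link{runParameters}} list.
#' @return list with the study directory, the \code{CoverageSet} and all
#'   result tables, invisibly.
#' @export
runStudy <- function(params) {
    stopifnot(inherits(params, "RunParameters"))
    outDir <- params$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tabDir <- file.path(outDir, "tables")
    figDir <- file.path(outDir, "figures")
    dir.create(tabDir, showWarnings = FALSE)
    dir.create(figDir, showWarnings = FALSE)
    logFile <- file.path(outDir, "run.log")
    logLine <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                 ..., "\n", file = logFile, append = TRUE)
    stage <- function(name, expr) {
        logLine("stage", name, "start")
        res <- tryCatch(expr, error = function(e) {
            logLine("stage", name, "FAILED:", conditionMessage(e))
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        logLine("stage", name, "done")
        res
    }

    echo <- params[c("gffFile", "designFile", "totalsFile",
                     "normalizationMode", "organismPrefix", "analyses")]
    echo$arfFiles <- as.list(params$arfFiles)
    echo$config <- list(test = params$config@test,
                        alpha = params$config@alpha,
                        minSigPositions = params$config@minSigPositions,
                        windowSize = params$config@windowSize,
                        graphicsFormat = params$config@graphicsFormat,
                        aggregate = params$config@aggregate)
    paramsJson <- file.path(outDir, "params.json")
    jsonlite::write_json(echo, paramsJson, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)

    cov <- stage("load", loadStudy(params))
    stage("coverage_export", exportCoverage(cov, file.path(outDir,
                                                           "coverage")))
    cfg <- params$config
    fmt <- cfg@graphicsFormat
    results <- list(coverage = cov)

    if ("expression" %in% params$analyses) {
        results$expression <- stage("expression",
                                    precursorExpression(cov, cfg))
        writeTsv(as.data.frame(results$expression),
                 file.path(tabDir, "precursor_expression.tsv"))
        if (params$makeFigures)
            plotManhattan(results$expression, cov@annotation,
                          file.path(figDir, paste0("manhattan_expression.",
                                                   fmt)),
                          fmt, main = "Precursor expression")
    }
    if (any(c("mature", "ratio") %in% params$analyses)) {
        results$mature <- stage("mature", matureExpression(cov, cfg))
        writeTsv(as.data.frame(results$mature),
                 file.path(tabDir, "mature_expression.tsv"))
        if (params$makeFigures)
            plotManhattan(results$mature, cov@annotation,
                          file.path(figDir, paste0("manhattan_mature.",
                                                   fmt)),
                          fmt, main = "Mature arm expression")
    }
    if ("ratio" %in% params$analyses) {
        results$ratio <- stage("ratio", armRatio(results$mature))
        writeTsv(as.data.frame(results$ratio),
                 file.path(tabDir, "arm_ratio.tsv"))
    }
    if ("per_base" %in% params$analyses) {
        results$perBase <- stage("per_base", perBaseExpression(cov, cfg))
        long <- do.call(rbind, lapply(names(results$perBase$positions),
            function(id) {
                df <- as.data.frame(results$perBase$positions[[id]])
                cbind(precursor_id = id, df)
            }))
        writeTsv(long, file.path(tabDir, "per_base_long.tsv"))
        writeTsv(as.data.frame(results$perBase$summary),
                 file.path(tabDir, "per_base_summary.tsv"))
        writeTsv(as.data.frame(results$perBase$arms),
                 file.path(tabDir, "per_base_arms.tsv"))
    }
    if ("window" %in% params$analyses) {
        results$windows <- stage("window", windowAnalysis(cov, cfg))
        writeTsv(as.data.frame(results$windows),
                 file.path(tabDir, "window_analysis.tsv"))
    }
    if ("novel" %in% params$analyses) {
        results$novelArms <- stage("novel", novelArmScan(cov, cfg))
        writeTsv(as.data.frame(results$novelArms),
                 file.path(tabDir, "novel_arms.tsv"))
    }
    if (params$makeFigures)
        stage("figures", {
            design <- cov@design
            for (id in names(cov)) {
                pc <- cov[[id]]
                if (!any(pc@raw > 0)) next
                if (!is.null(results$perBase))
                    plotPerBaseBars(results$perBase$positions[[id]],
                                    file.path(figDir,
                                              paste0("perbase_", id, ".",
                                                     fmt)),
                                    fmt, main = paste("Per-base", id))
                plotReadDistribution(pc, design,
                                     file.path(figDir,
                                               paste0("readdist_", id, ".",
                                                      fmt)),
                                     fmt, main = paste("Coverage", id))
                plotPileup(pc, cov@annotation, design,
                           file.path(figDir, paste0("pileup_", id, ".",
                                                    fmt)),
                           fmt)
            }
        })

    if (cfg@aggregate && !is.null(params$storePath))
        stage("aggregation", {
            findings <- collectFindings(
                results$expression %||% emptyExpressionDF(),
                results$mature %||% emptyExpressionDF(),
                results$novelArms %||% novelArmScan(cov, cfg),
                results$windows, cov, cfg)
            store <- openStore(params$storePath)
            store <- recordStudy(store, studyHash(paramsJson), findings)
            freq <- do.call(rbind, lapply(
                unique(findings$mirna_key[findings$significant]),
                function(k) {
                    ft <- findings$finding_type[findings$mirna_key == k &
                                                findings$significant][1L]
                    q <- queryFrequency(store, k, ft)
                    data.frame(mirna_key = k, finding_type = ft,
                               n_experiments = q$n_experiments,
                               n_with_finding = q$n_with_finding)
                }))
            if (!is.null(freq))
                writeTsv(freq, file.path(tabDir,
                                         "aggregation_frequency.tsv"))
        })

    stage("bundle", exportBundle(outDir))
    logLine("study complete")
    invisible(c(list(outDir = outDir), results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

emptyExpressionDF <- function() {
    DataFrame(feature_id = character(0), mean_case = numeric(0),
              mean_control = numeric(0), fold_change = numeric(0),
              p_value = numeric(0), p_adj = numeric(0),
              degenerate = logical(0))
}

#' Read run parameters from a YAML config file
#'
#' Field names mirror the \code{\link{runParameters}} arguments; the
#' \code{config} block mirrors \code{\link{testConfig}} arguments.
#' Relative paths are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return a \code{\link{runParameters}} list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    resolve <- function(p) {
        if (is.null(p)) return(NULL)
        out <- ifelse(grepl("^/", p), p, file.path(base, p))
        stats::setNames(out, names(p))
    }
    cfgArgs <- y$config %||% list()
    cfg <- do.call(testConfig, cfgArgs)
    runParameters(arfFiles = resolve(unlist(y$arfFiles) %||% y$arfDir),
                  gffFile = resolve(y$gffFile),
                  designFile = resolve(y$designFile),
                  outDir = resolve(y$outDir),
                  totalsFile = resolve(y$totalsFile),
                  hairpinFasta = resolve(y$hairpinFasta),
                  matureFasta = resolve(y$matureFasta),
                  caseLabel = y$caseLabel, controlLabel = y$controlLabel,
                  normalizationMode = y$normalizationMode %||% "total_run",
                  organismPrefix = y$organismPrefix %||% "hsa",
                  config = cfg,
                  analyses = y$analyses %||% c("expression", "mature",
                                               "ratio", "per_base",
                                               "window", "novel"),
                  storePath = resolve(y$storePath),
                  makeFigures = y$makeFigures %||% TRUE)
}
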