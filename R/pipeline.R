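## Pipeline orchestration: simulate or load -> curate -> profile/analyze ->
## write tables. The configuration is a plain list (or YAML file) that is
## echoed into the output directory for provenance.

#' Run the full analysis pipeline
#'
#' Stages run in fixed order: (1) obtain records, either by loading the
#' input files named in \code{config$input} or by simulating from
#' \code{config$simulate}; (2) curation (unless
#' \code{config$curation$enabled} is FALSE), with any threshold of
#' [curationParams()] overridable under \code{config$curation}; (3) per-cell
#' and cross-taxon analysis ([analyzeDataset()]); (4) result tables written
#' to \code{config$outDir} together with a YAML echo of the configuration.
#' A failure in one cell's analysis marks the cell failed in the summary and
#' does not abort the others.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized fields: \code{input} (cdsFasta, coverageTsv, taxonMapTsv,
#'   utrTable, alignmentsDir), \code{simulate} (arguments of
#'   [simulationConfig()]: taxa as lists of [taxonConfig()] arguments,
#'   contamination), \code{curation} (enabled + threshold overrides),
#'   \code{analysis} (minEncCodons, ssduMinGroupCount), \code{outDir},
#'   \code{seed}.
#' @return Invisibly, a list with \code{records}, \code{curation},
#'   \code{analysis}, \code{summary} (per-cell status data.frame) and
#'   \code{outDir}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$outDir)) stop("config$outDir is required")
  if (is.null(config$input) && is.null(config$simulate))
    stop("config must provide either input paths or a simulate block")
  code <- standardGeneticCode()
  if (!is.null(config$seed)) set.seed(config$seed)

  alignments <- list()
  if (!is.null(config$input)) {
    inp <- config$input
    loaded <- loadDataset(inp$cdsFasta, coverageTsv = inp$coverageTsv,
                          taxonMapTsv = inp$taxonMapTsv,
                          utrTable = inp$utrTable,
                          alignmentsDir = inp$alignmentsDir)
    records <- loaded$records
    alignments <- loaded$alignments
    loadLog <- loaded$log
  } else {
    simArgs <- config$simulate
    taxa <- if (!is.null(simArgs$taxa))
      lapply(simArgs$taxa, function(a) do.call(taxonConfig, a))
    else defaultPanel()
    sim <- simulateTranscriptome(
      simulationConfig(taxa = taxa,
                       contamination = simArgs$contamination %||% list()))
    records <- sim$records
    loadLog <- data.frame(transcriptId = character(0), event = character(0),
                          detail = character(0))
  }

  curEnabled <- is.null(config$curation$enabled) ||
    isTRUE(config$curation$enabled)
  if (curEnabled) {
    overrides <- config$curation[setdiff(names(config$curation), "enabled")]
    params <- do.call(curationParams, overrides %||% list())
    cur <- curateTranscripts(records, alignments, code, params)
  } else {
    cur <- list(records = records, decisions = .emptyDecisions(),
                utrEligibility = curateUtrs(records, alignments))
  }

  aArgs <- config$analysis %||% list()
  analysis <- analyzeDataset(cur$records, code,
                             utrEligibility = cur$utrEligibility,
                             minEncCodons = aArgs$minEncCodons %||% 100L,
                             ssduMinGroupCount =
                               aArgs$ssduMinGroupCount %||% 10L)

  cellsIn <- unique(cellIds(records))
  summary <- data.frame(
    cellId = cellsIn,
    nInput = as.integer(table(cellIds(records))[cellsIn]),
    nSurviving = as.integer(table(cellIds(cur$records))[cellsIn]),
    status = ifelse(cellsIn %in% names(analysis$failedCells), "failed", "ok"))
  summary$nSurviving[is.na(summary$nSurviving)] <- 0L

  tables <- analysis[c("composition", "compositionByTaxon",
                       "codonFrequencies", "rscu", "enc", "aaUsage",
                       "stopUsage", "ssdu", "regressions", "neutrality",
                       "crossTaxonAa")]
  tables$curation_log <- cur$decisions
  tables$load_log <- loadLog
  tables$pipeline_summary <- summary
  tables <- Filter(Negate(is.null), tables)
  writeResultTables(tables, config$outDir)
  yaml::write_yaml(.serializableConfig(config),
                   file.path(config$outDir, "config_echo.yaml"))

  invisible(list(records = cur$records, curation = cur,
                 analysis = analysis, summary = summary,
                 outDir = config$outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## internal: drop non-serializable entries (functions, environments)
.serializableConfig <- function(x) {
  if (is.list(x)) lapply(x, .serializableConfig)
  else if (is.function(x) || is.environment(x)) NULL
  else x
}
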