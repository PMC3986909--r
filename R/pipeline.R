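#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' grouping LOD 7.0, male-group merge LOD 4.0, segregation-distortion
#' P 0.001, completeness NULL (the at-least-95%-typed rule, 88 of 92),
#' anchoring E-value 1e-20 and bit-score ratio 2.0, error-LOD mask
#' threshold 2.0 with prior error 0.01, syntenic-box thresholds 6 and
#' 16, and the unlinked-rf cap 0.4999.
#'
#' @param lodGroup,lodMerge,distortionP,minTyped,evalueMax,bitscoreRatio
#'   see description.
#' @param errorLodMax,epsilon,tBox,tHigh,rfMax,exhaustiveMax,seed see
#'   description.
#' @return a named list of class "PipelineConfig".
#' @export
pipelineConfig <- function(lodGroup = 7, lodMerge = 4,
                           distortionP = 0.001, minTyped = NULL,
                           evalueMax = 1e-20, bitscoreRatio = 2,
                           errorLodMax = 2, epsilon = 0.01, tBox = 6,
                           tHigh = 16, rfMax = 0.4999,
                           exhaustiveMax = 8, seed = 1L) {
  stopifnot(lodGroup > 0, lodMerge > 0, distortionP > 0,
            distortionP < 1, evalueMax > 0, bitscoreRatio > 0,
            errorLodMax > 0, epsilon > 0, epsilon < 1, tBox >= 1,
            tHigh >= tBox, rfMax > 0, rfMax < 0.5)
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Stages run in order: genotype QC (recode, completeness,
#' distortion, sex split), sex-specific map construction with error-LOD
#' correction and sex-map pairing, map summary (Chakravarti correction,
#' coverage), scaffold anchoring and ordering (if a hit table is given)
#' and Oxford-grid synteny (if a segment table is given).  Later stages
#' are skipped when their inputs are absent; a requested stage with a
#' missing input fails before any work.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} (or path to a
#'   genotype CSV).
#' @param hits optional hit data.frame or path (anchoring stage).
#' @param scaffoldLengths data.frame (scaffold_id, length_bp), required
#'   with \code{hits}.
#' @param segments optional segment data.frame or path (synteny stage).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, stage outputs are
#'   written as headers-plus-TSV files.
#' @return list: \code{qc} (report + funnel), \code{femaleMap},
#'   \code{maleMap}, \code{pairing}, \code{femaleSummary},
#'   \code{maleSummary}, \code{anchoring} (assignments, anchored,
#'   orders, conflicts) or NULL, \code{synteny} (grid, boxes) or NULL,
#'   and \code{log}, one line per stage with record counts.
#' @export
runPipeline <- function(genotypes, hits = NULL, scaffoldLengths = NULL,
                        segments = NULL, config = pipelineConfig(),
                        outDir = NULL) {
  if (is.character(genotypes)) genotypes <- readGenotypesCSV(genotypes)
  if (is.character(hits)) hits <- readHitTable(hits)
  if (is.character(segments)) segments <- readSegmentTable(segments)
  if (!is.null(hits) && is.null(scaffoldLengths))
    stop("anchoring stage requested but scaffoldLengths is missing")
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  qc <- applyGenotypeQC(genotypes, config$minTyped, config$distortionP)
  note("qc: ", qc$funnel["input"], " markers in, ",
       qc$funnel["after_distortion"], " retained (",
       nMarkers(qc$dam), " dam, ", nMarkers(qc$sire), " sire)")

  buildOne <- function(gmx, sex)
    buildSexMap(gmx, sex = sex, minTyped = config$minTyped,
                lodGroup = config$lodGroup, epsilon = config$epsilon,
                errorLodMax = config$errorLodMax, rfMax = config$rfMax,
                exhaustiveMax = config$exhaustiveMax)
  fem <- buildOne(qc$dam, "female")
  mal <- buildOne(qc$sire, "male")
  pairing <- pairSexMaps(fem$map, mal$map, markerInfo(genotypes),
                         maleLinkage = mal$linkage,
                         mergeLod = config$lodMerge)
  if (length(pairing$merges)) {
    mal$map <- assembleMap(mal$genotypes, mal$linkage,
                           pairing$maleGroups, sex = "male",
                           rfMax = config$rfMax,
                           exhaustiveMax = config$exhaustiveMax)
    note("map: merged ", length(pairing$merges),
         " split male group(s)")
  }
  femSummary <- mapSummary(fem$map, fem$linkage)
  malSummary <- mapSummary(mal$map, mal$linkage)
  note("map: female ", length(groupLengths(fem$map)), " groups / ",
       sprintf("%.1f cM", femSummary$totals$observed_cM),
       "; male ", length(groupLengths(mal$map)), " groups / ",
       sprintf("%.1f cM", malSummary$totals$observed_cM))

  anchoring <- NULL
  if (!is.null(hits)) {
    assignments <- assignMarkers(hits, config$evalueMax,
                                 config$bitscoreRatio)
    anchored <- anchorScaffolds(assignments, fem$map, mal$map,
                                scaffoldLengths)
    orders <- orderScaffolds(anchored)
    conflicts <- detectConflicts(assignments,
                                 list(fem$map, mal$map))
    anchoring <- list(assignments = assignments, anchored = anchored,
                      orders = orders, conflicts = conflicts)
    note("anchor: ", sum(assignments$status == "assigned"),
         " markers assigned, ", nrow(anchored), " scaffolds anchored, ",
         sum(orders$status == "ordered", na.rm = TRUE), " ordered")
  }

  synteny <- NULL
  if (!is.null(segments)) {
    grid <- buildGrid(segments)
    boxes <- classifyBoxes(grid, config$tBox, config$tHigh)
    synteny <- list(grid = grid, boxes = boxes)
    note("synteny: ", boxes$total, " segments gridded, ",
         boxes$in_box, " (", boxes$in_box_pct, "%) in ",
         boxes$n_boxes, " boxes")
  }

  out <- list(qc = qc[c("report", "funnel")], femaleMap = fem$map,
              maleMap = mal$map, pairing = pairing,
              femaleSummary = femSummary, maleSummary = malSummary,
              anchoring = anchoring, synteny = synteny, log = log)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    writeTSV(qc$report, file.path(outDir, "qc_report.tsv"), seed)
    writeMapTSV(fem$map, file.path(outDir, "map_female.tsv"), seed)
    writeMapTSV(mal$map, file.path(outDir, "map_male.tsv"), seed)
    if (!is.null(anchoring))
      writeScaffoldOrder(anchoring$orders,
                         file.path(outDir, "scaffold_order.tsv"), seed)
    if (!is.null(synteny))
      writeGridTSV(synteny$grid, file.path(outDir, "oxford_grid.tsv"),
                   seed)
    writeLines(c(provenanceHeader(seed), log),
               file.path(outDir, "pipeline_log.txt"))
  }
  out
}

#' Published per-linkage-group map summary bundled with the package
#'
#' The per-linkage-group summary table of the Japanese eel ddRAD
#' linkage map: marker counts, female and male genetic lengths and
#' anchored-scaffold counts/sizes for the 19 linkage groups.  Used as
#' the reference input for map-summary arithmetic (totals, means,
#' Chakravarti correction, coverage).
#'
#' @return data.frame with columns linkage_group, total_markers,
#'   female_markers, female_length_cM, male_markers, male_length_cM,
#'   anchored_scaffolds, anchored_bp.
#' @export
eelLinkageSummary <- function() {
  path <- system.file("extdata", "eel_linkage_groups.tsv",
                      package = "ddRADmap", mustWork = TRUE)
  readTSVBody(path)
}
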