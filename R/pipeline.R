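## End-to-end orchestration: simulate -> call -> design -> genotype -> map ->
## anchor, with every stage result written as machine-readable TSV and a
## plain-text report reproducing the class-summary and group-summary layouts.

PIPELINE_KEYS <- c("lodThreshold", "maxRf", "kbPerCm", "minSupport",
                   "maxGap", "minLen", "maxLen", "flank", "absMin", "relMin",
                   "nScreeningMarkers", "writeFasta", "writePairs")

#' Read a pipeline run configuration file
#'
#' YAML with two blocks: \code{simulate} (fields of [simConfig()]) and
#' \code{pipeline} (any of \code{lodThreshold}, \code{maxRf}, \code{kbPerCm},
#' \code{minSupport}, \code{maxGap}, \code{minLen}, \code{maxLen},
#' \code{flank}, \code{absMin}, \code{relMin}, \code{nScreeningMarkers},
#' \code{writeFasta}, \code{writePairs}). Unknown keys are rejected.
#'
#' @param path YAML config path.
#' @return list with \code{config} (a \linkS4class{SimConfig}) and
#'   \code{params} (named list of pipeline options).
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("simulate", "pipeline"))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  simArgs <- y$simulate
  known <- names(formals(simConfig))
  bad <- setdiff(names(simArgs), known)
  if (length(bad)) stop("unknown simulate key(s): ", paste(bad, collapse = ", "))
  params <- y$pipeline
  bad <- setdiff(names(params), PIPELINE_KEYS)
  if (length(bad)) stop("unknown pipeline key(s): ", paste(bad, collapse = ", "))
  list(config = do.call(simConfig, simArgs),
       params = if (is.null(params)) list() else params)
}

#' Run the full SV-marker mapping pipeline on simulated data
#'
#' Simulates the parental genome pair and read layer, calls SV loci from the
#' discordant pairs, designs co-dominant markers, simulates the single-spore
#' mapping population over the true marker positions (1 cM per
#' \code{kbPerCm} kb of scaffold), filters out heterokaryons, builds the
#' linkage map and anchors the scaffolds. Every stage output is written to
#' \code{outDir} as TSV/FASTA and a deterministic plain-text report is
#' produced (same config + seed gives byte-identical output).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outDir output directory.
#' @param lodThreshold LOD grouping threshold (default 3.0).
#' @param maxRf recombination-fraction co-requirement used for grouping
#'   (default 0.3: with populations of ~200 meioses and hundreds of marker
#'   pairs, a pure LOD-3 rule sporadically links independent chromosomes;
#'   see the methods vignette).
#' @param kbPerCm physical-to-genetic scale used to place the true marker
#'   positions of the simulated meiosis (default 47.7 kb/cM).
#' @param minSupport,maxGap SV caller parameters, see [callSVs()].
#' @param minLen,maxLen,flank,absMin,relMin marker design parameters, see
#'   [designMarkers()] and [scoreCodominance()].
#' @param nScreeningMarkers number of markers used for heterokaryon
#'   screening (default 3).
#' @param writeFasta,writePairs whether to write the genome FASTAs and the
#'   full pair table (defaults TRUE and FALSE; the pair table can be large).
#' @return list of all stage results, invisibly: \code{sim}, \code{model},
#'   \code{calls}, \code{markers}, \code{genotypes}, \code{population},
#'   \code{map}, \code{anchoring}, \code{stats}, \code{conflicts},
#'   \code{scan}.
#' @export
runPipeline <- function(config, outDir,
                        lodThreshold = 3.0, maxRf = 0.3, kbPerCm = 47.7,
                        minSupport = 6L, maxGap = 100L,
                        minLen = 200L, maxLen = 800L, flank = 300L,
                        absMin = 20, relMin = 0.05,
                        nScreeningMarkers = 3L,
                        writeFasta = TRUE, writePairs = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log_ <- c(sprintf("svmap pipeline run"),
            sprintf("seed: %d", config@seed),
            sprintf("params: lod=%g maxRf=%g kbPerCm=%g minSupport=%d maxGap=%d",
                    lodThreshold, maxRf, kbPerCm, minSupport, maxGap),
            sprintf("marker design: len [%d,%d], flank %d, absMin %g, relMin %g",
                    minLen, maxLen, flank, absMin, relMin))

  sim <- simulateParentalGenomes(config)
  if (writeFasta) writeGenomesFasta(sim, outDir)
  writeVariantsTsv(sim$variants, file.path(outDir, "truth_variants.tsv"))
  pairs <- simulateReadPairs(sim, config)
  if (writePairs) writePairsTsv(pairs, file.path(outDir, "pairs.tsv"))

  model <- tryCatch(fitInsertModel(pairs),
                    error = function(e) list(mean = config@insertMean,
                                             sd = config@insertSd, k = 3))
  calls <- callSVs(pairs, model, minSupport = minSupport, maxGap = maxGap)
  writeCallsBed(calls, file.path(outDir, "sv_calls.tsv"))
  sumTab <- summarizeCalls(calls)
  write.table(sumTab, file.path(outDir, "sv_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  markers <- designMarkers(calls, sim$reference, sim$donor, sim$segments,
                           minLen = minLen, maxLen = maxLen, flank = flank,
                           absMin = absMin, relMin = relMin)
  write.table(markers, file.path(outDir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeMarkerFlanksFasta(markers, sim$reference,
                         file.path(outDir, "marker_flanks.fasta"))
  eff <- effectiveMarkers(markers)

  report <- c(log_, "", "== SV class summary ==",
              utils::capture.output(print(sumTab, row.names = FALSE)),
              sprintf("scaffolds with >= 1 locus: %d",
                      attr(sumTab, "nScaffolds")),
              "",
              sprintf("markers: %d loci -> %d effective (%.1f%%)",
                      nrow(markers), nrow(eff),
                      if (nrow(markers)) 100 * nrow(eff) / nrow(markers)
                      else 0))

  result <- list(sim = sim, model = model, calls = calls, markers = markers)
  if (nrow(eff) < 2L * max(1L, nScreeningMarkers)) {
    report <- c(report, "", "too few effective markers; mapping stages skipped")
    writeLines(report, file.path(outDir, "report.txt"))
    return(invisible(result))
  }

  ## true genetic positions: each scaffold is a chromosome, 1 cM per kbPerCm
  mid <- (eff$start + eff$end) / 2
  scIdx <- match(eff$scaffold, names(sim$reference))
  trueMap <- GeneticMap(data.frame(group = scIdx, marker = eff$id,
                                   position = mid / (kbPerCm * 1e3),
                                   stringsAsFactors = FALSE))
  gt <- simulateMeiosis(trueMap, config@nProgeny,
                        heterokaryonRate = config@heterokaryonRate,
                        missingRate = config@missingRate,
                        seed = config@seed + 2L)
  writeGenotypeMatrix(gt, file.path(outDir, "genotypes.tsv"))

  screen <- head(markerNames(gt), nScreeningMarkers)
  cls <- classifyStrains(gt, screen)
  pop <- suppressWarnings(filterPopulation(gt, screen))
  writeGenotypeMatrix(pop, file.path(outDir, "genotypes_homokaryon.tsv"))
  writeMapmakerRaw(pop, file.path(outDir, "genotypes.raw"))
  report <- c(report, "",
              sprintf("population: %d strains -> %d homokaryons (%d heterokaryons, %d undetermined)",
                      nrow(scores(gt)), length(cls$homokaryons),
                      length(cls$heterokaryons), length(cls$undetermined)))

  map <- buildMap(pop, lodThreshold = lodThreshold, maxRf = maxRf)
  write.table(mapTable(map), file.path(outDir, "map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ms <- mapSummary(map)
  write.table(ms$perGroup, file.path(outDir, "map_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  markerInfo <- data.frame(marker = eff$id, scaffold = eff$scaffold,
                           bp = mid, stringsAsFactors = FALSE)
  scafLens <- setNames(Biostrings::width(sim$reference),
                       names(sim$reference))
  anchoring <- anchorScaffolds(map, markerInfo, scafLens)
  write.table(anchoring$anchors, file.path(outDir, "anchors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeSuperScaffolds(anchoring, map, markerInfo,
                      file.path(outDir, "super_scaffolds.tsv"))
  stats <- genomeStatsFromMap(map, anchoring, sum(scafLens),
                              length(scafLens))
  conflicts <- detectConflicts(map, markerInfo)
  scan <- recombinationScan(map, markerInfo,
                            meanCmPerKb = stats$mapLengthCm /
                              stats$anchoredKb)
  write.table(scan, file.path(outDir, "recombination_scan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  report <- c(report, "", "== Linkage group summary ==",
              utils::capture.output(print(ms$perGroup, row.names = FALSE)),
              sprintf("total: %.3f cM, %d markers, mean spacing %.3f cM, %d unlinked",
                      ms$totalLengthCm, ms$totalMarkers, ms$meanSpacingCm,
                      length(unlinkedMarkers(map))),
              "", "== Anchoring ==",
              sprintf("%d scaffolds anchored to %d groups (%.0f kb, %.1f%% of genome)",
                      stats$nAnchored, nrow(anchoring$perGroup),
                      stats$anchoredKb, stats$coveragePct),
              sprintf("scaffold count %d -> %d; %.1f kb/cM",
                      length(scafLens), stats$reducedScaffolds,
                      stats$kbPerCm),
              sprintf("interleaving conflicts: %d; hot intervals: %d; cold intervals: %d",
                      nrow(conflicts), sum(scan$label == "hot"),
                      sum(scan$label == "cold")))
  writeLines(report, file.path(outDir, "report.txt"))

  invisible(c(result, list(genotypes = gt, population = pop, map = map,
                           anchoring = anchoring, stats = stats,
                           conflicts = conflicts, scan = scan)))
}
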