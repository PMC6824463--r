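stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end replication-stress pipeline
#'
#' Orchestrates simulation (or reading) of G1/S coverage, copy-number
#' profiling, peak and fired-origin calling, interorigin distances, peak
#' widths, and -- when damage tracks are available -- control and
#' replication normalization, origin-centred metaprofiles, gene-pair
#' orientation contexts and T_rep-binned damage enrichment. All results are
#' written as TSV/bedGraph into \code{outdir} together with a JSON run
#' manifest (config snapshot, seed, input/output digests). Outputs are
#' byte-identical for identical config and seed.
#'
#' In simulate mode the S and G1 tracks are depth-matched by construction,
#' so the copy-number normalization defaults to \code{"none"}; with real
#' inputs it defaults to the config value (modal anchoring).
#'
#' @param outdir output directory (created if needed).
#' @param config an \code{\link{analysisConfig}}.
#' @param seed integer seed covering every stochastic stage.
#' @param inputs NULL (simulate) or a named list of file paths: g1, s,
#'   origins, and optionally genes, ip, control.
#' @param genomeConfig simulate mode: passed to \code{\link{buildGenome}}.
#' @param condition simulate mode: a \linkS4class{SimulationCondition}.
#' @param nCells,depth simulate mode: population size and mean reads/bin.
#' @param truth simulate mode: \code{\link{damageTruth}} for the damage
#'   tracks (NULL skips the damage stage).
#' @param normalize copy-number normalization override (NULL = default
#'   behaviour described above).
#' @return invisibly, a list with the in-memory results and \code{outdir}.
#' @export
runPipeline <- function(outdir, config = analysisConfig(), seed = 1L,
                        inputs = NULL, genomeConfig = list(),
                        condition = simulationCondition("HU"),
                        nCells = 500, depth = 30,
                        truth = damageTruth(), normalize = NULL) {
  validateConfig(config)
  simulate <- is.null(inputs)
  if (!simulate) {
    need <- c("g1", "s", "origins")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("inputs must name files: ", paste(miss, collapse = ", "))
    for (nm in names(inputs))
      if (!file.exists(inputs[[nm]]))
        stop("input '", nm, "': no such file '", inputs[[nm]], "'")
  }
  if (is.null(normalize))
    normalize <- if (simulate) "none" else config$normalize
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (simulate) {
    genome <- stage("simulate", {
      gc <- utils::modifyList(list(binSize = config$binSize, seed = seed),
                              genomeConfig)
      buildGenome(gc)
    })
    state <- stage("simulate",
      simulateCellPopulation(genome, condition, nCells, seed = seed))
    reads <- stage("simulate", sampleReads(state, depth, seed = seed + 1L))
    g1 <- reads$g1
    s <- reads$s
    originTab <- origins(genome)
    geneTab <- genes(genome)
  } else {
    originTab <- stage("read", readOrigins(inputs$origins))
    geneTab <- if (!is.null(inputs$genes))
      stage("read", readGenes(inputs$genes)) else NULL
    g1 <- stage("read", readTrack(inputs$g1, binSize = config$binSize,
                                  label = "G1 coverage"))
    s <- stage("read", readTrack(inputs$s, binSize = config$binSize,
                                 seqlengths = seqLengths(g1),
                                 label = "S coverage"))
  }

  profile <- stage("profile",
    replicationProfile(s, g1, minG1 = config$minG1, normalize = normalize,
                       cutoffWavelength = config$fourierCutoff))
  peaks <- stage("peaks", callPeaks(profile, config$persistenceBp))
  widths <- stage("peaks", peakWidths(profile, peaks))
  calls <- stage("fired origins",
    callFiredOrigins(profile, originTab,
                     firedThreshold = config$firedThreshold,
                     matchTol = config$matchTol, peaks = peaks))
  dists <- stage("fired origins", interoriginDistances(calls))

  damage <- NULL
  if (simulate && !is.null(truth)) {
    dm <- stage("damage",
      simulateDamageTracks(state, genome, truth, seed = seed + 2L,
                           window = config$damageWindow))
    ip <- dm$ip
    control <- dm$control
  } else if (!simulate && !is.null(inputs$ip) && !is.null(inputs$control)) {
    ip <- stage("read", readTrack(inputs$ip, binSize = config$binSize,
                                  seqlengths = seqLengths(g1),
                                  label = "damage IP"))
    control <- stage("read",
      readTrack(inputs$control, binSize = config$binSize,
                seqlengths = seqLengths(g1), label = "control IP"))
  } else {
    ip <- NULL
  }
  if (!is.null(ip) && !is.null(geneTab) && nrow(geneTab)) {
    damage <- stage("damage", {
      ratio <- normalizeChip(ip, control)
      normd <- normalizeByReplication(ratio, profile,
                                      config$minReplication)
      meta <- metaOriginProfile(ratio, originTab,
                                halfWindow = 10L * config$binSize,
                                trepCutoff = config$trepCutoff)
      ctx <- classifyOriginGeneContext(originTab, geneTab)
      tab <- suppressWarnings(
        binnedDamageByTrep(normd, ctx, window = config$damageWindow))
      list(ratio = ratio, normalized = normd, meta = meta, contexts = ctx,
           table = tab)
    })
  }

  stage("write", {
    writeTrack(profile@rawRatio, file.path(outdir, "copy_number.bedgraph"))
    writeTrack(profile@smoothed, file.path(outdir, "smoothed.bedgraph"))
    writeTsv(widths, file.path(outdir, "peaks.tsv"))
    writeTsv(calls, file.path(outdir, "fired_origins.tsv"))
    writeTsv(dists, file.path(outdir, "interorigin_distances.tsv"))
    writeOrigins(originTab, file.path(outdir, "origins.tsv"))
    if (!is.null(damage)) {
      writeTsv(damage$meta, file.path(outdir, "metaprofile.tsv"))
      writeTsv(damage$contexts, file.path(outdir, "origin_contexts.tsv"))
      writeTsv(damage$table, file.path(outdir, "damage_by_trep.tsv"))
    }
  })

  manifest <- list(
    package = "RepliFire",
    version = as.character(utils::packageVersion("RepliFire")),
    seed = seed,
    mode = if (simulate) "simulate" else "inputs",
    normalize = normalize,
    config = unclass(config),
    inputs = if (simulate) NULL else
      lapply(inputs, function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))),
    outputs = {
      fs <- sort(setdiff(list.files(outdir), "manifest.json"))
      stats::setNames(lapply(fs, function(f)
        unname(tools::md5sum(file.path(outdir, f)))), fs)
    })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(outdir = outdir, profile = profile, peaks = widths,
                 calls = calls, distances = dists, damage = damage,
                 manifest = manifest))
}
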