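#' Analysis configuration
#'
#' One object holding every tunable analysis constant, with the defaults
#' used throughout: 1-kb bins, 20-kb Fourier cutoff, 3-kb peak persistence,
#' fired threshold 0.20 (fired in at least 20% of cells), T_rep early/late
#' cutoff 27.5 min, 5-kb origin-to-peak match tolerance, 2-kb damage
#' aggregation window, QFA top fraction 0.25 and q < 0.05.
#'
#' @param binSize bp.
#' @param fourierCutoff bp (>= 2 * binSize).
#' @param persistenceBp bp (> 0).
#' @param firedThreshold fraction in (0, 1].
#' @param trepCutoff minutes (> 0).
#' @param matchTol bp (>= 0).
#' @param damageWindow bp (> 0).
#' @param minG1 minimum G1 count per bin (>= 1).
#' @param minReplication replication floor (> 0).
#' @param normalize copy-number normalization mode (see
#'   \code{\link{computeCopyNumber}}).
#' @param topFraction QFA effect-size fraction in (0, 1].
#' @param qMax BH threshold in (0, 1].
#' @return list of class \code{analysis_config}.
#' @examples
#' cfg <- analysisConfig(fourierCutoff = 25000)
#' @export
analysisConfig <- function(binSize = 1000L, fourierCutoff = 20000,
                           persistenceBp = 3000, firedThreshold = 0.2,
                           trepCutoff = 27.5, matchTol = 5000,
                           damageWindow = 2000, minG1 = 1,
                           minReplication = 0.05,
                           normalize = c("mode", "total", "none"),
                           topFraction = 0.25, qMax = 0.05) {
  cfg <- list(binSize = as.integer(binSize), fourierCutoff = fourierCutoff,
              persistenceBp = persistenceBp,
              firedThreshold = firedThreshold, trepCutoff = trepCutoff,
              matchTol = matchTol, damageWindow = damageWindow,
              minG1 = minG1, minReplication = minReplication,
              normalize = match.arg(normalize),
              topFraction = topFraction, qMax = qMax)
  validateConfig(cfg)
  structure(cfg, class = "analysis_config")
}

validateConfig <- function(cfg) {
  with(cfg, {
    stopifnot(binSize >= 1, fourierCutoff >= 2 * binSize,
              persistenceBp > 0,
              firedThreshold > 0, firedThreshold <= 1,
              trepCutoff > 0, matchTol >= 0, damageWindow > 0,
              minG1 >= 1, minReplication > 0,
              topFraction > 0, topFraction <= 1, qMax > 0, qMax <= 1)
  })
  invisible(cfg)
}

#' Read / write an analysis configuration as YAML
#'
#' Unknown keys are rejected; missing keys take their defaults. The
#' round trip \code{readAnalysisConfig(writeAnalysisConfig(cfg))} is
#' stable.
#'
#' @param path YAML file path.
#' @return an \code{analysis_config} list.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysisConfig, vals)
}

#' @rdname readAnalysisConfig
#' @param config an \code{analysis_config} list.
#' @export
writeAnalysisConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
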