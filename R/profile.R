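## kernel-density mode of a numeric vector
densityMode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(x[1])
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Compute S/G1 copy number
#'
#' Divides binned S-phase coverage by G1 coverage to obtain per-bin copy
#' number (1 = unreplicated, 2 = replicated in all cells). Three
#' normalization modes:
#' \describe{
#'   \item{"mode"}{(default) both tracks are scaled to equal genome-wide
#'     totals and the ratio is then divided by the mode of its histogram,
#'     anchoring the unreplicated background at 1.0. Appropriate for real
#'     libraries of unknown relative depth, provided a substantial fraction
#'     of the genome is unreplicated (otherwise the mode is not the
#'     background; see the package vignette).}
#'   \item{"total"}{equal-totals scaling only. A partially replicated
#'     genome deflates the background below 1.}
#'   \item{"none"}{raw per-bin ratio. Correct when the two libraries are
#'     depth-matched, as tracks from \code{\link{sampleReads}} are by
#'     construction.}
#' }
#'
#' @param sTrack,g1Track \linkS4class{GenomicTrack}s with identical binning.
#' @param minG1 bins with G1 count below this are flagged missing (NA)
#'   rather than divided (default 1).
#' @param normalize one of "mode", "total", "none".
#' @return A copy-number \linkS4class{GenomicTrack}.
#' @export
computeCopyNumber <- function(sTrack, g1Track, minG1 = 1,
                              normalize = c("mode", "total", "none")) {
  normalize <- match.arg(normalize)
  stopIfBinningMismatch(sTrack, g1Track)
  if (minG1 < 1) stop("minG1 must be >= 1")
  totG1 <- trackSum(g1Track)
  totS <- trackSum(sTrack)
  if (totG1 <= 0) stop("G1 track is all zero")
  scale <- if (normalize == "none") 1 else totG1 / totS
  ratio <- trackBinop(sTrack, g1Track, function(s, g) {
    out <- s * scale / g
    out[!is.na(g) & g < minG1] <- NA_real_
    out
  }, label = "S/G1 copy number")
  if (normalize == "mode") {
    m <- densityMode(unlist(ratio@values, use.names = FALSE))
    if (!is.finite(m) || m <= 0) stop("cannot locate a modal ratio")
    ratio <- trackApply(ratio, function(v, chr) v / m,
                        label = "S/G1 copy number")
  }
  ratio
}

## brick-wall low-pass of one chromosome vector (no NA allowed here)
lowpassVector <- function(x, binSizeBp, cutoffBp) {
  n <- length(x)
  y <- c(x, rev(x))                     # mirror pad (even extension)
  n2 <- 2L * n
  fy <- stats::fft(y)
  k <- 0:(n2 - 1L)
  kk <- pmin(k, n2 - k)                 # folded frequency index
  wavelength <- ifelse(kk == 0L, Inf, n2 * binSizeBp / kk)
  fy[wavelength < cutoffBp] <- 0+0i
  Re(stats::fft(fy, inverse = TRUE))[seq_len(n)] / n2
}

#' Fourier low-pass smoothing of a track
#'
#' Per chromosome: missing bins are linearly interpolated, the signal is
#' mirror-padded (even extension, removing the wrap-around discontinuity),
#' transformed with the FFT, all components of wavelength shorter than
#' \code{cutoffWavelength} are zeroed, and the signal is inverse-transformed
#' and un-padded. Missing bins are re-flagged afterwards. The chromosome
#' mean is preserved exactly (the DC component always passes).
#'
#' @param track a \linkS4class{GenomicTrack}.
#' @param cutoffWavelength bp; must be >= 2 * bin size. Default 20 kb.
#' @param endMask optional named list of per-chromosome logical vectors;
#'   TRUE bins (e.g. telomere-proximal, unmappable) are treated as missing.
#' @return smoothed \linkS4class{GenomicTrack}.
#' @export
fourierSmooth <- function(track, cutoffWavelength = 20000, endMask = NULL) {
  if (cutoffWavelength < 2 * track@binSize)
    stop("cutoffWavelength must be >= 2 * bin size")
  trackApply(track, function(v, chr) {
    if (!is.null(endMask) && chr %in% names(endMask))
      v[endMask[[chr]]] <- NA_real_
    n <- length(v)
    if (n < 2L) {
      warning("chromosome '", chr, "' shorter than 2 bins: passthrough")
      return(v)
    }
    nas <- is.na(v)
    if (all(nas)) return(v)
    if (any(nas)) {
      ok <- which(!nas)
      v[nas] <- stats::approx(ok, v[ok], xout = which(nas), rule = 2)$y
    }
    out <- lowpassVector(v, track@binSize, cutoffWavelength)
    out[nas] <- NA_real_
    out
  }, label = paste0(track@label, " (smoothed)"))
}

#' Build a replication profile from S and G1 coverage
#'
#' Convenience constructor chaining \code{\link{computeCopyNumber}} and
#' \code{\link{fourierSmooth}}.
#'
#' @inheritParams computeCopyNumber
#' @inheritParams fourierSmooth
#' @return A \linkS4class{ReplicationProfile}.
#' @examples
#' gm <- buildGenome(list(nOrigins = 8))
#' st <- simulateCellPopulation(gm, simulationCondition("HU"), 100, seed = 1)
#' rd <- sampleReads(st, depth = 50, seed = 2)
#' pr <- replicationProfile(rd$s, rd$g1, normalize = "none")
#' @export
replicationProfile <- function(sTrack, g1Track, minG1 = 1,
                               normalize = c("mode", "total", "none"),
                               cutoffWavelength = 20000, endMask = NULL) {
  raw <- computeCopyNumber(sTrack, g1Track, minG1 = minG1,
                           normalize = normalize)
  sm <- fourierSmooth(raw, cutoffWavelength = cutoffWavelength,
                      endMask = endMask)
  new("ReplicationProfile", rawRatio = raw, smoothed = sm,
      cutoffWavelength = cutoffWavelength)
}
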