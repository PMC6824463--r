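## Peak definition (frozen; the brute-force oracle in the test suite
## implements the same wording independently):
##
## On the smoothed copy number of one chromosome, take the discrete
## derivative d[i] = x[i+1] - x[i]. A peak is a sign change from plus to
## minus: a pair i <= j' with d[i] > 0, d[j'] < 0 and d == 0 strictly
## between (a zero-derivative plateau at the top), such that the sign is
## kept -- d strictly positive over the m bins ending at i and strictly
## negative over the m bins starting at j', where
## m = persistence %/% binSize + 1 (so the kept sign spans strictly more
## than `persistence` bp on each side; a flat stretch does not keep the
## sign, so short bumps on a flat background are rejected). Windows
## truncated by the chromosome end (or interrupted by missing bins)
## disqualify the candidate. The apex is the midpoint bin of the x-plateau
## between i and j'.

requiredRun <- function(persistenceBp, binSize) {
  as.integer(persistenceBp %/% binSize + 1L)
}

callPeaksChrom <- function(x, binSize, persistenceBp, chromLen) {
  n <- length(x)
  if (n < 2L) return(NULL)
  d <- diff(x)
  m <- requiredRun(persistenceBp, binSize)
  nd <- length(d)
  neg <- which(!is.na(d) & d < 0)
  if (!length(neg)) return(NULL)
  ## previous non-zero (or missing) derivative index for every position
  nz <- ifelse(is.na(d) | d != 0, seq_len(nd), 0L)
  prevNZ <- cummax(nz)
  ## run length of d > 0 ending at i (NA or zero breaks the run)
  okUp <- !is.na(d) & d > 0
  runUp <- integer(nd)
  acc <- 0L
  for (i in seq_len(nd)) {
    acc <- if (okUp[i]) acc + 1L else 0L
    runUp[i] <- acc
  }
  okDn <- !is.na(d) & d < 0
  runDn <- integer(nd)
  acc <- 0L
  for (i in rev(seq_len(nd))) {
    acc <- if (okDn[i]) acc + 1L else 0L
    runDn[i] <- acc
  }
  res <- list()
  for (j in neg) {
    if (j == 1L) next
    i <- prevNZ[j - 1L]   # last non-zero derivative strictly before j
    if (i == 0L || is.na(d[i]) || d[i] <= 0) next
    ## persistence windows must exist in full and keep the sign
    if (i < m) next
    if (j + m - 1L > nd) next
    if (runUp[i] < m) next
    if (runDn[j] < m) next
    apex <- (i + 1L + j) %/% 2L
    res[[length(res) + 1L]] <- data.frame(
      apex_bin = apex,
      apex_pos = min((apex - 0.5) * binSize, chromLen),
      apex_value = x[apex],
      left_extent = runUp[i] * binSize,
      right_extent = runDn[j] * binSize)
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Call replication peaks on a smoothed profile
#'
#' A peak is a local maximum of the smoothed copy number at which the
#' per-bin derivative changes sign from plus to minus and keeps its sign
#' (strictly positive before, strictly negative after) for more than
#' \code{persistenceBp} on each side of the change point (default 3 kb).
#' Zero-derivative plateaus at the top take the plateau midpoint bin as
#' apex; chromosome-terminal windows shorter than the persistence span
#' cannot host a peak.
#'
#' @param smoothed smoothed copy-number \linkS4class{GenomicTrack} (or a
#'   \linkS4class{ReplicationProfile}, whose smoothed track is used).
#' @param persistenceBp required span of sustained derivative sign, bp.
#' @return data.frame with columns chrom, apex_bin, apex_pos, apex_value,
#'   left_extent, right_extent.
#' @export
callPeaks <- function(smoothed, persistenceBp = 3000) {
  if (is(smoothed, "ReplicationProfile")) smoothed <- smoothed@smoothed
  out <- list()
  for (chr in names(smoothed@values)) {
    pk <- callPeaksChrom(smoothed@values[[chr]], smoothed@binSize,
                         persistenceBp, smoothed@seqlengths[[chr]])
    if (!is.null(pk)) {
      pk <- cbind(chrom = chr, pk)
      out[[chr]] <- pk
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), apex_bin = integer(),
                      apex_pos = numeric(), apex_value = numeric(),
                      left_extent = numeric(), right_extent = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full width at half maximum of replication peaks
#'
#' Width of each peak at half its height above the copy-number baseline of
#' 1.0 (half height = 1 + (apex - 1)/2), with linear interpolation between
#' bin midpoints. Peaks whose profile never drops below the half height
#' before the adjacent valley (local minimum, missing bin, or chromosome
#' end) are reported with the valley-to-valley distance instead and flagged
#' \code{truncated}. Peaks with apex at or below baseline have no defined
#' width (NA, flagged \code{undefined}).
#'
#' @param profile a \linkS4class{ReplicationProfile} (or smoothed
#'   \linkS4class{GenomicTrack}).
#' @param peaks data.frame from \code{\link{callPeaks}}.
#' @return \code{peaks} with added columns fwhm (bp), truncated, undefined.
#' @export
peakWidths <- function(profile, peaks) {
  sm <- if (is(profile, "ReplicationProfile")) profile@smoothed else profile
  bs <- sm@binSize
  fwhm <- rep(NA_real_, nrow(peaks))
  truncated <- rep(FALSE, nrow(peaks))
  undefined <- rep(FALSE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    x <- sm@values[[peaks$chrom[i]]]
    a <- peaks$apex_bin[i]
    A <- x[a]
    if (is.na(A) || A <= 1) {
      undefined[i] <- TRUE
      next
    }
    half <- 1 + (A - 1) / 2
    mid <- function(b) (b - 0.5) * bs
    ## walk one direction; returns list(pos, trunc)
    walk <- function(step) {
      prev <- a
      j <- a + step
      while (j >= 1 && j <= length(x)) {
        if (is.na(x[j])) return(list(pos = mid(prev), trunc = TRUE))
        if (x[j] < half) {
          frac <- (x[prev] - half) / (x[prev] - x[j])
          return(list(pos = mid(prev) + step * frac * bs, trunc = FALSE))
        }
        if (x[j] > x[prev])            # passed a valley at prev
          return(list(pos = mid(prev), trunc = TRUE))
        prev <- j
        j <- j + step
      }
      list(pos = mid(prev), trunc = TRUE)
    }
    L <- walk(-1L)
    R <- walk(+1L)
    truncated[i] <- L$trunc || R$trunc
    fwhm[i] <- R$pos - L$pos
  }
  cbind(peaks, fwhm = fwhm, truncated = truncated, undefined = undefined)
}
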