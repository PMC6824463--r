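#' Call fired origins from a replication profile
#'
#' For each annotated origin, takes the smoothed copy number at the origin
#' bin, converts it to the estimated fraction of cells in which the origin
#' fired -- under a two-state (replicated/unreplicated) population the copy
#' number is 1 + fired fraction, so fired fraction = clamp(copy number - 1,
#' 0, 1) -- and flags the origin as fired when that fraction reaches
#' \code{firedThreshold} (default 0.20, i.e. fired in at least 20% of
#' cells). When a peak table is supplied, each origin is matched to the
#' nearest called peak apex within \code{matchTol}.
#'
#' @param profile a \linkS4class{ReplicationProfile}.
#' @param origins data.frame with columns id, chrom, pos (and optionally
#'   t_rep, status), or a \linkS4class{GenomeModel}.
#' @param firedThreshold fired-fraction threshold in (0, 1].
#' @param matchTol bp; maximum origin-to-apex distance for a peak match.
#' @param peaks optional data.frame from \code{\link{callPeaks}}.
#' @return data.frame with columns id, chrom, pos, t_rep (NA if absent),
#'   copy_number, fired_fraction, fired, matched_peak_pos (NA when no peak
#'   within tolerance or no peak table given).
#' @export
callFiredOrigins <- function(profile, origins, firedThreshold = 0.2,
                             matchTol = 5000, peaks = NULL) {
  if (is(origins, "GenomeModel")) origins <- origins(origins)
  if (!(firedThreshold > 0 && firedThreshold <= 1))
    stop("firedThreshold must lie in (0, 1]")
  sm <- profile@smoothed
  bad <- !(origins$chrom %in% names(sm@values))
  if (any(bad))
    stop(sprintf("origin '%s' lies on unknown chromosome '%s'",
                 origins$id[bad][1], origins$chrom[bad][1]))
  cn <- vapply(seq_len(nrow(origins)), function(i) {
    v <- sm@values[[origins$chrom[i]]]
    v[min(binIndexOf(sm, origins$pos[i]), length(v))]
  }, 0)
  frac <- pmin(pmax(cn - 1, 0), 1)
  out <- data.frame(
    id = origins$id, chrom = origins$chrom, pos = origins$pos,
    t_rep = if ("t_rep" %in% names(origins)) origins$t_rep else NA_real_,
    copy_number = cn, fired_fraction = frac,
    fired = !is.na(frac) & frac >= firedThreshold,
    matched_peak_pos = NA_real_)
  out$fired[is.na(frac)] <- NA
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(out))) {
      pk <- peaks[peaks$chrom == out$chrom[i], , drop = FALSE]
      if (!nrow(pk)) next
      dd <- abs(pk$apex_pos - out$pos[i])
      if (min(dd) <= matchTol)
        out$matched_peak_pos[i] <- pk$apex_pos[which.min(dd)]
    }
  }
  out
}

#' Nearest-neighbour distances between fired origins
#'
#' For each fired origin, the distance (bp) to the nearest other fired
#' origin on the same chromosome. Fired origins that are alone on their
#' chromosome are reported with a missing distance.
#'
#' @param calls data.frame from \code{\link{callFiredOrigins}}.
#' @return data.frame with columns id, chrom, pos, distance for the fired
#'   origins.
#' @examples
#' calls <- data.frame(id = c("a", "b", "c"), chrom = "chrI",
#'                     pos = c(1e5, 1.5e5, 4e5), fired = TRUE)
#' interoriginDistances(calls)$distance   # 50, 50, 250 kb
#' @export
interoriginDistances <- function(calls) {
  fired <- calls[!is.na(calls$fired) & calls$fired, , drop = FALSE]
  if (!nrow(fired))
    return(data.frame(id = character(), chrom = character(),
                      pos = numeric(), distance = numeric()))
  out <- lapply(split(fired, fired$chrom), function(fc) {
    d <- rep(NA_real_, nrow(fc))
    if (nrow(fc) >= 2) {
      for (i in seq_len(nrow(fc)))
        d[i] <- min(abs(fc$pos[-i] - fc$pos[i]))
    }
    data.frame(id = fc$id, chrom = fc$chrom, pos = fc$pos, distance = d)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
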