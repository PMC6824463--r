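#' @rdname GenomicTrack-class
setMethod("binSize", "GenomicTrack", function(x) x@binSize)

#' @rdname GenomicTrack-class
setMethod("seqLengths", "GenomicTrack", function(x) x@seqlengths)

#' @rdname GenomicTrack-class
setMethod("chromNames", "GenomicTrack", function(x) names(x@values))

#' @rdname GenomicTrack-class
setMethod("trackValues", "GenomicTrack", function(x) x@values)

#' @rdname GenomicTrack-class
setMethod("trackLabel", "GenomicTrack", function(x) x@label)

setMethod("show", "GenomicTrack", function(object) {
  nb <- sum(vapply(object@values, length, 0L))
  nm <- sum(vapply(object@values, function(v) sum(is.na(v)), 0L))
  cat(sprintf(
    "GenomicTrack%s: %d chromosome(s), %d bins of %d bp (%d missing)\n",
    if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
    length(object@values), nb, object@binSize, nm))
})

#' @rdname GenomeModel-class
setMethod("binSize", "GenomeModel", function(x) x@binSize)

#' @rdname GenomeModel-class
setMethod("seqLengths", "GenomeModel", function(x) x@seqlengths)

#' @rdname GenomeModel-class
setMethod("chromNames", "GenomeModel", function(x) names(x@seqlengths))

#' @rdname GenomeModel-class
setMethod("origins", "GenomeModel", function(x) x@origins)

#' @rdname GenomeModel-class
setMethod("genes", "GenomeModel", function(x) x@genes)

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf(
    "GenomeModel: %d chromosome(s), %.3g Mb, %d origins, %d genes, %d bp bins\n",
    length(object@seqlengths), sum(object@seqlengths) / 1e6,
    nrow(object@origins), nrow(object@genes), object@binSize))
})

#' @rdname ReplicationState-class
setMethod("replicatedFraction", "ReplicationState",
          function(x) x@replicatedFraction)

#' @rdname ReplicationState-class
setMethod("trueFiredFraction", "ReplicationState",
          function(x) x@trueFiredFraction)

#' @rdname ReplicationState-class
setMethod("nCells", "ReplicationState", function(x) x@nCells)

setMethod("show", "ReplicationState", function(object) {
  cat(sprintf(
    "ReplicationState: %d cells, %d origins, mean replicated fraction %.3f\n",
    object@nCells, length(object@trueFiredFraction),
    mean(unlist(object@replicatedFraction@values), na.rm = TRUE)))
})

#' @rdname ReplicationProfile-class
setMethod("rawRatio", "ReplicationProfile", function(x) x@rawRatio)

#' @rdname ReplicationProfile-class
setMethod("smoothedTrack", "ReplicationProfile", function(x) x@smoothed)

#' @rdname ReplicationProfile-class
setMethod("cutoffWavelength", "ReplicationProfile",
          function(x) x@cutoffWavelength)

#' @rdname ReplicationProfile-class
setMethod("binSize", "ReplicationProfile", function(x) x@rawRatio@binSize)

setMethod("show", "ReplicationProfile", function(object) {
  cat(sprintf(
    "ReplicationProfile: %d chromosome(s), %d bp bins, %g bp Fourier cutoff\n",
    length(object@rawRatio@values), object@rawRatio@binSize,
    object@cutoffWavelength))
})

#' @rdname CatenaneDistribution-class
setMethod("catWeights", "CatenaneDistribution", function(x) {
  w <- x@weights
  names(w) <- seq_along(w)
  w
})

setMethod("show", "CatenaneDistribution", function(object) {
  cat(sprintf("CatenaneDistribution over n = 1..%d, median CatA_n = %d\n",
              length(object@weights), medianCatenane(object)))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit: K = %.4g, r = %.4g /day, g0 = %.4g (%s)\n",
              object@K, object@r, object@g0,
              if (object@converged) "converged" else "NOT converged"))
})

## ---- internal track utilities ----

sameBinning <- function(a, b) {
  identical(a@binSize, b@binSize) &&
    identical(names(a@values), names(b@values)) &&
    identical(unname(vapply(a@values, length, 0L)),
              unname(vapply(b@values, length, 0L)))
}

stopIfBinningMismatch <- function(a, b) {
  if (!sameBinning(a, b))
    stop("tracks do not share binning (bin size and per-chromosome bins)")
}

## 1-based bp position -> 1-based bin index
binIndexOf <- function(track, pos) {
  (as.integer(pos) - 1L) %/% track@binSize + 1L
}

## midpoints (bp) of the bins of one chromosome
binMids <- function(track, chrom) {
  n <- length(track@values[[chrom]])
  pmin((seq_len(n) - 0.5) * track@binSize, track@seqlengths[[chrom]])
}

## apply fn(values, chrom) per chromosome, keep structure
trackApply <- function(track, fn, label = track@label) {
  vals <- track@values
  for (chr in names(vals)) vals[[chr]] <- fn(vals[[chr]], chr)
  new("GenomicTrack", values = vals, binSize = track@binSize,
      seqlengths = track@seqlengths, label = label)
}

## elementwise binary op on two tracks with identical binning
trackBinop <- function(a, b, fn, label = "") {
  stopIfBinningMismatch(a, b)
  vals <- a@values
  for (chr in names(vals)) vals[[chr]] <- fn(a@values[[chr]], b@values[[chr]])
  new("GenomicTrack", values = vals, binSize = a@binSize,
      seqlengths = a@seqlengths, label = label)
}

trackSum <- function(track) {
  sum(unlist(track@values, use.names = FALSE), na.rm = TRUE)
}

#' Flatten a GenomicTrack to a data.frame
#'
#' One row per bin with 0-based half-open bin coordinates (the bedGraph
#' convention) and the bin value.
#'
#' @param x a \linkS4class{GenomicTrack}.
#' @param ... unused.
#' @return data.frame with columns chrom, start, end, value.
#' @export
setMethod("as.data.frame", "GenomicTrack", function(x, ...) {
  out <- lapply(names(x@values), function(chr) {
    v <- x@values[[chr]]
    n <- length(v)
    start <- (seq_len(n) - 1L) * x@binSize
    end <- pmin(start + x@binSize, x@seqlengths[[chr]])
    data.frame(chrom = chr, start = start, end = end, value = v)
  })
  do.call(rbind, out)
})
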