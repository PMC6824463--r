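#' @import methods
NULL

#' GenomicTrack: binned per-chromosome numeric signal
#'
#' The universal carrier for coverage, copy-number, ChIP and damage signal.
#' One numeric vector per chromosome, one value per fixed-size bin; `NA`
#' flags missing bins (masked, unmappable, or below a count floor). The
#' last bin of a chromosome may cover a partial bin.
#'
#' @slot values named list of numeric vectors, one per chromosome.
#' @slot binSize bin width in bp.
#' @slot seqlengths named numeric vector of chromosome lengths (bp).
#' @slot label free-text description of what the signal is.
#'
#' @exportClass GenomicTrack
setClass("GenomicTrack",
  representation(
    values = "list",
    binSize = "integer",
    seqlengths = "numeric",
    label = "character"
  )
)

setValidity("GenomicTrack", function(object) {
  v <- object@values
  sl <- object@seqlengths
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L)
    return("binSize must be a single positive integer")
  if (is.null(names(v)) || anyDuplicated(names(v)))
    return("values must be a uniquely named list of chromosomes")
  if (!identical(sort(names(v)), sort(names(sl))))
    return("names of values and seqlengths disagree")
  if (any(sl <= 0))
    return("chromosome lengths must be > 0")
  for (chr in names(v)) {
    if (!is.numeric(v[[chr]]))
      return(sprintf("values for chromosome '%s' are not numeric", chr))
    expected <- ceiling(sl[[chr]] / object@binSize)
    if (length(v[[chr]]) != expected)
      return(sprintf(
        "chromosome '%s': %d bins but expected ceiling(%g/%d) = %d",
        chr, length(v[[chr]]), sl[[chr]], object@binSize, expected))
    if (any(is.infinite(v[[chr]])))
      return(sprintf("chromosome '%s' holds non-finite (infinite) values; use NA for missing", chr))
  }
  TRUE
})

#' Construct a GenomicTrack
#'
#' @param values named list of numeric vectors (one per chromosome), or a
#'   single numeric vector (taken as one chromosome named \code{"chrI"}).
#' @param binSize bin width in bp.
#' @param seqlengths named chromosome lengths in bp; when omitted, each
#'   chromosome is assumed to span exactly its bins
#'   (\code{length(values) * binSize}).
#' @param label signal description.
#' @return A \linkS4class{GenomicTrack}.
#' @examples
#' gt <- GenomicTrack(list(chrI = rnorm(100, 1)), binSize = 1000)
#' binSize(gt)
#' @export
GenomicTrack <- function(values, binSize = 1000L, seqlengths = NULL,
                         label = "") {
  if (is.numeric(values)) values <- list(chrI = values)
  if (is.null(seqlengths))
    seqlengths <- vapply(values, length, 0L) * as.numeric(binSize)
  new("GenomicTrack", values = values, binSize = as.integer(binSize),
      seqlengths = seqlengths[names(values)], label = as.character(label))
}

#' GenomeModel: chromosomes, origins and genes for simulation
#'
#' @slot seqlengths named chromosome lengths (bp).
#' @slot binSize bin size used for simulated tracks (bp).
#' @slot origins data.frame with columns id, chrom, pos, t_rep, status.
#'   \code{t_rep} is the average replication time (minutes) of the origin in
#'   an unperturbed S-phase; \code{status} is one of confirmed/likely/dormant.
#' @slot genes data.frame with columns id, chrom, start, end, strand
#'   (1-based closed coordinates, strand "+" or "-").
#'
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(
    seqlengths = "numeric",
    binSize = "integer",
    origins = "data.frame",
    genes = "data.frame"
  )
)

setValidity("GenomeModel", function(object) {
  sl <- object@seqlengths
  if (length(sl) < 1 || any(sl <= 0) || is.null(names(sl)))
    return("need >= 1 named chromosome with positive length")
  o <- object@origins
  need <- c("id", "chrom", "pos", "t_rep", "status")
  if (!all(need %in% names(o)))
    return(paste("origins must have columns:", paste(need, collapse = ", ")))
  if (nrow(o)) {
    if (anyDuplicated(o$id)) return("duplicated origin ids")
    bad <- !(o$chrom %in% names(sl))
    if (any(bad))
      return(sprintf("origin '%s' lies on unknown chromosome '%s'",
                     o$id[bad][1], o$chrom[bad][1]))
    out <- o$pos < 1 | o$pos > sl[o$chrom]
    if (any(out))
      return(sprintf("origin '%s' at %d is outside chromosome '%s'",
                     o$id[out][1], o$pos[out][1], o$chrom[out][1]))
    if (any(o$t_rep <= 0)) return("origin t_rep must be > 0")
    if (!all(o$status %in% c("confirmed", "likely", "dormant")))
      return("origin status must be confirmed, likely or dormant")
  }
  g <- object@genes
  needg <- c("id", "chrom", "start", "end", "strand")
  if (!all(needg %in% names(g)))
    return(paste("genes must have columns:", paste(needg, collapse = ", ")))
  if (nrow(g)) {
    if (any(g$start > g$end)) {
      i <- which(g$start > g$end)[1]
      return(sprintf("gene '%s' has start > end", g$id[i]))
    }
    bad <- !(g$chrom %in% names(sl))
    if (any(bad))
      return(sprintf("gene '%s' lies on unknown chromosome '%s'",
                     g$id[bad][1], g$chrom[bad][1]))
    out <- g$start < 1 | g$end > sl[g$chrom]
    if (any(out))
      return(sprintf("gene '%s' extends outside chromosome '%s'",
                     g$id[out][1], g$chrom[out][1]))
    if (!all(g$strand %in% c("+", "-")))
      return("gene strand must be '+' or '-'")
  }
  TRUE
})

#' SimulationCondition: the replication-stress regime being simulated
#'
#' Encodes one experimental condition of the origin-firing simulator: the
#' drug regime, whether the intra-S checkpoint can suppress late firing,
#' the T_rep cutoff below which firing is permitted under an intact
#' checkpoint, the firing probabilities, and the fork geometry. Under
#' HU/MMS the fork travel is capped at \code{maxForkTravel} (dNTP depletion
#' stalls forks); permitted origins fire at the moment of release (t = 0),
#' while in an unperturbed S-phase firing times are exponentially dispersed
#' around each origin's T_rep.
#'
#' @slot regime one of "HU", "MMS", "unperturbed".
#' @slot checkpointIntact logical; FALSE models checkpoint-blind firing
#'   (sld3-A dbf4-A-like behaviour).
#' @slot trepCutoff minutes; origins with t_rep below this fire freely
#'   under an intact checkpoint (default 27.5).
#' @slot baseFiringProb per-cell firing probability of permitted origins.
#' @slot suppressedFiringProb firing probability of checkpoint-suppressed
#'   origins.
#' @slot forkSpeed bp/min.
#' @slot maxForkTravel bp; cap on per-fork travel.
#' @slot sDuration minutes of S-phase (or arrest) simulated.
#'
#' @exportClass SimulationCondition
setClass("SimulationCondition",
  representation(
    regime = "character",
    checkpointIntact = "logical",
    trepCutoff = "numeric",
    baseFiringProb = "numeric",
    suppressedFiringProb = "numeric",
    forkSpeed = "numeric",
    maxForkTravel = "numeric",
    sDuration = "numeric"
  )
)

setValidity("SimulationCondition", function(object) {
  if (!object@regime %in% c("HU", "MMS", "unperturbed"))
    return("regime must be HU, MMS or unperturbed")
  p <- c(object@baseFiringProb, object@suppressedFiringProb)
  if (any(p < 0 | p > 1)) return("firing probabilities must lie in [0, 1]")
  if (object@maxForkTravel <= 0) return("maxForkTravel must be > 0")
  if (object@forkSpeed <= 0) return("forkSpeed must be > 0")
  if (object@sDuration <= 0) return("sDuration must be > 0")
  if (object@trepCutoff <= 0) return("trepCutoff must be > 0")
  TRUE
})

#' @rdname SimulationCondition-class
#' @param regime,checkpointIntact,trepCutoff,baseFiringProb,suppressedFiringProb,forkSpeed,maxForkTravel,sDuration see slots.
#' @return A \linkS4class{SimulationCondition}.
#' @examples
#' simulationCondition("HU", checkpointIntact = FALSE)
#' @export
simulationCondition <- function(regime = c("HU", "MMS", "unperturbed"),
                                checkpointIntact = TRUE,
                                trepCutoff = 27.5,
                                baseFiringProb = 0.9,
                                suppressedFiringProb = 0.02,
                                forkSpeed = 1500,
                                maxForkTravel = 10000,
                                sDuration = 90) {
  new("SimulationCondition", regime = match.arg(regime),
      checkpointIntact = checkpointIntact, trepCutoff = trepCutoff,
      baseFiringProb = baseFiringProb,
      suppressedFiringProb = suppressedFiringProb,
      forkSpeed = forkSpeed, maxForkTravel = maxForkTravel,
      sDuration = sDuration)
}

#' ReplicationState: ground truth of a simulated cell population
#'
#' @slot replicatedFraction \linkS4class{GenomicTrack}; per-bin fraction of
#'   simulated cells in which the bin is replicated (values in [0, 1]).
#' @slot nCells number of simulated cells.
#' @slot trueFiredFraction named numeric; per origin, the fraction of cells
#'   in which it fired actively (passive replication does not count).
#'
#' @exportClass ReplicationState
setClass("ReplicationState",
  representation(
    replicatedFraction = "GenomicTrack",
    nCells = "integer",
    trueFiredFraction = "numeric"
  )
)

setValidity("ReplicationState", function(object) {
  vals <- unlist(object@replicatedFraction@values, use.names = FALSE)
  if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE))
    return("replicatedFraction values must lie in [0, 1]")
  f <- object@trueFiredFraction
  if (length(f) && (any(f < 0 | f > 1) || is.null(names(f))))
    return("trueFiredFraction must be named values in [0, 1]")
  if (object@nCells < 1L) return("nCells must be >= 1")
  TRUE
})

#' ReplicationProfile: raw and smoothed S/G1 copy number
#'
#' @slot rawRatio \linkS4class{GenomicTrack} of S/G1 copy number (expected
#'   range about [1, 2]: 1 = unreplicated, 2 = replicated in all cells).
#' @slot smoothed Fourier low-pass smoothed copy number, identical binning.
#' @slot cutoffWavelength bp; wavelengths below this were removed.
#'
#' @exportClass ReplicationProfile
setClass("ReplicationProfile",
  representation(
    rawRatio = "GenomicTrack",
    smoothed = "GenomicTrack",
    cutoffWavelength = "numeric"
  )
)

setValidity("ReplicationProfile", function(object) {
  if (!sameBinning(object@rawRatio, object@smoothed))
    return("rawRatio and smoothed must share binning")
  if (object@cutoffWavelength < 2 * object@rawRatio@binSize)
    return("cutoffWavelength must be >= 2 * binSize")
  TRUE
})

#' CatenaneDistribution: weights over discrete catenane number
#'
#' Normalized band-intensity weights over catenane number n = 1..n_max, as
#' quantified from nicked 2D-gel catenane (CatA) ladders. Supports a
#' weighted discrete median.
#'
#' @slot weights numeric vector of non-negative weights; element i is the
#'   intensity fraction of the n = i isoform. Normalized to sum 1 on
#'   construction.
#'
#' @exportClass CatenaneDistribution
setClass("CatenaneDistribution", representation(weights = "numeric"))

setValidity("CatenaneDistribution", function(object) {
  w <- object@weights
  if (length(w) < 1) return("need n_max >= 1")
  if (any(!is.finite(w)) || any(w < 0))
    return("weights must be finite and non-negative")
  if (sum(w) <= 0) return("weights must not be all zero")
  if (abs(sum(w) - 1) > 1e-8) return("weights must be normalized to sum 1")
  TRUE
})

#' @rdname CatenaneDistribution-class
#' @param weights non-negative intensities for n = 1, 2, ... (any scale;
#'   normalized internally).
#' @return A \linkS4class{CatenaneDistribution}.
#' @examples
#' catenaneDistribution(c(0, 2, 3, 1))
#' @export
catenaneDistribution <- function(weights) {
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not be all zero")
  new("CatenaneDistribution", weights = weights / s)
}

#' LogisticFit: fitted logistic growth model of one culture
#'
#' Parameters of g(t) = K g0 exp(rt) / (K + g0 (exp(rt) - 1)).
#'
#' @slot K carrying capacity (density units).
#' @slot r intrinsic rate (1/day).
#' @slot g0 inoculum density.
#' @slot converged logical; FALSE when optimisation failed or the fitted
#'   model is degenerate (no growth, K <= g0).
#' @slot rss residual sum of squares.
#'
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(K = "numeric", r = "numeric", g0 = "numeric",
                 converged = "logical", rss = "numeric")
)

setValidity("LogisticFit", function(object) {
  if (object@converged) {
    if (!(object@K > object@g0 && object@g0 > 0))
      return("converged fit requires K > g0 > 0")
    if (object@r < 0) return("converged fit requires r >= 0")
  }
  TRUE
})
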