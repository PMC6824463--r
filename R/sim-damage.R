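#' Ground-truth parameters for the damage-signal simulator
#'
#' @param betaConvergent unitless enrichment coefficient added at origins in
#'   a convergent gene-pair context.
#' @param trepSlope unitless per-minute growth of that enrichment with the
#'   origin's T_rep (relative to the earliest origin).
#' @param noiseSd lognormal noise sd (log scale) on both tracks (>= 0).
#' @return list of class \code{damage_truth}.
#' @examples
#' damageTruth(betaConvergent = 1, trepSlope = 0.03)
#' @export
damageTruth <- function(betaConvergent = 1, trepSlope = 0.03,
                        noiseSd = 0.05) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(betaConvergent = betaConvergent, trepSlope = trepSlope,
                 noiseSd = noiseSd), class = "damage_truth")
}

#' Simulate damage (gamma-H2A-like) IP and control ChIP tracks
#'
#' The damage mark only accumulates at replicating loci: the expected IP
#' signal is proportional to the per-bin replicated fraction, multiplied --
#' within \code{window} bp of origins sitting between convergently
#' transcribed gene pairs -- by
#' \code{1 + beta * (1 + slope * (t_rep - min t_rep))}. The control
#' (unmodified histone) track is flat. Both tracks carry multiplicative
#' lognormal noise plus a small nonspecific-IP background
#' (\code{backgroundFrac} of the control level), so an unreplicated genome
#' yields IP signal at the noise floor rather than exactly zero.
#'
#' @param state a \linkS4class{ReplicationState}.
#' @param genome the \linkS4class{GenomeModel} the state was simulated from.
#' @param truth a \code{\link{damageTruth}} list.
#' @param seed integer seed.
#' @param window bp around a convergent-context origin over which the extra
#'   enrichment applies (default 2000).
#' @param scale expected counts per bin of the control track.
#' @param backgroundFrac nonspecific IP background as a fraction of the
#'   control level.
#' @return list with GenomicTracks \code{ip} and \code{control}.
#' @export
simulateDamageTracks <- function(state, genome, truth = damageTruth(),
                                 seed = 1L, window = 2000,
                                 scale = 100, backgroundFrac = 0.02) {
  stopifnot(inherits(truth, "damage_truth"))
  f <- replicatedFraction(state)
  o <- origins(genome)
  ctx <- classifyOriginGeneContext(o, genes(genome))
  conv <- ctx[ctx$pair_class == "convergent", , drop = FALSE]
  tmin <- if (nrow(o)) min(o$t_rep) else 0

  ## per-bin enrichment multiplier
  mult <- trackApply(f, function(v, chr) {
    m <- rep(1, length(v))
    cc <- conv[conv$chrom == chr, , drop = FALSE]
    if (nrow(cc)) {
      mids <- pmin((seq_along(v) - 0.5) * f@binSize, f@seqlengths[[chr]])
      for (i in seq_len(nrow(cc))) {
        sel <- abs(mids - cc$pos[i]) <= window
        m[sel] <- 1 + truth$betaConvergent *
          (1 + truth$trepSlope * (cc$t_rep[i] - tmin))
      }
    }
    m
  })

  withSeed(seed, {
    ip <- trackBinop(f, mult, function(v, m)
      scale * v * m * exp(stats::rnorm(length(v), 0, truth$noiseSd)) +
      scale * backgroundFrac *
        exp(stats::rnorm(length(v), 0, truth$noiseSd)),
      label = "damage IP")
    control <- trackApply(f, function(v, chr)
      scale * exp(stats::rnorm(length(v), 0, truth$noiseSd)),
      label = "control IP")
  })
  list(ip = ip, control = control)
}
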