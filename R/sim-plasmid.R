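#' Simulate a plasmid-loss colony assay
#'
#' Inverts the per-generation loss statistic: after G generations of
#' nonselective growth at a true loss rate of \code{lossRatePct} percent
#' per generation, the expected ratio of plasmid maintenance is
#' RMP = (1 - rate/100)^G, and the number of colonies that still carry the
#' plasmid (grow on selective medium) is Binomial(nColonies, RMP).
#'
#' @param lossRatePct true loss rate, percent per generation, in [0, 100].
#' @param G generations of nonselective growth (> 0).
#' @param nColonies colonies plated on nonselective medium.
#' @param seed integer seed.
#' @return list with \code{nSelective}, \code{nNonselective} and the true
#'   \code{RMP}.
#' @examples
#' simulatePlasmidCounts(6.697, G = 10, nColonies = 1000, seed = 1)
#' @export
simulatePlasmidCounts <- function(lossRatePct, G, nColonies, seed = 1L) {
  if (lossRatePct < 0 || lossRatePct > 100)
    stop("lossRatePct must lie in [0, 100]")
  if (G <= 0) stop("G must be > 0")
  rmp <- (1 - lossRatePct / 100)^G
  nSel <- withSeed(seed, stats::rbinom(1L, as.integer(nColonies), rmp))
  list(nSelective = nSel, nNonselective = as.integer(nColonies), RMP = rmp)
}

#' Simulate a catenane (CatA_n) band-intensity distribution
#'
#' Discretizes a normal distribution with the given mean and spread over
#' the integer catenane numbers 1..nMax (bin integrals, renormalized).
#' When \code{nMolecules} is finite, multinomial sampling noise at that
#' effective molecule count is added, emulating band quantification of a
#' finite plasmid population. As spread tends to 0 the distribution
#' collapses to a point mass at \code{round(meanCat)}.
#'
#' @param meanCat expected catenane number.
#' @param spread sd of the underlying continuous distribution (>= 0).
#' @param nMax largest catenane number carried (>= 1).
#' @param seed integer seed (used only when \code{nMolecules} is finite).
#' @param nMolecules effective number of molecules behind the gel lane;
#'   \code{Inf} (default) returns the exact discretized weights.
#' @return A \linkS4class{CatenaneDistribution}.
#' @examples
#' medianCatenane(simulateCatenaneDistribution(5, 1.5, 20))
#' @export
simulateCatenaneDistribution <- function(meanCat, spread, nMax = 30,
                                         seed = 1L, nMolecules = Inf) {
  if (nMax < 1) stop("nMax must be >= 1")
  if (spread < 0) stop("spread must be >= 0")
  n <- seq_len(nMax)
  if (spread == 0) {
    w <- as.numeric(n == max(1, min(nMax, round(meanCat))))
  } else {
    w <- stats::pnorm(n + 0.5, meanCat, spread) -
      stats::pnorm(n - 0.5, meanCat, spread)
    if (sum(w) <= 0) w <- as.numeric(n == max(1, min(nMax, round(meanCat))))
  }
  if (is.finite(nMolecules)) {
    cnt <- withSeed(seed,
      stats::rmultinom(1L, as.integer(nMolecules), w / sum(w)))[, 1]
    if (sum(cnt) > 0) w <- cnt
  }
  catenaneDistribution(w)
}
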