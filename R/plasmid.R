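#' Plasmid loss rate per generation
#'
#' The ratio of plasmid maintenance RMP is the number of colonies on
#' selective medium divided by the number on nonselective medium after G
#' generations of nonselective growth; the loss rate per generation is
#' 100 * (1 - RMP^(1/G)) percent. RMP = 0 returns exactly 100.
#'
#' @param nSelective,nNonselective colony counts (0 <= nSelective <=
#'   nNonselective, nNonselective > 0).
#' @param G generations of nonselective growth (> 0).
#' @return loss rate, percent per generation.
#' @examples
#' plasmidLossRate(500, 1000, G = 10)   # ~6.697
#' @export
plasmidLossRate <- function(nSelective, nNonselective, G) {
  if (any(nNonselective <= 0)) stop("nNonselective must be > 0")
  if (any(G <= 0)) stop("G must be > 0")
  if (any(nSelective < 0) || any(nSelective > nNonselective))
    stop("need 0 <= nSelective <= nNonselective")
  rmp <- nSelective / nNonselective
  100 * (1 - rmp^(1 / G))
}

#' Plasmid loss rate with a bootstrap confidence interval
#'
#' Percentile bootstrap over binomial resampling of the selective colony
#' count at the observed maintenance ratio. The interval is widened, if
#' necessary, to contain the point estimate. \code{nBoot = 0} returns the
#' point estimate only.
#'
#' @inheritParams plasmidLossRate
#' @param nBoot bootstrap replicates.
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with rate, lower, upper, nBoot.
#' @export
lossRateWithCI <- function(nSelective, nNonselective, G, nBoot = 1000,
                           level = 0.95, seed = 1L) {
  rate <- plasmidLossRate(nSelective, nNonselective, G)
  if (nBoot <= 0)
    return(list(rate = rate, lower = NA_real_, upper = NA_real_,
                nBoot = 0L))
  rmp <- nSelective / nNonselective
  boot <- withSeed(seed, {
    ns <- stats::rbinom(nBoot, nNonselective, rmp)
    plasmidLossRate(ns, nNonselective, G)
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  list(rate = rate, lower = min(ci[1], rate), upper = max(ci[2], rate),
       nBoot = as.integer(nBoot))
}

#' Weighted discrete median catenane number
#'
#' The smallest n whose cumulative weight reaches 0.5 (discrete weighted
#' median; band counts are integers by nature, so no interpolation).
#'
#' @param dist a \linkS4class{CatenaneDistribution}.
#' @return integer median CatA_n.
#' @examples
#' medianCatenane(catenaneDistribution(c(1, 1, 1, 1)))   # 2
#' @export
medianCatenane <- function(dist) {
  w <- dist@weights
  as.integer(which(cumsum(w) >= 0.5 - 1e-12)[1])
}

#' Compare catenation between two distributions
#'
#' Difference of median catenane numbers (b minus a) with a bootstrap CI
#' obtained by multinomial resampling of each distribution's weights at a
#' stated effective molecule count.
#'
#' @param distA,distB \linkS4class{CatenaneDistribution}s.
#' @param nBoot bootstrap replicates (0 for the point estimate only).
#' @param effectiveCount multinomial resampling depth per distribution.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with delta_median, lower, upper.
#' @export
compareCatenation <- function(distA, distB, nBoot = 1000,
                              effectiveCount = 1000, level = 0.95,
                              seed = 1L) {
  delta <- medianCatenane(distB) - medianCatenane(distA)
  if (nBoot <= 0)
    return(list(delta_median = delta, lower = NA_real_, upper = NA_real_))
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      wa <- stats::rmultinom(1L, effectiveCount, distA@weights)[, 1]
      wb <- stats::rmultinom(1L, effectiveCount, distB@weights)[, 1]
      medianCatenane(catenaneDistribution(wb)) -
        medianCatenane(catenaneDistribution(wa))
    }, 0)
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  list(delta_median = delta, lower = ci[1], upper = ci[2])
}

#' Summarise replicate plasmid-loss assays
#'
#' Mirrors the n = 3 replicate-culture design: per strain, the mean and SD
#' of the per-replicate loss rates plus a pooled bootstrap CI.
#'
#' @param assays data.frame with columns strain, replicate, n_selective,
#'   n_nonselective, G.
#' @param nBoot,level,seed passed to \code{\link{lossRateWithCI}}.
#' @return data.frame with strain, n_replicates, mean_rate, sd_rate,
#'   lower, upper.
#' @export
summarisePlasmidAssays <- function(assays, nBoot = 1000, level = 0.95,
                                   seed = 1L) {
  rows <- lapply(split(assays, assays$strain), function(a) {
    rates <- plasmidLossRate(a$n_selective, a$n_nonselective, a$G)
    ci <- lossRateWithCI(sum(a$n_selective), sum(a$n_nonselective),
                         G = a$G[1], nBoot = nBoot, level = level,
                         seed = seed)
    data.frame(strain = a$strain[1], n_replicates = nrow(a),
               mean_rate = mean(rates),
               sd_rate = if (nrow(a) > 1) stats::sd(rates) else NA_real_,
               lower = ci$lower, upper = ci$upper)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
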