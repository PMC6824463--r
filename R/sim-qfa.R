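#' Logistic growth helpers
#'
#' \code{logisticDensity} evaluates the logistic solution
#' g(t) = K g0 exp(rt) / (K + g0 (exp(rt) - 1)); \code{logisticFitness}
#' returns its fitness F = MDP x MDR = log2(K/g0) (r/ln 2)(1 - g0/K).
#'
#' @param t time (days).
#' @param K carrying capacity.
#' @param r intrinsic rate (1/day).
#' @param g0 inoculum density.
#' @return density (or fitness) value(s).
#' @export
logisticDensity <- function(t, K, r, g0) {
  K * g0 * exp(r * t) / (K + g0 * (exp(r * t) - 1))
}

#' @rdname logisticDensity
#' @export
logisticFitness <- function(K, r, g0) {
  log2(K / g0) * (r / log(2)) * (1 - g0 / K)
}

#' Simulate replicate-level fitness of a genome-wide screen
#'
#' Draws a control-background fitness per gene, places the query-background
#' expectation on the population line \code{F_query = a + b * F_control},
#' adds the injected genetic interaction \code{gamma} for the stated genes,
#' and then adds independent Gaussian replicate noise. This is the
#' fitness-level ground truth that \code{\link{simulateGrowthCurves}}
#' renders as growth curves.
#'
#' @param nGenes number of genes.
#' @param gamma named numeric of true interaction strengths (names are gene
#'   ids \code{gene001}, ...); genes not named carry gamma = 0. May be NULL
#'   (null screen).
#' @param reps replicates per gene x background.
#' @param noiseSd replicate-level fitness noise sd.
#' @param seed integer seed.
#' @param baseMean,baseSd control-background fitness distribution.
#' @param slope,intercept population line relating query to control
#'   expectation.
#' @return list with \code{truth} (gene, gamma, F_control_true,
#'   F_query_true) and \code{reps} (gene, background, replicate, F).
#' @examples
#' sc <- simulateScreenFitness(50, gamma = c(gene001 = -0.4), seed = 1)
#' head(sc$reps)
#' @export
simulateScreenFitness <- function(nGenes, gamma = NULL, reps = 4,
                                  noiseSd = 0.05, seed = 1L,
                                  baseMean = 30, baseSd = 3,
                                  slope = 0.8, intercept = 0) {
  geneIds <- sprintf("gene%03d", seq_len(nGenes))
  g <- stats::setNames(numeric(nGenes), geneIds)
  if (!is.null(gamma)) {
    if (is.null(names(gamma)) || !all(names(gamma) %in% geneIds))
      stop("gamma must be named with gene ids present in the screen")
    g[names(gamma)] <- gamma
  }
  withSeed(seed, {
    fc <- stats::setNames(pmax(stats::rnorm(nGenes, baseMean, baseSd), 1),
                          geneIds)
    fq <- pmax(intercept + slope * fc + g, 0)
    repdf <- data.frame(
      gene = rep(geneIds, each = 2 * reps),
      background = rep(rep(c("control", "query"), each = reps), nGenes),
      replicate = rep(seq_len(reps), 2 * nGenes),
      F = NA_real_)
    mu <- ifelse(repdf$background == "control", fc[repdf$gene],
                 fq[repdf$gene])
    repdf$F <- pmax(mu + stats::rnorm(nrow(repdf), 0, noiseSd), 0)
  })
  list(truth = data.frame(gene = geneIds, gamma = unname(g),
                          F_control_true = fc, F_query_true = fq),
       reps = repdf)
}

#' Simulate colony growth curves for a fitness screen
#'
#' Renders the replicate-level fitness values of
#' \code{\link{simulateScreenFitness}} as logistic growth curves: every
#' culture shares the inoculum \code{g0} and carrying capacity \code{K},
#' and the intrinsic rate r of each replicate is set so that the realized
#' fitness F = MDP x MDR equals that replicate's target. Densities carry
#' multiplicative lognormal measurement noise.
#'
#' @param screen output of \code{\link{simulateScreenFitness}}; when NULL a
#'   screen is simulated from the remaining arguments.
#' @param nGenes,gamma,reps,fitnessNoiseSd,seed passed to
#'   \code{\link{simulateScreenFitness}} when \code{screen} is NULL.
#' @param timepoints observation times in days, strictly increasing
#'   (default every 4 h over 5 days).
#' @param densityNoiseSd lognormal sd of the density measurements.
#' @param K,g0 shared carrying capacity and inoculum density.
#' @return list with \code{curves} (long data.frame: strain, gene,
#'   background, replicate, time_days, density), \code{truth} and
#'   \code{reps} from the underlying screen.
#' @export
simulateGrowthCurves <- function(screen = NULL, nGenes = 400, gamma = NULL,
                                 reps = 4, fitnessNoiseSd = 0.05,
                                 timepoints = seq(0, 5, by = 1 / 6),
                                 densityNoiseSd = 0.002,
                                 K = 1, g0 = 2^-10, seed = 1L) {
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (is.null(screen))
    screen <- simulateScreenFitness(nGenes, gamma = gamma, reps = reps,
                                    noiseSd = fitnessNoiseSd, seed = seed)
  repdf <- screen$reps
  ## invert F = log2(K/g0) * (r/ln2) * (1 - g0/K) for r
  fac <- log2(K / g0) * (1 - g0 / K) / log(2)
  r <- repdf$F / fac
  nt <- length(timepoints)
  curves <- data.frame(
    strain = rep(paste0(repdf$gene, ".", substr(repdf$background, 1, 1),
                        repdf$replicate), each = nt),
    gene = rep(repdf$gene, each = nt),
    background = rep(repdf$background, each = nt),
    replicate = rep(repdf$replicate, each = nt),
    time_days = rep(timepoints, nrow(repdf)),
    density = NA_real_)
  mu <- logisticDensity(curves$time_days, K, rep(r, each = nt), g0)
  curves$density <- withSeed(seed + 1L,
    mu * exp(stats::rnorm(nrow(curves), 0, densityNoiseSd)))
  list(curves = curves, truth = screen$truth, reps = repdf)
}
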