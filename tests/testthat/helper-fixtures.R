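## one-chromosome track shorthand
gt1 <- function(x, binSize = 1000, chrom = "chrI") {
  v <- list(x)
  names(v) <- chrom
  GenomicTrack(v, binSize = binSize)
}

## DCT-II basis cosine: exactly periodic in the mirror-padded domain, so a
## brick-wall filter either passes or removes it exactly.
## wavelength (bp) = 2 * n * binSize / k
dctCosine <- function(n, k) cos(pi * k * (2 * seq_len(n) - 1) / (2 * n))

## Brute-force peak oracle: tests every derivative position against the
## "+ -> - sign change with the sign kept for more than `persistenceBp` on
## each side" definition, scanning plateaus literally. Returns apex bins.
oraclePeaks <- function(x, binSize, persistenceBp) {
  n <- length(x)
  if (n < 2) return(integer(0))
  d <- x[-1] - x[-n]
  m <- persistenceBp %/% binSize + 1
  apexes <- integer(0)
  for (i in seq_len(n - 1)) {
    if (is.na(d[i]) || d[i] <= 0) next
    j <- i + 1L
    while (j <= n - 1 && !is.na(d[j]) && d[j] == 0) j <- j + 1L
    if (j > n - 1 || is.na(d[j]) || d[j] >= 0) next
    if (i - m + 1 < 1 || j + m - 1 > n - 1) next
    pre <- d[(i - m + 1):i]
    post <- d[j:(j + m - 1)]
    if (any(is.na(pre)) || any(pre <= 0)) next
    if (any(is.na(post)) || any(post >= 0)) next
    apexes <- c(apexes, (i + 1L + j) %/% 2L)
  }
  apexes
}

## random piecewise-linear profile with occasional exact plateaus
randomProfile <- function(seed, n = 1000) {
  set.seed(seed)
  knots <- c(1, cumsum(sample(3:80, n, replace = TRUE)))
  knots <- c(knots[knots < n], n)
  vals <- runif(length(knots), 1, 2)
  for (i in seq_along(vals)[-1])
    if (runif(1) < 0.25) vals[i] <- vals[i - 1]   # plateau segment
  approx(knots, vals, xout = seq_len(n))$y
}

## tiny deterministic genome for fast tests
tinyGenome <- function(nOrigins = 8, len = 2e5, ...) {
  buildGenome(list(chromosomes = c(chrI = len), nOrigins = nOrigins, ...))
}
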