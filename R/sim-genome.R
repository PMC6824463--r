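## Evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a synthetic genome model
#'
#' Constructs a small genome with regularly spaced replication origins and,
#' around a stated subset of origins, non-overlapping flanking gene pairs
#' with prescribed orientations. This defines the ground truth that the
#' downstream profiling and damage-mapping stages are tested against.
#'
#' Origin T_rep values (average replication time in an unperturbed S-phase,
#' minutes) are drawn uniformly from \code{config$trepRange} using
#' \code{config$seed}, so the model is fully deterministic given the
#' config. Gene pairs are 1-kb genes placed symmetrically at
#' \code{config$geneOffset} bp from the origin; their orientation class is
#' assigned per origin by recycling \code{config$pairClasses}:
#' \itemize{
#'   \item convergent: left gene "+", right gene "-" (transcription of both
#'     genes meets the outgoing replication forks head-on);
#'   \item codirectional: both genes "+";
#'   \item divergent: left "-", right "+";
#'   \item none: no flanking genes for that origin.
#' }
#'
#' @param config a list; recognised fields (all optional):
#'   \code{chromosomes} named lengths in bp (default \code{c(chrI = 1e6)}),
#'   \code{binSize} (1000), \code{nOrigins} (40), \code{posJitter}
#'   (uniform origin-position jitter as a fraction of the mean spacing,
#'   default 0.2; 0 gives a regular grid),
#'   \code{trepRange} (\code{c(15, 40)}), \code{trepValues} (explicit
#'   per-origin T_rep overriding the draw), \code{seed} (1),
#'   \code{pairClasses} (character, recycled over origins; default
#'   alternates convergent / codirectional / divergent),
#'   \code{geneOffset} (3000), \code{geneLength} (1000).
#' @return A \linkS4class{GenomeModel}.
#' @examples
#' gm <- buildGenome(list(nOrigins = 10))
#' origins(gm)[1:3, ]
#' @export
buildGenome <- function(config = list()) {
  cfg <- utils::modifyList(list(
    chromosomes = c(chrI = 1e6), binSize = 1000L, nOrigins = 40L,
    posJitter = 0.2, trepRange = c(15, 40), trepValues = NULL, seed = 1L,
    pairClasses = c("convergent", "codirectional", "divergent"),
    geneOffset = 3000L, geneLength = 1000L), config)
  sl <- cfg$chromosomes
  if (length(sl) < 1) stop("config must list >= 1 chromosome")
  if (is.null(names(sl))) names(sl) <- paste0("chr", seq_along(sl))

  ## spread origins across chromosomes proportionally to length
  nOri <- as.integer(cfg$nOrigins)
  if (nOri < 1) stop("config must place >= 1 origin")
  share <- floor(nOri * sl / sum(sl))
  while (sum(share) < nOri) share[which.max(sl - share * sum(sl) / nOri)] <-
      share[which.max(sl - share * sum(sl) / nOri)] + 1
  oriList <- withSeed(cfg$seed, lapply(names(sl)[share > 0], function(chr) {
    k <- share[[chr]]
    spacing <- sl[[chr]] / k
    ## real inter-origin spacing is irregular; jitter each origin around
    ## its grid position so nearest-neighbour statistics are non-degenerate
    jit <- if (k > 1) stats::runif(k, -cfg$posJitter * spacing,
                                   cfg$posJitter * spacing) else 0
    pos <- pmin(pmax(round(spacing * (seq_len(k) - 0.5) + jit), 1),
                sl[[chr]])
    data.frame(chrom = chr, pos = as.integer(pos))
  }))
  ori <- do.call(rbind, oriList)
  ori$id <- sprintf("ori%02d", seq_len(nrow(ori)))
  if (!is.null(cfg$trepValues)) {
    if (length(cfg$trepValues) != nrow(ori))
      stop("trepValues must have one value per origin")
    ori$t_rep <- cfg$trepValues
  } else {
    ori$t_rep <- withSeed(cfg$seed + 1L,
      stats::runif(nrow(ori), cfg$trepRange[1], cfg$trepRange[2]))
  }
  ori$status <- "confirmed"
  ori <- ori[, c("id", "chrom", "pos", "t_rep", "status")]

  ## flanking gene pairs
  classes <- rep_len(cfg$pairClasses, nrow(ori))
  glist <- list()
  for (i in seq_len(nrow(ori))) {
    cls <- classes[i]
    if (cls == "none") next
    strands <- switch(cls,
      convergent = c("+", "-"),
      codirectional = c("+", "+"),
      divergent = c("-", "+"),
      stop("unknown pair class '", cls, "'"))
    off <- cfg$geneOffset
    len <- cfg$geneLength
    glist[[length(glist) + 1L]] <- data.frame(
      id = sprintf("gene%02d%s", i, c("L", "R")),
      chrom = ori$chrom[i],
      start = c(ori$pos[i] - off - len + 1L, ori$pos[i] + off),
      end = c(ori$pos[i] - off, ori$pos[i] + off + len - 1L),
      strand = strands)
  }
  gdf <- if (length(glist)) do.call(rbind, glist) else
    data.frame(id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  ## drop gene pairs that would fall off a chromosome end
  if (nrow(gdf)) {
    keep <- gdf$start >= 1 & gdf$end <= sl[gdf$chrom]
    gdf <- gdf[keep, , drop = FALSE]
  }
  rownames(gdf) <- NULL
  rownames(ori) <- NULL
  new("GenomeModel", seqlengths = sl, binSize = as.integer(cfg$binSize),
      origins = ori, genes = gdf)
}

## per-origin firing probability under a condition
firingProbabilities <- function(genome, cond) {
  o <- origins(genome)
  p <- rep(cond@baseFiringProb, nrow(o))
  if (cond@checkpointIntact)
    p[o$t_rep >= cond@trepCutoff] <- cond@suppressedFiringProb
  names(p) <- o$id
  p
}

#' Simulate replication of a cell population
#'
#' Per cell, each origin fires with its condition-determined probability
#' (see \code{\link{simulationCondition}}): under an intact checkpoint only
#' origins with t_rep below the cutoff fire at the base probability, all
#' others at the suppressed probability; with the checkpoint off, every
#' origin uses the base probability. A fired origin at position x
#' replicates [x - d, x + d] with
#' d = min(forkSpeed * (sDuration - firing time), maxForkTravel). In the
#' HU/MMS regimes permitted origins fire at t = 0 (one synchronous release
#' snapshot); in the unperturbed regime firing times are exponential with
#' mean t_rep, and an origin that is passively replicated by an incoming
#' fork before its own firing time does not count as actively fired.
#'
#' A bin counts as replicated in a cell when its midpoint lies inside a
#' replicated interval.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param cond a \linkS4class{SimulationCondition}.
#' @param nCells number of cells (>= 1).
#' @param seed integer seed; the simulation is bit-reproducible given it.
#' @param firingProb optional per-origin firing probabilities overriding
#'   the condition (recycled to the number of origins).
#' @return A \linkS4class{ReplicationState}.
#' @examples
#' gm <- buildGenome(list(nOrigins = 8))
#' st <- simulateCellPopulation(gm, simulationCondition("HU"), 50, seed = 1)
#' trueFiredFraction(st)
#' @export
simulateCellPopulation <- function(genome, cond, nCells, seed = 1L,
                                   firingProb = NULL) {
  nCells <- as.integer(nCells)
  if (nCells < 1L) stop("nCells must be >= 1")
  o <- origins(genome)
  p <- if (is.null(firingProb)) firingProbabilities(genome, cond) else {
    pp <- rep_len(firingProb, nrow(o))
    if (any(pp < 0 | pp > 1)) stop("firingProb must lie in [0, 1]")
    names(pp) <- o$id
    pp
  }
  sl <- seqLengths(genome)
  bs <- binSize(genome)
  vals <- lapply(names(sl), function(chr)
    numeric(ceiling(sl[[chr]] / bs)))
  names(vals) <- names(sl)
  firedFrac <- stats::setNames(numeric(nrow(o)), o$id)

  withSeed(seed, {
    for (chr in names(sl)) {
      oc <- which(o$chrom == chr)
      n <- length(vals[[chr]])
      if (!length(oc)) next
      mids <- pmin((seq_len(n) - 0.5) * bs, sl[[chr]])
      if (cond@regime %in% c("HU", "MMS")) {
        ## synchronous firing at release: no passive suppression possible
        d <- min(cond@forkSpeed * cond@sDuration, cond@maxForkTravel)
        ## inversion draws: with a fixed seed, firing is monotone-coupled
        ## across probabilities and fork geometries
        F <- matrix(stats::runif(nCells * length(oc)) <
                      rep(p[oc], each = nCells), nrow = nCells)
        firedFrac[oc] <- colMeans(F)
        cover <- lapply(seq_along(oc), function(j)
          which(mids >= o$pos[oc[j]] - d & mids <= o$pos[oc[j]] + d))
        sets <- integer(n)   # signature per bin
        binCov <- vector("list", n)
        for (j in seq_along(oc)) for (b in cover[[j]])
          binCov[[b]] <- c(binCov[[b]], j)
        sig <- vapply(binCov, function(s)
          if (is.null(s)) "" else paste(s, collapse = ","), "")
        for (key in unique(sig[nzchar(sig)])) {
          js <- as.integer(strsplit(key, ",")[[1]])
          covered <- if (length(js) == 1L) F[, js] else
            rowSums(F[, js, drop = FALSE]) > 0L
          vals[[chr]][sig == key] <- sum(covered) / nCells
        }
      } else {
        ## unperturbed: exponential firing delays, passive suppression
        counts <- numeric(n)
        nAct <- stats::setNames(numeric(length(oc)), o$id[oc])
        for (cell in seq_len(nCells)) {
          fired <- stats::runif(length(oc)) < p[oc]
          if (!any(fired)) next
          tf <- stats::rexp(length(oc), rate = 1 / o$t_rep[oc])
          idx <- which(fired & tf < cond@sDuration)
          if (!length(idx)) next
          idx <- idx[order(tf[idx])]
          keep <- logical(length(idx))
          for (k in seq_along(idx)) {
            j <- idx[k]
            passive <- FALSE
            for (m in idx[seq_len(k - 1L)][keep[seq_len(k - 1L)]]) {
              reach <- min(cond@forkSpeed * (tf[j] - tf[m]),
                           cond@maxForkTravel)
              if (abs(o$pos[oc[j]] - o$pos[oc[m]]) <= reach) {
                passive <- TRUE
                break
              }
            }
            keep[k] <- !passive
          }
          act <- idx[keep]
          nAct[act] <- nAct[act] + 1
          covered <- rep(FALSE, n)
          for (j in act) {
            d <- min(cond@forkSpeed * (cond@sDuration - tf[j]),
                     cond@maxForkTravel)
            covered <- covered |
              (mids >= o$pos[oc[j]] - d & mids <= o$pos[oc[j]] + d)
          }
          counts <- counts + covered
        }
        vals[[chr]] <- counts / nCells
        firedFrac[oc] <- nAct / nCells
      }
    }
  })

  new("ReplicationState",
      replicatedFraction = GenomicTrack(vals, binSize = bs, seqlengths = sl,
                                        label = "replicated fraction"),
      nCells = nCells, trueFiredFraction = firedFrac)
}

#' Sample binned sequencing reads from a replication state
#'
#' Emulates the G1 (0 min) and S (arrested) sequencing libraries behind an
#' S/G1 replication profile: per bin, G1 counts are Poisson(depth) and S
#' counts Poisson(depth * (1 + replicated fraction)), so a bin replicated
#' in every cell has twice the expected S coverage. Both libraries share
#' the same mean depth, i.e. they are depth-matched by construction.
#'
#' @param state a \linkS4class{ReplicationState}.
#' @param depth mean reads per bin (> 0).
#' @param seed integer seed.
#' @return list with GenomicTracks \code{g1} and \code{s}.
#' @examples
#' gm <- buildGenome(list(nOrigins = 4))
#' st <- simulateCellPopulation(gm, simulationCondition("HU"), 20, seed = 1)
#' rd <- sampleReads(st, depth = 50, seed = 2)
#' @export
sampleReads <- function(state, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  f <- replicatedFraction(state)
  withSeed(seed, {
    g1 <- trackApply(f, function(v, chr)
      as.numeric(stats::rpois(length(v), depth)), label = "G1 coverage")
    s <- trackApply(f, function(v, chr)
      as.numeric(stats::rpois(length(v), depth * (1 + v))),
      label = "S coverage")
  })
  list(g1 = g1, s = s)
}
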