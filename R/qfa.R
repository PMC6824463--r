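#' Fit a logistic growth model to one culture
#'
#' Least-squares fit of g(t) = K g0 exp(rt) / (K + g0 (exp(rt) - 1)) to a
#' colony density time series, with multi-start Levenberg-Marquardt
#' optimisation: g0 starts at the first density, K at the maximum density,
#' and r at the early log-linear slope (plus bracketing alternatives).
#' Residuals are taken on the log scale: colony-density measurement error
#' is multiplicative, and log-scale least squares is the maximum-likelihood
#' fit under lognormal noise (a raw-scale fit would let the saturation
#' plateau swamp the information on g0 and r). A failed optimisation or a
#' degenerate result (no growth, K <= g0) yields \code{converged = FALSE},
#' never an exception.
#'
#' @param time observation times (days), strictly increasing, >= 4 points.
#' @param density positive culture densities (integrated optical density
#'   units).
#' @return A \linkS4class{LogisticFit} (\code{rss} is on the log scale).
#' @examples
#' t <- seq(0, 5, by = 0.2)
#' fitGrowthCurve(t, logisticDensity(t, K = 1, r = 5, g0 = 2^-10))
#' @export
fitGrowthCurve <- function(time, density) {
  if (length(time) < 4 || length(density) != length(time))
    stop("need >= 4 timepoints with matching densities")
  if (any(diff(time) <= 0)) stop("timepoints must be strictly increasing")
  if (any(density <= 0)) stop("densities must be positive")
  failed <- new("LogisticFit", K = NA_real_, r = NA_real_, g0 = NA_real_,
                converged = FALSE, rss = NA_real_)
  if (stats::sd(density) < 1e-12 * mean(density)) return(failed)

  K0 <- max(density)
  g00 <- max(density[1], K0 * 1e-9)
  ## early log-linear slope for r
  early <- density < K0 / 3
  r0 <- if (sum(early) >= 2) {
    sl <- stats::coef(stats::lm(log(density[early]) ~ time[early]))[2]
    max(sl, 0.1)
  } else 1
  starts <- list(c(K0, r0, g00), c(K0, r0 * 2, g00), c(K0, r0 / 2, g00),
                 c(K0 * 1.2, 1, g00 / 2))
  best <- NULL
  logDensity <- log(density)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        logDensity ~ log(K * g0 * exp(r * time) /
                           (K + g0 * (exp(r * time) - 1))),
        start = list(K = st[1], r = st[2], g0 = st[3]),
        lower = c(K = K0 * 1e-3, r = 0, g0 = K0 * 1e-12),
        upper = c(K = K0 * 100, r = 1e3, g0 = K0 * 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) return(failed)
  co <- best$coef
  if (!(co[["K"]] > co[["g0"]] && co[["g0"]] > 0 && co[["r"]] >= 0))
    return(failed)
  ## no-growth guard: fitted dynamic range indistinguishable from flat
  if (co[["K"]] / co[["g0"]] < 1 + 1e-6) return(failed)
  new("LogisticFit", K = co[["K"]], r = co[["r"]], g0 = co[["g0"]],
      converged = TRUE, rss = best$rss)
}

#' Fitness of a logistic fit: MDP, MDR and F
#'
#' MDP (maximum doubling potential, population doublings) = log2(K/g0);
#' MDR (maximum doubling rate, doublings/day) = (r/ln 2)(1 - g0/K), the
#' maximal instantaneous doubling rate of the logistic solution (attained
#' at inoculation); fitness F = MDP x MDR. An unconverged fit is a dead
#' culture: F = 0, flagged.
#'
#' @param fit a \linkS4class{LogisticFit}.
#' @return named list with mdp, mdr, f, dead.
#' @examples
#' computeFitness(new("LogisticFit", K = 1024, r = log(2), g0 = 1,
#'                    converged = TRUE, rss = 0))   # MDP = 10
#' @export
computeFitness <- function(fit) {
  if (!fit@converged)
    return(list(mdp = 0, mdr = 0, f = 0, dead = TRUE))
  mdp <- log2(fit@K / fit@g0)
  mdr <- (fit@r / log(2)) * (1 - fit@g0 / fit@K)
  list(mdp = mdp, mdr = mdr, f = mdp * mdr, dead = FALSE)
}

#' Fit every culture of a screen and compute replicate fitness
#'
#' @param curves long data.frame with columns gene, background, replicate,
#'   time_days, density (one culture per gene x background x replicate).
#' @return data.frame with one row per culture: gene, background,
#'   replicate, K, r, g0, converged, mdp, mdr, F.
#' @export
screenFitness <- function(curves) {
  need <- c("gene", "background", "replicate", "time_days", "density")
  if (!all(need %in% names(curves)))
    stop("curves must have columns: ", paste(need, collapse = ", "))
  key <- interaction(curves$gene, curves$background, curves$replicate,
                     drop = TRUE)
  rows <- lapply(split(curves, key), function(cc) {
    cc <- cc[order(cc$time_days), ]
    fit <- fitGrowthCurve(cc$time_days, cc$density)
    fo <- computeFitness(fit)
    data.frame(gene = cc$gene[1], background = cc$background[1],
               replicate = cc$replicate[1], K = fit@K, r = fit@r,
               g0 = fit@g0, converged = fit@converged,
               mdp = fo$mdp, mdr = fo$mdr, F = fo$f)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Aggregate replicate fitness per gene and background
#'
#' Means and sds of replicate fitness F per gene x background; genes
#' missing either background (or with fewer than \code{minReps} replicates
#' in one of them) are excluded with a warning.
#'
#' @param repFitness data.frame with columns gene, background, F (e.g. from
#'   \code{\link{screenFitness}} or \code{\link{simulateScreenFitness}}).
#' @param minReps minimum replicates per gene x background (default 2).
#' @return data.frame with gene, F_control, sd_control, n_control, F_query,
#'   sd_query, n_query.
#' @export
aggregateFitness <- function(repFitness, minReps = 2) {
  agg <- function(bg) {
    d <- repFitness[repFitness$background == bg, , drop = FALSE]
    s <- split(d$F, d$gene)
    data.frame(gene = names(s),
               mean = vapply(s, mean, 0),
               sd = vapply(s, stats::sd, 0),
               n = vapply(s, length, 0L))
  }
  ct <- agg("control")
  qr <- agg("query")
  m <- merge(ct, qr, by = "gene", suffixes = c("_control", "_query"))
  keep <- m$n_control >= minReps & m$n_query >= minReps
  excluded <- setdiff(unique(repFitness$gene), m$gene[keep])
  if (length(excluded))
    warning(length(excluded),
            " gene(s) lacking both backgrounds (or enough replicates) excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
  out <- m[keep, , drop = FALSE]
  names(out) <- c("gene", "F_control", "sd_control", "n_control",
                  "F_query", "sd_query", "n_query")
  rownames(out) <- NULL
  out
}

#' Population model of equal growth
#'
#' Robust linear regression (iteratively reweighted least squares with
#' Huber weights) of mean query fitness on mean control fitness across all
#' genes. The robust fit keeps genuine interactions from dragging the
#' "equal growth" line, which summarises the behaviour of the typical
#' (non-interacting) strain.
#'
#' @param records data.frame from \code{\link{aggregateFitness}}.
#' @param minGenes smallest screen the model will be fitted to (default
#'   20 genes with both backgrounds).
#' @return list with intercept \code{a}, slope \code{b}, \code{r_squared}
#'   (weighted), \code{weights}, and the \code{rlm} fit object.
#' @export
populationModel <- function(records, minGenes = 20) {
  if (nrow(records) < minGenes)
    stop("need >= ", minGenes, " genes with both backgrounds")
  if (stats::sd(records$F_control) < 1e-12)
    stop("degenerate variance in control fitness")
  fit <- MASS::rlm(F_query ~ F_control, data = records,
                   psi = MASS::psi.huber, maxit = 100)
  w <- fit$w
  yhat <- stats::fitted(fit)
  ybar <- sum(w * records$F_query) / sum(w)
  r2 <- 1 - sum(w * (records$F_query - yhat)^2) /
    sum(w * (records$F_query - ybar)^2)
  list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
       r_squared = r2, weights = w, fit = fit)
}

#' Genetic interaction strength (GIS)
#'
#' GIS = mean query fitness - population-model prediction from the control
#' fitness. A negative GIS means the deletion grows worse in the query
#' background than the population of strains predicts (an enhancer of the
#' query phenotype); positive means better (a suppressor). Significance is
#' a two-sided one-sample t-test of the replicate-level query fitness
#' against the predicted value, BH-adjusted across genes. Genes with fewer
#' than 2 query replicates get a missing p and are excluded from hit
#' calling.
#'
#' @param records data.frame from \code{\link{aggregateFitness}}.
#' @param model list from \code{\link{populationModel}}.
#' @param repFitness replicate-level data.frame (gene, background, F).
#' @return data.frame with gene, F_control, F_query, predicted_F_query,
#'   gis, p, q.
#' @export
computeGIS <- function(records, model, repFitness) {
  pred <- model$a + model$b * records$F_control
  gis <- records$F_query - pred
  p <- vapply(seq_len(nrow(records)), function(i) {
    fq <- repFitness$F[repFitness$gene == records$gene[i] &
                         repFitness$background == "query"]
    if (length(fq) < 2 || stats::sd(fq) < 1e-12) {
      if (length(fq) >= 2 && isTRUE(all.equal(mean(fq), pred[i])))
        return(1)
      return(NA_real_)
    }
    stats::t.test(fq, mu = pred[i])$p.value
  }, 0)
  data.frame(gene = records$gene, F_control = records$F_control,
             F_query = records$F_query, predicted_F_query = pred,
             gis = gis, p = p, q = stats::p.adjust(p, method = "BH"))
}

#' Classify enhancer and suppressor hits
#'
#' A hit must be significant (BH q below \code{qMax}) \emph{and} have a
#' |GIS| at or above the (1 - \code{topFraction}) quantile of |GIS| over
#' all screened genes (the "top 25 percent" of gene deletions by effect
#' size, ties included). Significant hits with negative GIS are enhancers,
#' with positive GIS suppressors; everything else is neutral.
#'
#' @param gisRecords data.frame from \code{\link{computeGIS}}.
#' @param topFraction fraction of the screen admitted by effect size.
#' @param qMax BH q-value threshold.
#' @return \code{gisRecords} with a \code{hit_class} column (enhancer /
#'   suppressor / neutral).
#' @export
classifyHits <- function(gisRecords, topFraction = 0.25, qMax = 0.05) {
  g <- gisRecords
  g$hit_class <- "neutral"
  ok <- is.finite(g$gis)
  if (any(ok)) {
    cut <- stats::quantile(abs(g$gis[ok]), probs = 1 - topFraction,
                           names = FALSE)
    sig <- !is.na(g$q) & g$q < qMax & ok & abs(g$gis) >= cut
    g$hit_class[sig & g$gis < 0] <- "enhancer"
    g$hit_class[sig & g$gis > 0] <- "suppressor"
  }
  g
}

#' Protein-complex enrichment of a hit set
#'
#' Hypergeometric upper-tail test of the overlap between the hits and each
#' complex of the catalog (cyc2008-style two-column table), restricted to
#' the screened universe, BH-adjusted across complexes.
#'
#' @param hits character vector of hit genes (subset of universe).
#' @param universe character vector of all screened genes.
#' @param catalog data.frame with columns gene, complex.
#' @param minSize smallest in-universe complex tested (default 2).
#' @return data.frame sorted by q with complex, size_universe, n_hits,
#'   overlap, expected, p, q.
#' @export
complexEnrichment <- function(hits, universe, catalog, minSize = 2) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  hits <- unique(hits)
  N <- length(universe)
  n <- length(hits)
  rows <- list()
  for (cx in unique(catalog$complex)) {
    members <- intersect(unique(catalog$gene[catalog$complex == cx]),
                         universe)
    K <- length(members)
    if (K < minSize) next
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      complex = cx, size_universe = K, n_hits = n, overlap = k,
      expected = n * K / N, p = p)
  }
  if (!length(rows))
    return(data.frame(complex = character(), size_universe = integer(),
                      n_hits = integer(), overlap = integer(),
                      expected = numeric(), p = numeric(), q = numeric()))
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$q, res$p), ]
  rownames(res) <- NULL
  res
}

#' Compare two genetic-interaction screens
#'
#' Pairs GIS over the gene intersection of two screens (e.g. HU versus
#' phleomycin), reporting the Spearman correlation and the overlap and
#' Jaccard index of the enhancer and suppressor sets.
#'
#' @param gisA,gisB data.frames from \code{\link{classifyHits}} (must carry
#'   gene, gis, hit_class).
#' @return list with \code{table} (gene, gis_a, gis_b, hit_class_a,
#'   hit_class_b), \code{spearman}, \code{n_shared},
#'   \code{enhancer_overlap}, \code{enhancer_jaccard},
#'   \code{suppressor_overlap}, \code{suppressor_jaccard}.
#' @export
crossScreenCompare <- function(gisA, gisB) {
  shared <- intersect(gisA$gene, gisB$gene)
  if (!length(shared)) stop("screens share no genes")
  if (length(shared) < 20)
    warning("only ", length(shared), " shared genes")
  a <- gisA[match(shared, gisA$gene), ]
  b <- gisB[match(shared, gisB$gene), ]
  tab <- data.frame(gene = shared, gis_a = a$gis, gis_b = b$gis,
                    hit_class_a = a$hit_class, hit_class_b = b$hit_class)
  jacc <- function(x, y) {
    u <- union(x, y)
    if (!length(u)) return(NA_real_)
    length(intersect(x, y)) / length(u)
  }
  enhA <- shared[a$hit_class == "enhancer"]
  enhB <- shared[b$hit_class == "enhancer"]
  supA <- shared[a$hit_class == "suppressor"]
  supB <- shared[b$hit_class == "suppressor"]
  list(table = tab,
       spearman = stats::cor(tab$gis_a, tab$gis_b, method = "spearman",
                             use = "complete.obs"),
       n_shared = length(shared),
       enhancer_overlap = length(intersect(enhA, enhB)),
       enhancer_jaccard = jacc(enhA, enhB),
       suppressor_overlap = length(intersect(supA, supB)),
       suppressor_jaccard = jacc(supA, supB))
}
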