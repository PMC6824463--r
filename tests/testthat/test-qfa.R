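test_that("logistic fitting recovers noiseless parameters to 1e-6", {
  t <- seq(0, 5, by = 1 / 6)
  fit <- fitGrowthCurve(t, logisticDensity(t, K = 1, r = 5, g0 = 2^-10))
  expect_true(fit@converged)
  expect_lt(abs(fit@K - 1), 1e-6)
  expect_lt(abs(fit@r - 5) / 5, 1e-6)
  expect_lt(abs(fit@g0 - 2^-10) / 2^-10, 1e-6)
})

test_that("degenerate cultures fail softly, bad input loudly", {
  t <- seq(0, 5, by = 0.5)
  expect_false(fitGrowthCurve(t, rep(0.4, length(t)))@converged)
  expect_error(fitGrowthCurve(c(0, 1, 2), c(1, 2, 3)), ">= 4")
  expect_error(fitGrowthCurve(c(0, 1, 1, 2), rep(1, 4)), "increasing")
  expect_error(fitGrowthCurve(t, rep(-1, length(t))), "positive")
  ## dead culture: F = 0, flagged
  fo <- computeFitness(fitGrowthCurve(t, rep(0.4, length(t))))
  expect_equal(fo$f, 0)
  expect_true(fo$dead)
})

test_that("r is recovered within 5% under 5% lognormal noise", {
  t <- seq(0, 5, length.out = 30)
  set.seed(200)
  relErr <- replicate(200, {
    d <- logisticDensity(t, 1, 2, 2^-10) * exp(rnorm(30, 0, 0.05))
    fit <- fitGrowthCurve(t, d)
    abs(fit@r - 2) / 2
  })
  expect_lt(median(relErr), 0.05)
})

test_that("MDP and MDR follow their closed forms", {
  fit <- new("LogisticFit", K = 1024, r = log(2), g0 = 1,
             converged = TRUE, rss = 0)
  fo <- computeFitness(fit)
  expect_equal(fo$mdp, 10)                       # log2(1024)
  expect_equal(fo$mdr, (1 - 1 / 1024))           # ~1 doubling/day
  expect_equal(fo$f, fo$mdp * fo$mdr)
  ## g0 << K, r = ln 2 -> MDR ~ 1
  fit2 <- new("LogisticFit", K = 1, r = log(2), g0 = 1e-9,
              converged = TRUE, rss = 0)
  expect_equal(computeFitness(fit2)$mdr, 1, tolerance = 1e-8)
})

test_that("fitness is invariant to a global density rescaling", {
  t <- seq(0, 5, by = 0.25)
  d <- logisticDensity(t, 0.8, 3, 1e-3)
  f1 <- computeFitness(fitGrowthCurve(t, d))
  f2 <- computeFitness(fitGrowthCurve(t, d * 37.5))
  expect_equal(f1$mdp, f2$mdp, tolerance = 1e-6)
  expect_equal(f1$mdr, f2$mdr, tolerance = 1e-6)
  expect_equal(f1$f, f2$f, tolerance = 1e-6)
})

test_that("replicate aggregation means, sds and exclusions", {
  rep4 <- data.frame(gene = "g1", background = rep(c("control", "query"),
                                                   each = 4),
                     F = c(2, 2, 2, 2, 1, 2, 3, 4))
  rec <- aggregateFitness(rep4)
  expect_equal(rec$F_control, 2)
  expect_equal(rec$sd_control, 0)
  expect_equal(rec$F_query, 2.5)
  ## unpaired gene excluded with a warning
  unpaired <- rbind(rep4, data.frame(gene = "g2", background = "control",
                                     F = c(1, 1)))
  expect_warning(rec2 <- aggregateFitness(unpaired), "excluded")
  expect_equal(rec2$gene, "g1")
})

test_that("population model recovers exact linear relations", {
  fc <- seq(5, 40, length.out = 30)
  recEq <- data.frame(gene = paste0("g", 1:30), F_control = fc,
                      sd_control = 0.1, n_control = 4, F_query = fc,
                      sd_query = 0.1, n_query = 4)
  pm <- populationModel(recEq)
  expect_equal(pm$a, 0, tolerance = 1e-8)
  expect_equal(pm$b, 1, tolerance = 1e-8)
  recHalf <- recEq
  recHalf$F_query <- 0.5 * fc
  expect_equal(populationModel(recHalf)$b, 0.5, tolerance = 1e-8)
  expect_error(populationModel(recEq[1:10, ]), ">= 20")
  recFlat <- recEq
  recFlat$F_control <- 10
  expect_error(populationModel(recFlat), "degenerate")
})

test_that("GIS of a screen against itself is zero with p ~ 1", {
  set.seed(5)
  sc <- simulateScreenFitness(40, seed = 2)
  reps <- sc$reps
  reps$F[reps$background == "query"] <-
    reps$F[reps$background == "control"]
  rec <- aggregateFitness(reps)
  pm <- populationModel(rec)
  gis <- computeGIS(rec, pm, reps)
  expect_lt(max(abs(gis$gis)), 1e-8)
  expect_true(all(gis$q > 0.9, na.rm = TRUE))
})

test_that("injected interactions are recovered with correct magnitude", {
  gam <- stats::setNames(c(-0.4, -0.4, 0.45), c("gene003", "gene010",
                                                "gene017"))
  sc <- simulateScreenFitness(100, gamma = gam, reps = 4, noiseSd = 0.05,
                              seed = 31)
  rec <- aggregateFitness(sc$reps)
  pm <- populationModel(rec)
  gis <- computeGIS(rec, pm, sc$reps)
  expect_equal(gis$gis[gis$gene == "gene003"], -0.4, tolerance = 0.25)
  hits <- classifyHits(gis)
  expect_equal(sort(hits$gene[hits$hit_class == "enhancer"]),
               c("gene003", "gene010"))
  expect_equal(hits$gene[hits$hit_class == "suppressor"], "gene017")
})

test_that("hit classes obey the sign and rank rules", {
  ## screen of exactly 100 significant negatives: top 25% = 25 enhancers,
  ## the 25 most negative
  g <- data.frame(gene = sprintf("g%03d", 1:100),
                  F_control = 10, F_query = 10,
                  predicted_F_query = 10,
                  gis = -seq(0.1, 10, length.out = 100),
                  p = 1e-6, q = 1e-5)
  hits <- classifyHits(g, topFraction = 0.25, qMax = 0.05)
  expect_equal(sum(hits$hit_class == "enhancer"), 25)
  expect_true(all(rank(g$gis)[hits$hit_class == "enhancer"] <= 25))
  ## nothing significant -> all neutral
  g$q <- 0.5
  expect_true(all(classifyHits(g)$hit_class == "neutral"))
  ## enhancer implies negative gis and significance
  g$q <- c(rep(1e-5, 50), rep(0.5, 50))
  g$gis[1:25] <- abs(g$gis[1:25])
  h <- classifyHits(g)
  expect_true(all(h$gis[h$hit_class == "enhancer"] < 0))
  expect_true(all(h$q[h$hit_class != "neutral"] < 0.05))
})

test_that("hypergeometric enrichment matches the exact tail", {
  catalog <- data.frame(gene = c(paste0("u", 1:5), paste0("x", 1:3)),
                        complex = c(rep("C5", 5), rep("C3", 3)))
  universe <- c(paste0("u", 1:5), paste0("x", 1:3), paste0("z", 1:92))
  hits <- c(paste0("u", 1:5), paste0("z", 1:5))
  res <- complexEnrichment(hits, universe, catalog)
  ## all 5 of a 5-complex among 10 hits from 100: C(10,5)/C(100,5)
  expect_equal(res$p[res$complex == "C5"],
               choose(10, 5) / choose(100, 5), tolerance = 1e-12)
  ## complexes below minSize in the universe are excluded
  res2 <- complexEnrichment(hits, universe, catalog, minSize = 4)
  expect_false("C3" %in% res2$complex)
  expect_error(complexEnrichment(c("nope"), universe, catalog), "subset")
  expect_error(complexEnrichment(hits, character(), catalog), "empty")
})

test_that("enrichment p-values match subset enumeration on small universes", {
  universe <- paste0("g", 1:18)
  catalog <- data.frame(gene = paste0("g", 1:6), complex = "CX")
  nHits <- 5
  allHitSets <- utils::combn(18, nHits)
  for (k in 1:4) {
    hits <- paste0("g", c(1:k, 15:(15 + (nHits - k) - 1)))
    p <- complexEnrichment(hits, universe, catalog)$p
    ## enumerate P(overlap >= k) over all equally likely hit sets
    ov <- colSums(allHitSets <= 6)
    expect_equal(p, mean(ov >= k), tolerance = 1e-12, info = paste("k =", k))
  }
})

test_that("cross-screen comparison: identity and quadrant behaviour", {
  gam <- stats::setNames(rep(-0.5, 4), sprintf("gene%03d", 1:4))
  sc <- simulateScreenFitness(60, gamma = gam, seed = 12)
  rec <- aggregateFitness(sc$reps)
  pm <- populationModel(rec)
  gis <- classifyHits(computeGIS(rec, pm, sc$reps))
  cmp <- crossScreenCompare(gis, gis)
  expect_equal(cmp$spearman, 1)
  expect_equal(cmp$enhancer_jaccard, 1)
  ## a second screen sharing the injected interactions
  sc2 <- simulateScreenFitness(60, gamma = gam, seed = 13)
  rec2 <- aggregateFitness(sc2$reps)
  gis2 <- classifyHits(computeGIS(rec2, populationModel(rec2), sc2$reps))
  cmp2 <- crossScreenCompare(gis, gis2)
  shared <- cmp2$table
  joint <- shared$gene[shared$hit_class_a == "enhancer" &
                         shared$hit_class_b == "enhancer"]
  expect_setequal(joint, names(gam))
  expect_error(crossScreenCompare(gis, transform(gis2, gene = paste0(gene, "_other"))),
               "share")
})
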