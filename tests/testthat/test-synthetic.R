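cond <- simulationCondition("HU")
condOff <- simulationCondition("HU", checkpointIntact = FALSE)

test_that("buildGenome follows the config arithmetic and is deterministic", {
  gm <- buildGenome(list(chromosomes = c(chrI = 1e6), nOrigins = 40,
                         posJitter = 0))
  expect_equal(nrow(origins(gm)), 40)
  expect_equal(length(trackValues(replicatedFraction(
    simulateCellPopulation(gm, cond, 1, seed = 1)))$chrI), 1000)
  ## regular grid: origins every 25 kb
  expect_equal(diff(origins(gm)$pos), rep(25000, 39))
  gm2 <- buildGenome(list(chromosomes = c(chrI = 1e6), nOrigins = 40,
                          posJitter = 0))
  expect_identical(origins(gm), origins(gm2))
  expect_identical(genes(gm), genes(gm2))
})

test_that("configured gene-pair orientations drive the context classes", {
  gm <- buildGenome(list(nOrigins = 6,
                         pairClasses = c("convergent", "codirectional",
                                         "divergent", "none")))
  ctx <- classifyOriginGeneContext(gm)
  expect_equal(ctx$pair_class[1], "convergent")
  expect_equal(ctx$pair_class[2], "nonconvergent")  # codirectional
  expect_equal(ctx$pair_class[3], "nonconvergent")  # divergent
  expect_equal(ctx$pair_class[4], "unclassified")   # no flanking genes
})

test_that("population simulation has the forced geometries", {
  ## no origins -> nothing replicates
  gm0 <- buildGenome(list(nOrigins = 1))
  o <- origins(gm0)[0, ]
  gm0@origins <- o
  st0 <- simulateCellPopulation(gm0, cond, 10, seed = 1)
  expect_true(all(unlist(trackValues(replicatedFraction(st0))) == 0))
  ## one certain origin, 10 kb max travel -> one 20 kb interval every cell
  gm1 <- buildGenome(list(chromosomes = c(chrI = 2e5), nOrigins = 1,
                          posJitter = 0))
  st1 <- simulateCellPopulation(gm1, cond, 25, seed = 1, firingProb = 1)
  f <- trackValues(replicatedFraction(st1))$chrI
  expect_setequal(unique(f), c(0, 1))
  expect_equal(sum(f) * binSize(gm1), 20000, tolerance = 0.1)
  expect_equal(unname(trueFiredFraction(st1)), 1)
})

test_that("checkpoint suppresses late origins; firing tallies are binomial", {
  gm <- buildGenome(list(nOrigins = 40))
  o <- origins(gm)
  late <- o$t_rep >= 27.5
  stOn <- simulateCellPopulation(gm, cond, 500, seed = 7)
  stOff <- simulateCellPopulation(gm, condOff, 500, seed = 7)
  expect_lt(mean(trueFiredFraction(stOn)[late]), 0.05)
  expect_gt(mean(trueFiredFraction(stOff)[late]), 0.8)
  ## per-origin tallies consistent with the firing probabilities
  expect_equal(mean(trueFiredFraction(stOff)), 0.9,
               tolerance = 3 * sqrt(0.9 * 0.1 / (500 * 40)) / 0.9 + 0.01)
})

test_that("replicated fraction is monotone in p, sDuration and fork travel", {
  gm <- buildGenome(list(nOrigins = 12))
  total <- function(condition, prob = NULL)
    sum(unlist(trackValues(replicatedFraction(
      simulateCellPopulation(gm, condition, 100, seed = 3,
                             firingProb = prob)))))
  for (seedless in 1) {
    t1 <- total(cond, prob = 0.3)
    t2 <- total(cond, prob = 0.6)
    t3 <- total(cond, prob = 0.9)
    expect_true(t1 <= t2 && t2 <= t3)
    c1 <- simulationCondition("HU", sDuration = 2)
    c2 <- simulationCondition("HU", sDuration = 5)
    expect_lte(total(c1), total(c2))
    c3 <- simulationCondition("HU", maxForkTravel = 3000)
    c4 <- simulationCondition("HU", maxForkTravel = 9000)
    expect_lte(total(c3), total(c4))
  }
})

test_that("unperturbed regime fires with delays and passive suppression", {
  gm <- buildGenome(list(chromosomes = c(chrI = 1e5), nOrigins = 4,
                         posJitter = 0, trepValues = c(5, 16, 30, 30)))
  cu <- simulationCondition("unperturbed", baseFiringProb = 1,
                            forkSpeed = 1500, maxForkTravel = 5e4,
                            sDuration = 120)
  st <- simulateCellPopulation(gm, cu, 300, seed = 2)
  tf <- trueFiredFraction(st)
  ## early origin nearly always fires actively; a late neighbour 25 kb away
  ## is often passively replicated first
  expect_gt(tf[["ori01"]], 0.9)
  expect_lt(tf[["ori02"]], 0.9)
  expect_true(all(unlist(trackValues(replicatedFraction(st))) <= 1))
})

test_that("read sampling matches Poisson expectations and totals", {
  gm <- buildGenome(list(nOrigins = 10))
  st <- simulateCellPopulation(gm, condOff, 200, seed = 11)
  f <- unlist(trackValues(replicatedFraction(st)))
  rd <- sampleReads(st, depth = 100, seed = 12)
  g1 <- unlist(trackValues(rd$g1))
  s <- unlist(trackValues(rd$s))
  expect_equal(mean(g1), 100, tolerance = 0.02)
  ## expected totals: depth * (n_bins + sum f)
  expT <- 100 * (length(f) + sum(f))
  expect_lt(abs(sum(s) - expT), 5 * sqrt(expT))
  ## identical seed -> identical draws
  rd2 <- sampleReads(st, depth = 100, seed = 12)
  expect_identical(trackValues(rd2$s), trackValues(rd$s))
  ## fully replicated vs unreplicated flat states
  st@replicatedFraction <- trackApply(replicatedFraction(st),
                                      function(v, chr) rep(1, length(v)))
  r2 <- sampleReads(st, depth = 200, seed = 3)
  expect_equal(mean(unlist(trackValues(r2$s))) /
                 mean(unlist(trackValues(r2$g1))), 2, tolerance = 0.05)
})

test_that("damage simulator is proportional to replication", {
  gm <- buildGenome(list(nOrigins = 10))
  st <- simulateCellPopulation(gm, condOff, 300, seed = 4)
  ## beta 0: ip/control correlates with replicated fraction
  dm <- simulateDamageTracks(st, gm, damageTruth(betaConvergent = 0),
                             seed = 5)
  f <- unlist(trackValues(replicatedFraction(st)))
  ratio <- unlist(trackValues(normalizeChip(dm$ip, dm$control)))
  ok <- is.finite(ratio)
  expect_gt(cor(ratio[ok], f[ok]), 0.8)
  ## unreplicated genome: ip stays at the background floor
  st0 <- st
  st0@replicatedFraction <- trackApply(replicatedFraction(st),
                                       function(v, chr) rep(0, length(v)))
  dm0 <- simulateDamageTracks(st0, gm, damageTruth(), seed = 6)
  expect_lt(mean(unlist(trackValues(dm0$ip))), 0.05 * 100)
})

test_that("growth-curve generator validates input and honours truth", {
  expect_error(simulateGrowthCurves(nGenes = 5, timepoints = c(0, 1, 1, 2)),
               "strictly increasing")
  sim <- simulateGrowthCurves(nGenes = 4, reps = 2, fitnessNoiseSd = 0,
                              densityNoiseSd = 0, seed = 8,
                              timepoints = seq(0, 5, by = 0.25))
  ## noiseless: the fitted curve recovers each replicate's target fitness
  sf <- screenFitness(sim$curves)
  m <- merge(sf, sim$reps, by = c("gene", "background", "replicate"))
  expect_lt(max(abs(m$F.x - m$F.y)), 1e-5)
})

test_that("plasmid-count simulator matches the loss formula", {
  ## rate 0: no loss
  expect_equal(simulatePlasmidCounts(0, 5, 400, seed = 1)$nSelective, 400)
  ## rate 50, G = 1: half kept in expectation
  ns <- vapply(1:200, function(s)
    simulatePlasmidCounts(50, 1, 1000, seed = s)$nSelective, 0L)
  expect_equal(mean(ns), 500, tolerance = 0.02)
  ## rate 6.697, G = 10: RMP 0.5
  expect_equal(simulatePlasmidCounts(6.697, 10, 10, seed = 1)$RMP, 0.5,
               tolerance = 1e-4)
})

test_that("catenane simulator collapses, normalizes and shifts", {
  expect_equal(medianCatenane(simulateCatenaneDistribution(7, 0, 20)), 7)
  d <- simulateCatenaneDistribution(6, 2, 25)
  expect_equal(sum(catWeights(d)), 1)
  meds <- vapply(seq(2, 14, by = 2), function(m)
    medianCatenane(simulateCatenaneDistribution(m, 1.5, 30)), 0L)
  expect_true(all(diff(meds) > 0))
})

test_that("simulators are bit-reproducible under a fixed seed", {
  gm <- buildGenome(list(nOrigins = 6))
  a <- simulateCellPopulation(gm, cond, 50, seed = 42)
  b <- simulateCellPopulation(gm, cond, 50, seed = 42)
  expect_identical(trackValues(replicatedFraction(a)),
                   trackValues(replicatedFraction(b)))
  expect_identical(trueFiredFraction(a), trueFiredFraction(b))
  expect_identical(simulateScreenFitness(20, seed = 9)$reps,
                   simulateScreenFitness(20, seed = 9)$reps)
})
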