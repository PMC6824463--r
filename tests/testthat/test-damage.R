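test_that("ChIP normalization is an anchored ratio with masking", {
  n <- 300
  ip <- gt1(rep(50, n))
  ## ip = control -> 1 everywhere
  expect_equal(unique(trackValues(normalizeChip(ip, ip, pseudocount = 0))$chrI),
               1)
  ## doubled bin -> ~2 there, ~1 elsewhere (large counts, tiny pseudocount)
  ip2 <- gt1(c(rep(1000, n - 1), 2000))
  ctl <- gt1(rep(1000, n))
  r <- trackValues(normalizeChip(ip2, ctl, pseudocount = 1))$chrI
  expect_equal(r[n] / r[1], 2, tolerance = 0.01)
  ## control below floor -> missing
  ctl2 <- ctl
  ctl2@values$chrI[7] <- 0
  r2 <- trackValues(normalizeChip(ip2, ctl2, pseudocount = 1,
                                  controlFloor = 0.5))$chrI
  expect_true(is.na(r2[7]))
  expect_error(normalizeChip(ip, gt1(rep(1, 10))), "binning")
})

test_that("replication normalization divides and masks, never explodes", {
  n <- 100
  sm <- rep(1.5, n)          # 0.5 replicated
  sm[40:60] <- 1.0           # unreplicated stretch
  pr <- new("ReplicationProfile", rawRatio = gt1(sm), smoothed = gt1(sm),
            cutoffWavelength = 20000)
  chip <- gt1(rep(0.5, n))   # equals the replication amount where present
  out <- trackValues(normalizeByReplication(chip, pr))$chrI
  expect_equal(unique(out[-(40:60)]), 1)
  expect_true(all(is.na(out[40:60])))
  expect_false(any(is.infinite(out)))
  expect_error(normalizeByReplication(chip, pr, minReplication = 0),
               "minReplication")
})

test_that("metaprofiles average aligned windows and split by T_rep", {
  gm <- buildGenome(list(nOrigins = 10))
  track <- gt1(rep(2.5, 1000))
  mp <- metaOriginProfile(track, origins(gm), halfWindow = 5000)
  expect_true(all(mp$mean_all == 2.5))
  expect_true(all(mp$mean_early == 2.5 | mp$n_early == 0))
  expect_equal(nrow(mp), 11)
  ## all-early genome: late profile empty with explicit n = 0
  o <- origins(gm)
  o$t_rep <- 16
  mp2 <- metaOriginProfile(track, o, halfWindow = 5000)
  expect_true(all(mp2$n_late == 0))
  expect_true(all(is.nan(mp2$mean_late)))
  ## t_rep exactly at the cutoff counts as early
  o$t_rep <- 27.5
  mp3 <- metaOriginProfile(track, o, halfWindow = 5000)
  expect_true(all(mp3$n_early == nrow(o)))
  ## windows truncated at chromosome ends still average correctly
  oEdge <- data.frame(id = "e", chrom = "chrI", pos = 1500, t_rep = 20,
                      status = "confirmed")
  mp4 <- metaOriginProfile(track, oEdge, halfWindow = 5000)
  expect_equal(mp4$n_all[1], 0)   # off-chromosome offset
  expect_equal(mp4$mean_all[mp4$offset_bp == 0], 2.5)
  expect_error(metaOriginProfile(track, origins(gm), halfWindow = 2500),
               "multiple")
})

test_that("gene-pair orientation classification follows the definitions", {
  ori <- data.frame(id = "o", chrom = "chrI", pos = 50000, t_rep = 20,
                    status = "confirmed")
  mkGenes <- function(sl, sr)
    data.frame(id = c("L", "R"), chrom = "chrI",
               start = c(44000, 53000), end = c(46000, 55000),
               strand = c(sl, sr))
  cls <- function(g) classifyOriginGeneContext(ori, g)$pair_class
  expect_equal(cls(mkGenes("+", "-")), "convergent")
  expect_equal(cls(mkGenes("-", "+")), "nonconvergent")  # divergent
  expect_equal(cls(mkGenes("+", "+")), "nonconvergent")  # codirectional
  expect_equal(cls(mkGenes("-", "-")), "nonconvergent")
  ## origin inside a gene body is unclassified
  inside <- data.frame(id = "G", chrom = "chrI", start = 49000,
                       end = 51000, strand = "+")
  expect_equal(cls(rbind(mkGenes("+", "-"), inside)), "unclassified")
  ## no flanking gene within scan range
  far <- mkGenes("+", "-")
  far$start <- far$start - 40000
  far$end <- far$end - 40000
  expect_equal(cls(far), "unclassified")
})

test_that("strand flip maps convergent to divergent and back", {
  gm <- buildGenome(list(nOrigins = 12))
  ctx <- classifyOriginGeneContext(gm)
  g2 <- genes(gm)
  g2$strand <- ifelse(g2$strand == "+", "-", "+")
  ctx2 <- classifyOriginGeneContext(origins(gm), g2)
  ## convergent <-> divergent subcase; codirectional stays nonconvergent
  wasConv <- ctx$pair_class == "convergent"
  expect_true(all(ctx2$pair_class[wasConv] == "nonconvergent"))
  isConvNow <- ctx2$pair_class == "convergent"
  expect_true(all(ctx$pair_class[isConvNow] == "nonconvergent"))
  expect_equal(sum(ctx$pair_class == "unclassified"),
               sum(ctx2$pair_class == "unclassified"))
})

test_that("T_rep binning reduces to class means and flags empties", {
  gm <- buildGenome(list(nOrigins = 12))
  ctx <- classifyOriginGeneContext(gm)
  const <- gt1(rep(1.7, 1000))
  ## single [0, Inf) bin: one row per class at the grand mean
  tab <- binnedDamageByTrep(const, ctx, binEdges = c(0, Inf))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$mean_enrichment == 1.7))
  expect_setequal(tab$pair_class, c("convergent", "nonconvergent"))
  ## constant track: every populated row equals the constant, no trend
  tab2 <- suppressWarnings(binnedDamageByTrep(const, ctx))
  expect_true(all(tab2$mean_enrichment == 1.7))
  ## empty bins are dropped with a warning
  expect_warning(binnedDamageByTrep(const, ctx,
                                    binEdges = c(0, 5, 15, 40)),
                 "dropped")
})

test_that("replication normalization cancels replication when beta = 0", {
  ## early vs late normalized damage indistinguishable over seeds
  gm <- buildGenome(list(nOrigins = 20))
  o <- origins(gm)
  pv <- vapply(1:8, function(s) {
    st <- simulateCellPopulation(
      gm, simulationCondition("HU", checkpointIntact = FALSE), 300,
      seed = s)
    dm <- simulateDamageTracks(st, gm, damageTruth(betaConvergent = 0),
                               seed = s + 50)
    rd <- sampleReads(st, depth = 60, seed = s + 100)
    pr <- replicationProfile(rd$s, rd$g1, normalize = "none")
    nd <- normalizeByReplication(normalizeChip(dm$ip, dm$control), pr)
    enr <- vapply(seq_len(nrow(o)), function(i) {
      v <- trackValues(nd)[[o$chrom[i]]]
      b <- (o$pos[i] - 1) %/% 1000 + 1
      mean(v[max(1, b - 2):min(length(v), b + 2)], na.rm = TRUE)
    }, 0)
    early <- o$t_rep <= 27.5
    stats::t.test(enr[early], enr[!early])$p.value
  }, 0)
  ## no systematic early/late difference at alpha 0.01
  expect_gt(mean(pv > 0.01), 0.85)
})

test_that("metaprofile of a shuffled track is flat", {
  gm <- buildGenome(list(nOrigins = 20))
  st <- simulateCellPopulation(gm, simulationCondition("HU"), 200, seed = 3)
  dm <- simulateDamageTracks(st, gm, damageTruth(), seed = 4)
  v <- trackValues(dm$ip)$chrI
  set.seed(9)
  shuffled <- gt1(sample(v))
  mp <- metaOriginProfile(shuffled, origins(gm), halfWindow = 10000)
  ## flat within Monte-Carlo error of the position-wise means
  mcErr <- sd(v) / sqrt(nrow(origins(gm)))
  expect_lt(max(abs(mp$mean_all - mean(v))), 4 * mcErr)
  ## whereas the aligned metaprofile shows real structure at the origin
  mpA <- metaOriginProfile(dm$ip, origins(gm), halfWindow = 10000)
  expect_gt(max(mpA$mean_all) - min(mpA$mean_all), 4 * mcErr)
})
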