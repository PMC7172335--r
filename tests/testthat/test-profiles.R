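test_that("anchored profiles reproduce constant and triangular signals", {
  pos <- seq(1, 20001, by = 33)
  tr <- makeTrack(pos, rep(2.5, length(pos)))
  anchors <- GRanges("chr1", IRanges(c(5001, 12001), width = 1), strand = "+")
  pm <- anchoredProfile(tr, anchors, span = c(-2000, 2000), window = 100)
  agg <- profileAggregate(pm)
  expect_true(all(abs(agg[!is.na(agg)] - 2.5) < 1e-12))
  ## triangular signal peaking at the anchor: aggregate maximal at 0
  apex <- 1 + 33 * 242   # on the probe grid
  vals <- pmax(0, 1000 - abs(pos - apex)) / 1000
  tr2 <- makeTrack(pos, vals)
  a2 <- GRanges("chr1", IRanges(apex, width = 1), strand = "+")
  pm2 <- anchoredProfile(tr2, a2, span = c(-1500, 1500), window = 10)
  agg2 <- profileAggregate(pm2)
  p0 <- which(profilePositions(pm2) == 0)
  expect_equal(agg2[p0], max(agg2, na.rm = TRUE))
  expect_equal(agg2[p0], 1)
  ## direct per-position recomputation oracle on a subsample
  rel <- pos - apex
  for (p in c(-1500, -777, -100, 0, 3, 250, 1499)) {
    i <- which(profilePositions(pm2) == p)
    expect_equal(agg2[i], oracleProfilePoint(rel, vals, p, 10),
                 tolerance = 1e-12)
  }
})

test_that("minus-strand anchors are reflected and aggregates are stable", {
  pos <- seq(1, 10001, by = 33)
  vals <- sin(pos / 500)
  tr <- makeTrack(pos, vals)
  aPlus <- GRanges("chr1", IRanges(5001, width = 1), strand = "+")
  aMinus <- GRanges("chr1", IRanges(5001, width = 1), strand = "-")
  pp <- anchoredProfile(tr, aPlus, span = c(-1000, 1000), window = 50)
  pmn <- anchoredProfile(tr, aMinus, span = c(-1000, 1000), window = 50)
  ## with the window convention [p - w/2, p + w/2), reflection maps the
  ## window at +p onto the window at -p shifted by one probe-position, so
  ## compare against the direct flipped-oracle rather than pure mirroring
  rel <- 5001 - pos
  for (p in c(-900, -333, 0, 250, 897)) {
    i <- which(profilePositions(pmn) == p)
    expect_equal(profileAggregate(pmn)[i],
                 oracleProfilePoint(rel, vals, p, 50), tolerance = 1e-12)
  }
  ## n identical anchors give the single-anchor profile
  many <- rep(aPlus, 5)
  pm5 <- anchoredProfile(tr, many, span = c(-1000, 1000), window = 50)
  expect_equal(profileAggregate(pm5), profileAggregate(pp))
  ## median statistic matches the oracle too
  pmed <- anchoredProfile(tr, aPlus, span = c(-500, 500), window = 100,
                          stat = "median")
  relF <- pos - 5001
  for (p in c(-500, -99, 0, 42, 500)) {
    i <- which(profilePositions(pmed) == p)
    expect_equal(profileAggregate(pmed)[i],
                 oracleProfilePoint(relF, vals, p, 100, "median"),
                 tolerance = 1e-12)
  }
})

test_that("domain boundary anchors point into the domain from both edges", {
  ## signal is a step up inside the domain; both edges must show the step
  ## at positive (inward) relative positions
  pos <- seq(1, 60001, by = 33)
  dom <- GRanges("chr1", IRanges(20001, 40000))
  vals <- ifelse(pos >= 20001 & pos <= 40000, 3, 0)
  tr <- makeTrack(pos, vals)
  pm <- anchoredProfile(tr, boundaryAnchors(dom), span = c(-3000, 3000),
                        window = 100)
  agg <- profileAggregate(pm)
  posGrid <- profilePositions(pm)
  expect_gt(mean(agg[posGrid > 500], na.rm = TRUE), 2.5)
  expect_lt(mean(agg[posGrid < -500], na.rm = TRUE), 0.5)
})

test_that("pooled domain signal test detects shifts with the right sign", {
  pos <- seq(1, 30001, by = 33)
  dom <- GRanges("chr1", IRanges(5001, 25000))
  inD <- pos >= 5001 & pos <= 25000
  ## identical conditions: t = 0, p = 1
  v <- rnorm(length(pos))
  trSame <- makeTrack2(pos, v, v)
  r0 <- domainSignalTest(trSame, dom)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  ## noiseless constant shift: p -> 0 and the mean difference is delta
  tr1 <- makeTrack2(pos, rep(2, length(pos)), rep(1.25, length(pos)))
  r1 <- domainSignalTest(tr1, dom)
  expect_equal(r1$p, 0)
  expect_equal(r1$mean_ctrl - r1$mean_mut, 0.75)
  ## too few probes inside domains errors
  expect_error(domainSignalTest(tr1, GRanges("chr1", IRanges(1, 10))),
               "insufficient")
})

test_that("Pol II classification applies length, tie, and direction rules", {
  ## gene shorter than 1 kb is excluded
  gm <- makeGenes("chr1", c(2000, 6000), c(2998, 9000), c("+", "+"),
                  ids = c("short", "long"))
  pos <- seq(1, 10001, by = 33)
  trTie <- makeTrack2(pos, rep(1, length(pos)), rep(1, length(pos)))
  cl <- classifyPolII(trTie, gm)
  expect_equal(as.character(cl$category), c("excluded", "excluded"))
  expect_equal(cl$reason, c("short_gene", "tie"))
  ## directional calls
  ctrl <- rep(1, length(pos))
  mutUp <- ctrl + (pos >= 5970 & pos <= 6300) * 1   # raise paused region
  cl2 <- classifyPolII(makeTrack2(pos, ctrl, mutUp), gm)
  expect_equal(as.character(cl2$category[cl2$gene_id == "long"]), "2")
  mutDn <- ctrl - (pos >= 5970 & pos <= 6300) * 0.5
  cl3 <- classifyPolII(makeTrack2(pos, ctrl, mutDn), gm)
  expect_equal(as.character(cl3$category[cl3$gene_id == "long"]), "1")
})

test_that("region tests control the null and match exact references", {
  ## identical conditions: rank test p = 1, nothing significant
  sim <- simulateAnnotation(nChrom = 2, chromLen = 300000, nGenes = 60,
                            dpgFraction = 0.2, seed = 17)
  pos <- seq(1, 300000, by = 100)
  v <- rnorm(2 * length(pos))
  tr <- ProbeTrack(rep(c("chr1", "chr2"), each = length(pos)),
                   rep(pos, 2), cbind(v, v), probeLength = 50,
                   condition = c("control", "mutant"))
  rt <- regionTest(tr, sim$genes, region = "k27", test = "mannwhitney")
  tested <- !rt$skipped
  expect_true(all(rt$p[tested] > 0.99))
  expect_equal(sum(rt$q[tested] < 0.05), 0)
  ## Mann-Whitney on {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  gm1 <- makeGenes("chr1", 1000, 4000, "+", ids = "g1")
  tr1 <- makeTrack2(c(1200, 1500, 1800), c(1, 2, 3), c(4, 5, 6))
  rt1 <- regionTest(tr1, gm1, region = "k4", test = "mannwhitney")
  expect_equal(rt1$p, 0.1)
  expect_equal(rt1$direction, "up")
  ## t-test route with a real difference
  tr2 <- makeTrack2(seq(1200, 2900, by = 100), rnorm(18, 0, 0.1),
                    rnorm(18, 2, 0.1))
  rt2 <- regionTest(tr2, gm1, region = "k4", test = "ttest")
  expect_lt(rt2$p, 1e-6)
  ## genes without probes are skipped with a reason
  gmF <- makeGenes("chr1", c(1000, 50000), c(4000, 55000), c("+", "+"))
  rtF <- regionTest(tr1, gmF, region = "k4")
  expect_true(rtF$skipped[2])
  expect_equal(rtF$reason[2], "no_probes")
})

test_that("profile smoothing is a shrinking-window moving average", {
  expect_equal(smoothProfile(rep(3, 50), 7), rep(3, 50))
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(smoothProfile(imp, 3), c(0, 0, 1/3, 1/3, 1/3, 0, 0))
  set.seed(81)
  y <- rnorm(200)
  got <- smoothProfile(y, 9)
  want <- vapply(seq_along(y), function(i)
    mean(y[max(1, i - 4):min(200, i + 4)]), numeric(1))
  expect_equal(got, want)
})

test_that("fold categories honor the published boundaries", {
  f <- c(1.99, 2, 3, 5, 5.01, 10, 10.5)
  expect_equal(as.character(foldCategory(f)),
               c("none", "moderate", "moderate", "moderate", "high",
                 "high", "maximal"))
  expect_error(foldCategory(0), "positive")
})

test_that("chromatin change classes combine the two marks correctly", {
  k27 <- data.frame(gene_id = c("a", "b", "c", "d"),
                    q = c(0.01, 0.01, 0.5, 0.01),
                    direction = c("down", "down", "down", "up"))
  k4 <- data.frame(gene_id = c("a", "b", "c", "d"),
                   q = c(0.5, 0.01, 0.01, 0.5),
                   direction = c("up", "up", "up", "down"))
  cls <- chromatinChangeClass(k27, k4, 0.05)
  expect_equal(as.character(cls$class),
               c("K27depletedOnly", "both", "K4enrichedOnly", "unchanged"))
  expect_error(chromatinChangeClass(k27, k4[1:3, ]), "same genes")
})
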