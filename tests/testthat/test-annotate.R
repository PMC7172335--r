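test_that("promoter rule and ranking behave as specified", {
  ## + gene with TSS at 1001: promoter is [801, 1000]
  gm <- makeGenes("chr1", 1001, 3000, "+")
  pk <- GRanges("chr1", IRanges(901, 950))
  expect_equal(as.character(assignFeature(pk, gm)), "promoter")
  ## a peak over one gene's intron and another's promoter ranks promoter
  gm2 <- makeGenes("chr1", c(1000, 5300), c(5000, 7000), c("+", "+"),
                   ids = c("gA", "gB"))
  ## gA exons cover [1000,2000] and [4000,5000]; intron (2001,3999)
  exl <- GRangesList(gA = GRanges("chr1", IRanges(c(1000, 4000), c(2000, 5000))),
                     gB = GRanges("chr1", IRanges(5300, 7000)))
  gm2 <- GeneModels(geneRanges(gm2), exl)
  pk2 <- GRanges("chr1", IRanges(3000, 5200))  # gA intron + gB promoter
  expect_equal(as.character(assignFeature(pk2, gm2)), "promoter")
  ## minus-strand promoter mirrors downstream in genome coordinates
  gmM <- makeGenes("chr1", 1000, 3000, "-")   # TSS at 3000
  expect_equal(as.character(assignFeature(GRanges("chr1", IRanges(3050, 3100)), gmM)),
               "promoter")
})

test_that("feature calls match the exhaustive oracle and fractions sum to 1", {
  sim <- simulateAnnotation(nChrom = 2, chromLen = 250000, nGenes = 40,
                            dpgFraction = 0.3, seed = 5)
  set.seed(6)
  n <- 200
  pk <- GRanges(sample(c("chr1", "chr2"), n, TRUE),
                IRanges(sample.int(249000, n), width = sample(50:800, n, TRUE)))
  got <- as.character(assignFeature(pk, sim$genes))
  want <- vapply(seq_len(n), function(i)
    oracleAssignFeature(start(pk)[i], end(pk)[i], sim$genes,
                        as.character(seqnames(pk))[i]), character(1))
  expect_equal(got, want)
  expect_equal(sum(table(got)) / n, 1)
})

test_that("TSS distances are signed in gene orientation", {
  gm <- makeGenes("chr1", c(1000, 6000), c(3000, 9000), c("+", "-"))
  ## peak midpoint exactly at the + TSS
  expect_equal(tssDistance(GRanges("chr1", IRanges(990, 1010)), gm), 0)
  ## 100 bp 5' of the minus gene's TSS (TSS = 9000, upstream = higher coords)
  expect_equal(tssDistance(GRanges("chr1", IRanges(9090, 9110)), gm), -100)
  ## random peaks match the all-TSS scan oracle
  sim <- simulateAnnotation(nChrom = 2, chromLen = 250000, nGenes = 40,
                            dpgFraction = 0.2, seed = 8)
  set.seed(9)
  pk <- GRanges(sample(c("chr1", "chr2"), 100, TRUE),
                IRanges(sample.int(249000, 100), width = 100))
  got <- tssDistance(pk, sim$genes)
  mid <- floor((start(pk) + end(pk)) / 2)
  want <- vapply(seq_len(100), function(i)
    oracleTssDistance(mid[i], sim$genes, as.character(seqnames(pk))[i]),
    numeric(1))
  expect_equal(abs(got), abs(want))
})

test_that("divergent pair discovery matches the rules and the oracle", {
  ## minus TSS 5000, plus TSS 5800: one pair with gap 800
  gm <- makeGenes("chr1", c(3000, 5800), c(5000, 8000), c("-", "+"),
                  ids = c("gm", "gp"))
  dp <- findDPGs(gm)
  expect_equal(nrow(dp), 1)
  expect_equal(dp$tss_gap, 800)
  ## gap 1001 is out
  gm2 <- makeGenes("chr1", c(3000, 6001), c(5000, 8000), c("-", "+"))
  expect_equal(nrow(findDPGs(gm2)), 0)
  ## gap exactly 1000 is in; gap 0 allowed
  gm3 <- makeGenes("chr1", c(3000, 6000, 10000), c(5000, 8000, 12000),
                   c("-", "+", "-"))
  expect_equal(findDPGs(gm3)$tss_gap, 1000)
  ## excluded ids are skipped
  gmX <- makeGenes("chr1", c(3000, 5800), c(5000, 8000), c("-", "+"),
                  ids = c("his1", "gp"))
  expect_equal(nrow(findDPGs(gmX, pipelineConfig(excludeGenes = "his1"))), 0)
  ## random annotation equals all-pairs oracle, and planted pairs recover
  sim <- simulateAnnotation(nChrom = 3, chromLen = 350000, nGenes = 90,
                            dpgFraction = 0.4, seed = 21)
  got <- findDPGs(sim$genes)
  want <- oracleDPGs(sim$genes)
  expect_equal(got$gene_minus, want$gene_minus)
  expect_equal(got$gene_plus, want$gene_plus)
  expect_equal(got$tss_gap, want$tss_gap)
  tr <- sim$truth$dpgs[order(sim$truth$dpgs$gene_minus), ]
  expect_equal(got$gene_minus, tr$gene_minus)
  expect_equal(got$tss_gap, tr$tss_gap)
})

test_that("planted pair count follows the requested fraction", {
  sim <- simulateAnnotation(nChrom = 2, chromLen = 400000, nGenes = 100,
                            dpgFraction = 0.5, geneLenRange = c(1500, 3000),
                            seed = 3)
  expect_equal(nrow(sim$truth$dpgs), 25)
  sim0 <- simulateAnnotation(nChrom = 2, chromLen = 400000, nGenes = 60,
                             dpgFraction = 0, seed = 3)
  expect_equal(nrow(findDPGs(sim0$genes)), 0)
})

test_that("DPG bound rule covers both flanks and the inter-TSS span", {
  gm <- makeGenes("chr1", c(3000, 5800), c(5000, 8000), c("-", "+"),
                  ids = c("gm", "gp"))
  dp <- findDPGs(gm)  # TSS- = 5000, TSS+ = 5800; region [4500, 6300]
  midPeak <- GRanges("chr1", IRanges(5300, 5400))
  expect_true(dpgBound(midPeak, dp, gm))
  ## 600 bp downstream of both TSSs, outside the span: not bound
  farPeak <- GRanges("chr1", IRanges(4300, 4390))
  expect_false(dpgBound(farPeak, dp, gm))
  expect_true(dpgBound(GRanges("chr1", IRanges(4400, 4500)), dp, gm))  # edge
  ## random peak sets agree with explicit union-region oracle
  set.seed(31)
  for (i in 1:50) {
    pk <- GRanges("chr1", IRanges(sample.int(9000, 5), width = 80))
    got <- dpgBound(pk, dp, gm)
    want <- any(start(pk) <= 6300 & end(pk) >= 4500)
    expect_equal(got, want)
  }
})

test_that("boundary proximity uses inclusive expansion", {
  bnd <- GRanges("chr1", IRanges(20000, 20000))
  ## peak ending exactly 5000 bp before the boundary: hit at slack 5000
  expect_true(nearBoundary(GRanges("chr1", IRanges(14900, 15000)), bnd, 5000)$hit)
  expect_false(nearBoundary(GRanges("chr1", IRanges(14800, 14999)), bnd, 5000)$hit)
  expect_equal(nearBoundary(GRanges(), bnd, 5000)$fraction, 0)
  expect_error(nearBoundary(GRanges(), bnd, -1), "slack")
  ## paired-edge summary
  dom <- GRanges("chr1", IRanges(c(10000, 50000), c(30000, 80000)))
  pk <- GRanges("chr1", IRanges(c(9000, 29000, 52000), width = 100))
  db <- domainBoundaryBinding(pk, dom, 5000)
  expect_equal(db$n_hit, c(2, 1))
})
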