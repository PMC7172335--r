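test_that("background fitting recovers composition and conditionals", {
  bgA <- suppressWarnings(fitBackground("AAAA", order = 0, pseudocount = 0))
  expect_equal(unname(bgA@marginal["A"]), 1)
  bgU <- suppressWarnings(fitBackground("ACGT", order = 0, pseudocount = 0))
  expect_equal(unname(bgU@marginal), rep(0.25, 4))
  ## order-2 conditionals match a hand-counting oracle
  set.seed(91)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE,
                    prob = c(0.4, 0.1, 0.2, 0.3)), collapse = "")
  bg2 <- suppressWarnings(fitBackground(s, order = 2, pseudocount = 0))
  ch <- strsplit(s, "")[[1]]
  ctx <- paste0(ch[1:9998], ch[2:9999])
  nxt <- ch[3:10000]
  for (cc in c("AA", "CG", "TA", "GT")) {
    sel <- ctx == cc
    for (b in c("A", "C", "G", "T")) {
      expect_equal(unname(bg2@transitions[cc, b]),
                   sum(sel & nxt == b) / sum(sel), tolerance = 1e-12)
    }
  }
  ## every conditional row is a proper distribution
  expect_true(all(abs(rowSums(bg2@transitions) - 1) < 1e-9))
  expect_error(fitBackground("ACGT", order = -1), "order")
})

test_that("a deterministic PWM hits exactly at literal matches", {
  pwm <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[1, "A"] <- 1; pwm[2, "A"] <- 1; pwm[3, "C"] <- 1; pwm[4, "G"] <- 1
  bg <- fitBackground("ACGTACGTACGT", order = 0, pseudocount = 1)
  seqs <- Biostrings::DNAStringSet(c(s1 = "TTAACGTTTTCGTTAA"))
  ## AACG at 3 (+); CGTT (= revcomp AACG) at 5 and 11 (-)
  hits <- scanPwm(seqs, pwm, bg, pThresh = 0.01)
  expect_equal(hits$start[hits$strand == "+"], 3)
  expect_equal(sort(hits$start[hits$strand == "-"]), c(5, 11))
  ## p of the exact word under near-uniform background is (1/4)^4-ish
  expect_true(all(hits$p < 0.01))
  ## zero threshold yields nothing
  expect_equal(nrow(scanPwm(seqs, pwm, bg, pThresh = 0)), 0)
})

test_that("DP score p-values equal exhaustive enumeration over all words", {
  bgU <- fitBackground(paste(rep("ACGT", 100), collapse = ""),
                       order = 0, pseudocount = 0)
  gran <- 1e-3
  set.seed(101)
  for (rep in 1:12) {
    pwm <- matrix(runif(16, 0.02, 1), 4, 4)
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- c("A", "C", "G", "T")
    ## enumeration oracle: every 4-mer, lattice score, uniform weight
    words <- expand.grid(b1 = 1:4, b2 = 1:4, b3 = 1:4, b4 = 1:4)
    smat <- log2(pwm / 0.25)          # rows = positions, cols = bases
    latt <- round(smat / gran)
    wScore <- latt[cbind(1L, words$b1)] + latt[cbind(2L, words$b2)] +
      latt[cbind(3L, words$b3)] + latt[cbind(4L, words$b4)]
    pEnum <- function(s) mean(wScore >= s)
    ## scan every 4-mer as its own sequence; + strand hits carry DP p
    alph <- c("A", "C", "G", "T")
    wseq <- apply(words, 1, function(r) paste(alph[r], collapse = ""))
    seqs <- Biostrings::DNAStringSet(wseq)
    names(seqs) <- paste0("w", seq_along(wseq))
    hits <- scanPwm(seqs, pwm, bgU, pThresh = 1.01, granularity = gran)
    plus <- hits[hits$strand == "+", ]
    expect_equal(nrow(plus), 256)
    o <- match(plus$seq, names(seqs))
    for (i in seq_len(256)) {
      expect_equal(plus$p[i], pEnum(round(plus$score[i] / gran)),
                   tolerance = 1e-9)
    }
  }
})

test_that("consensus scanning uses the closed-form match probability", {
  bgU <- fitBackground(paste(rep("ACGT", 250), collapse = ""),
                       order = 0, pseudocount = 0)
  ## YAACKG: 2*1*1*1*2*1 / 4^6 = 1/1024 < 0.001
  seqs <- Biostrings::DNAStringSet(c(a = "TTTTCAACTGTTTT", b = "GGGGGGGGGGGGGG"))
  hits <- scanConsensus(seqs, "YAACKG", bgU, pThresh = 0.001)
  expect_true(all(abs(hits$p - 1 / 1024) < 1e-12))
  expect_equal(hits$start[hits$seq == "a" & hits$strand == "+"], 5)
  expect_equal(nrow(hits[hits$seq == "b", ]), 0)
  ## a permissive motif is suppressed by the probability threshold
  expect_equal(nrow(scanConsensus(seqs, "NNN", bgU, 0.001)), 0)
  expect_error(scanConsensus(seqs, "AXC", bgU), "IUPAC")
})

test_that("planted consensus motifs are always recovered", {
  sim <- simulateAnnotation(nChrom = 1, chromLen = 200000, nGenes = 30,
                            dpgFraction = 0, seed = 7)
  sq <- simulateSequences(sim$genes, motif = "YAACKG", plantRate = 1,
                          gc = 0.4, seed = 8)
  bg <- fitBackground(sq$seqs, order = 0)
  hits <- scanConsensus(sq$seqs, "YAACKG", bg, pThresh = 0.001)
  for (i in seq_len(nrow(sq$truth))) {
    tr <- sq$truth[i, ]
    expect_true(any(hits$seq == tr$gene_id & hits$start == tr$pos &
                      hits$strand == tr$strand))
  }
})

test_that("false-hit rate on unplanted windows matches the closed form", {
  sim <- simulateAnnotation(nChrom = 2, chromLen = 400000, nGenes = 100,
                            dpgFraction = 0, geneLenRange = c(1500, 2500),
                            seed = 9)
  sq <- simulateSequences(sim$genes, motif = "YAACKG", plantRate = 0,
                          gc = 0.5, seed = 10)
  bgU <- fitBackground(paste(rep("ACGT", 250), collapse = ""),
                       order = 0, pseudocount = 0)
  hits <- scanConsensus(sq$seqs, "YAACKG", bgU, pThresh = 0.001)
  perWindow <- nrow(hits) / 100
  expected <- 2 * (1001 - 5) / 1024   # ~1.95 per window, both strands
  expect_lt(abs(perWindow - expected), 0.45)
})

test_that("scans are strand-symmetric under reverse complement", {
  set.seed(111)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(x = s))
  rcSeqs <- Biostrings::reverseComplement(seqs)
  names(rcSeqs) <- "x"
  ## a complement-symmetric background (both-strand estimate) is what
  ## makes plus/minus scanning exactly mirror-equivalent
  bg <- fitBackground(seqs, order = 0, bothStrands = TRUE)
  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.7, 0.1, 0.1,
                  0.1, 0.1, 0.7, 0.1,
                  0.25, 0.25, 0.25, 0.25,
                  0.1, 0.1, 0.1, 0.7), 5, 4, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pwmRC <- pwm[5:1, c("T", "G", "C", "A")]
  colnames(pwmRC) <- c("A", "C", "G", "T")
  h1 <- scanPwm(seqs, pwm, bg, pThresh = 0.05)
  h2 <- scanPwm(rcSeqs, pwmRC, bg, pThresh = 0.05)
  L <- 5; n <- 400
  ## both the sequence and the motif are reverse-complemented, so a hit
  ## keeps its strand label and mirrors its position
  mirror <- function(st) n - L + 2 - st
  k1 <- paste(h1$start, h1$strand)
  k2 <- paste(mirror(h2$start), h2$strand)
  expect_setequal(k1, k2)
})

test_that("promoter windows slice and orient the genome correctly", {
  set.seed(121)
  chr <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  gm <- makeGenes("chr1", c(1001, 2000), c(1800, 3200), c("+", "-"),
                  ids = c("gp", "gm"))
  win <- promoterWindows(gm, genome, flank = 500)
  expect_equal(as.character(win[["gp"]]), substr(chr, 501, 1501))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 2700, 3700))))
  expect_equal(as.character(win[["gm"]]), rc)
  ## edge truncation
  gmEdge <- makeGenes("chr1", 100, 900, "+", ids = "ge")
  wE <- promoterWindows(gmEdge, genome, flank = 500)
  expect_equal(as.character(wE[["ge"]]), substr(chr, 1, 600))
  expect_error(promoterWindows(makeGenes("chrZ", 100, 900, "+"), genome),
               "missing")
})
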