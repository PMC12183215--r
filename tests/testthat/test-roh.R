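hom <- function(n) rep(2L, n)

test_that("fully heterozygous chromosomes contain no runs", {
  g <- mkGeno(matrix(1L, 100, 1), pos = seq(5e4, by = 5e4, length.out = 100))
  expect_equal(nrow(detectRoh(g)), 0L)
  expect_equal(nrow(bruteForceRoh(g)), 0L)
})

test_that("a fully homozygous chromosome is one run covering every SNP", {
  pos <- seq(5e4, by = 5e4, length.out = 100)
  seg <- detectRoh(mkGeno(matrix(hom(100), ncol = 1), pos = pos))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 100L)
  expect_equal(seg$start, 5e4)
  expect_equal(seg$end, 5e6)
  expect_equal(seg$length_bp, 5e6 - 5e4 + 1)
  expect_equal(as.character(seg$length_class), "4-8Mb")
})

test_that("the minimum-SNP rule is a sharp 30-SNP boundary", {
  pos30 <- seq(5e4, by = 5e4, length.out = 30)
  expect_equal(nrow(detectRoh(mkGeno(matrix(hom(30), ncol = 1), pos = pos30))), 1L)
  pos29 <- seq(5e4, by = 5e4, length.out = 29)
  expect_equal(nrow(detectRoh(mkGeno(matrix(hom(29), ncol = 1), pos = pos29))), 0L)
})

test_that("the minimum-length rule is a sharp 500 kb boundary", {
  ## 40 SNPs, dense spacing; total span tuned to 499,000 vs 500,000 bp
  mk <- function(lenBp) {
    pos <- round(seq(1e5, 1e5 + lenBp - 1, length.out = 40))
    mkGeno(matrix(hom(40), ncol = 1), pos = pos)
  }
  expect_equal(nrow(detectRoh(mk(500000))), 1L)
  expect_equal(nrow(detectRoh(mk(499000))), 0L)
  ## brute force agrees on both sides of the boundary
  expect_equal(detectRoh(mk(499000)), bruteForceRoh(mk(499000)))
  expect_equal(detectRoh(mk(500000)), bruteForceRoh(mk(500000)))
})

test_that("runs split at gaps above 1,000 kb but not below", {
  mk <- function(gap) {
    ## 20 kb spacing keeps the merged run inside the density limit, so the
    ## gap rule is the only thing distinguishing the two cases
    pos <- c(seq(2e4, by = 2e4, length.out = 40),
             seq(2e4 * 40 + gap, by = 2e4, length.out = 40))
    mkGeno(matrix(hom(80), ncol = 1), pos = pos)
  }
  noSplit <- detectRoh(mk(999000))
  expect_equal(nrow(noSplit), 1L)
  expect_equal(noSplit$n_snps, 80L)
  split <- detectRoh(mk(1001000))
  expect_equal(nrow(split), 2L)
  expect_equal(split$n_snps, c(40L, 40L))
  expect_true(all(diff(split$start) > 0))
})

test_that("one heterozygote per window is tolerated, two are not", {
  pos <- seq(5e4, by = 5e4, length.out = 120)
  ## single isolated het: windows hold at most one -> a single unbroken run
  g1 <- hom(120); g1[60] <- 1L
  seg1 <- detectRoh(mkGeno(matrix(g1, ncol = 1), pos = pos))
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$n_snps, 120L)
  ## adjacent het pair: every covering window fails, the run is broken
  g2 <- hom(120); g2[60:61] <- 1L
  seg2 <- detectRoh(mkGeno(matrix(g2, ncol = 1), pos = pos))
  expect_equal(nrow(seg2), 2L)
  ## both behaviours confirmed by the exhaustive scanner
  expect_equal(seg1, bruteForceRoh(mkGeno(matrix(g1, ncol = 1), pos = pos)))
  expect_equal(seg2, bruteForceRoh(mkGeno(matrix(g2, ncol = 1), pos = pos)))
})

test_that("a 40-SNP homozygous run on a heterozygous background stays below the window rule", {
  ## every 50-SNP window overlapping the run carries >= 10 flanking
  ## heterozygotes, so no window hits; the exhaustive scanner agrees
  pos <- seq(5e4, by = 5e4, length.out = 100)
  g <- rep(1L, 100); g[30:69] <- 2L
  gm <- mkGeno(matrix(g, ncol = 1), pos = pos)
  expect_equal(nrow(detectRoh(gm)), 0L)
  expect_equal(detectRoh(gm), bruteForceRoh(gm))
})

test_that("detector and brute-force scanner agree on random chromosomes", {
  for (seed in 1:40) {
    g <- randChromGeno(sample(200:1500, 1), seed = seed)
    expect_equal(detectRoh(g), bruteForceRoh(g))
  }
})

test_that("segments never overlap and never span a gap beyond the limit", {
  params <- rohParams()
  for (seed in 101:110) {
    g <- randChromGeno(1000, seed = seed)
    seg <- detectRoh(g, params)
    if (nrow(seg) < 2) next
    expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
    pos <- markerMap(g)$pos
    for (r in seq_len(nrow(seg))) {
      inRun <- pos[pos >= seg$start[r] & pos <= seg$end[r]]
      expect_true(all(diff(inRun) <= params@maxGapKb * 1000))
    }
  }
})

test_that("relaxing minSnps or minLength only adds segments", {
  strict <- rohParams()
  looseSnps <- rohParams(minSnps = 20)
  looseLen <- rohParams(minLengthKb = 200)
  key <- function(s) paste(s$animal, s$chrom, s$start, s$end)
  for (seed in 201:210) {
    g <- randChromGeno(800, seed = seed)
    s0 <- key(detectRoh(g, strict))
    expect_true(all(s0 %in% key(detectRoh(g, looseSnps))))
    expect_true(all(s0 %in% key(detectRoh(g, looseLen))))
  }
})

test_that("chromosomes shorter than the window are scanned with a truncated window", {
  pos <- seq(5e4, by = 2e4, length.out = 35)     # 35 SNPs < 50-SNP window
  seg <- detectRoh(mkGeno(matrix(hom(35), ncol = 1), pos = pos))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 35L)
})

test_that("fRoh divides summed lengths by the map-derived genome length", {
  map <- data.frame(chrom = c(1, 1, 2), pos = c(1e6, 1.25e9, 1.25e9),
                    id = c("a", "b", "c"))
  none <- fRoh(data.frame(animal = character(0), chrom = integer(0),
                          start = numeric(0), end = numeric(0),
                          n_snps = integer(0), length_bp = numeric(0),
                          length_class = factor(character(0))),
               map, animals = "i1")
  expect_true(all(none[, -1] == 0))
  ## one 125 Mb segment over a 2,500 Mb genome
  seg <- data.frame(animal = "i1", chrom = 1, start = 1, end = 125e6,
                    n_snps = 1000L, length_bp = 125e6,
                    length_class = factor(">16Mb"))
  got <- fRoh(seg, map, animals = c("i1", "i2"))
  expect_equal(got$F_ROH, c(0.05, 0))
  expect_equal(got$F_ROH_gt16Mb, c(0.05, 0))
  expect_equal(attr(got, "autosome_length_bp"), 2.5e9)
  expect_error(fRoh(seg, map[0, ]), "empty")
})

test_that("per-class coefficients always sum to the total", {
  cfg <- simConfig(nFounders = 30, nGenerations = 5, nPerGeneration = 40,
                   consanguinityRate = 0.6, nChromosomes = 4,
                   chromosomeLengthMb = 60, snpSpacingKb = 40, seed = 17)
  d <- geneDrop(simulatePedigree(cfg), cfg)
  seg <- detectRoh(d$geno)
  ro <- fRoh(seg, markerMap(d$geno), sampleIds(d$geno))
  classSum <- rowSums(ro[, grep("F_ROH_", names(ro))])
  expect_lt(max(abs(classSum - ro$F_ROH)), 1e-12)
  expect_true(all(ro$F_ROH >= 0 & ro$F_ROH <= 1))
})
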