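test_that("simConfig validates its inputs", {
  expect_error(simConfig(), "seed")
  expect_error(simConfig(nFounders = 2, seed = 1))
  expect_error(simConfig(sigma2a = -1, seed = 1))
})

test_that("pedigree simulation honours the consanguinity dial", {
  ## no consanguinity from a wide founder base: early generations non-inbred
  cfg0 <- simConfig(nFounders = 60, nGenerations = 2, consanguinityRate = 0,
                    seed = 2)
  f0 <- computeFPed(suppressWarnings(simulatePedigree(cfg0)))
  expect_true(all(f0 == 0))
  ## forced full-sib matings: all generation-2 animals have F = 1/4,
  ## matching the Wright path-counting oracle
  cfg1 <- simConfig(nFounders = 8, nGenerations = 2, nPerGeneration = 8,
                    consanguinityRate = 1,
                    matingWeights = c(full_sib = 1, half_sib = 0,
                                      parent_offspring = 0), seed = 3)
  ped <- simulatePedigree(cfg1)
  f <- computeFPed(ped)
  g2 <- pedIds(ped)[generationIndex(ped) == 2]
  expect_true(all(abs(f[g2] - 0.25) < 1e-12))
  expect_equal(f, wrightF(parentIds(ped))[pedIds(ped)], tolerance = 1e-12)
})

test_that("a fixed seed reproduces the pedigree exactly", {
  cfg <- simConfig(nFounders = 20, nGenerations = 3, consanguinityRate = 0.5,
                   seed = 4)
  p1 <- simulatePedigree(cfg)
  p2 <- simulatePedigree(cfg)
  expect_identical(parentIds(p1), parentIds(p2))
  expect_identical(attr(p1, "sex"), attr(p2, "sex"))
})

test_that("founders carry no realized autozygosity", {
  cfg <- simConfig(nFounders = 10, nGenerations = 1, nChromosomes = 2,
                   chromosomeLengthMb = 50, snpSpacingKb = 100, seed = 5)
  d <- geneDrop(simulatePedigree(cfg), cfg)
  founders <- d$truth$animal[d$truth$f_ped == 0 &
                               grepl("^G0", d$truth$animal)]
  expect_true(all(d$truth$realized_ibd[d$truth$animal %in% founders] == 0))
  ## dosage states are complete and valid
  expect_true(all(dosage(d$geno) %in% 0:2))
})

test_that("realized IBD fluctuates around pedigree F for full-sib offspring", {
  cfg <- simConfig(nFounders = 4, nGenerations = 2, nPerGeneration = 4,
                   consanguinityRate = 1,
                   matingWeights = c(full_sib = 1, half_sib = 0,
                                     parent_offspring = 0),
                   nChromosomes = 4, chromosomeLengthMb = 100,
                   snpSpacingKb = 500, seed = 6)
  ped <- simulatePedigree(cfg)
  ibd <- replicate(60, {
    d <- geneDrop(ped, cfg, seed = sample.int(1e6, 1))
    mean(d$truth$realized_ibd[d$truth$f_ped == 0.25])
  })
  se <- sd(ibd) / sqrt(length(ibd))
  expect_lt(abs(mean(ibd) - 0.25), 3 * se)
})

test_that("without recombination autozygous tracts span whole chromosomes", {
  cfg <- simConfig(nFounders = 4, nGenerations = 3, nPerGeneration = 4,
                   consanguinityRate = 1,
                   matingWeights = c(full_sib = 1, half_sib = 0,
                                     parent_offspring = 0),
                   nChromosomes = 4, chromosomeLengthMb = 30,
                   snpSpacingKb = 25, cMPerMb = 0, seed = 7)
  ped <- simulatePedigree(cfg)
  d <- geneDrop(ped, cfg)
  ## realized IBD comes in whole-chromosome quanta
  frac <- d$truth$realized_ibd * cfg$nChromosomes
  expect_true(all(abs(frac - round(frac)) < 1e-9))
  expect_true(any(frac > 0))
  ## every detected segment therefore covers a full 30 Mb chromosome and
  ## falls in the >16 Mb class only
  seg <- detectRoh(d$geno)
  expect_gt(nrow(seg), 0L)
  expect_true(all(seg$length_class == ">16Mb"))
  expect_true(all(seg$n_snps == 30e6 %/% 25000))
})

test_that("phenotype simulation follows the model equation", {
  ## all variances zero, no slope: y is exactly the mean
  cfg <- simConfig(nFounders = 10, nGenerations = 2, sigma2a = 0,
                   sigma2e = 0, sigma2cg = 0, mu = 42, beta = 0, seed = 9)
  ped <- simulatePedigree(cfg)
  ph <- simulatePhenotypes(ped, computeFPed(ped), cfg)
  expect_true(all(ph$y == 42))
  ## beta = -20 with noise off separates F groups by exactly -5
  cfg2 <- simConfig(nFounders = 8, nGenerations = 2, nPerGeneration = 8,
                    consanguinityRate = 1,
                    matingWeights = c(full_sib = 1, half_sib = 0,
                                      parent_offspring = 0),
                    sigma2a = 0, sigma2e = 0, sigma2cg = 0, mu = 100,
                    beta = -20, seed = 10)
  ped2 <- simulatePedigree(cfg2)
  ph2 <- simulatePhenotypes(ped2, computeFPed(ped2), cfg2)
  m <- tapply(ph2$y, ph2$F, mean)
  expect_equal(unname(m[["0.25"]] - m[["0"]]), -5)
})

test_that("simulated phenotypic variance matches the variance bookkeeping", {
  cfg <- simConfig(nFounders = 300, nGenerations = 3, nPerGeneration = 700,
                   consanguinityRate = 0.3, sigma2a = 30, sigma2e = 50,
                   sigma2cg = 20, beta = -20, seed = 11)
  ped <- simulatePedigree(cfg)
  f <- computeFPed(ped)
  ph <- simulatePhenotypes(ped, f, cfg)
  expected <- cfg$sigma2a * mean(1 + f[ph$animal]) + cfg$sigma2e +
    cfg$sigma2cg + cfg$beta^2 * var(ph$F)
  expect_lt(abs(var(ph$y) / expected - 1), 0.10)
})

test_that("mean realized IBD converges to pedigree F on a mixed pedigree", {
  cfg <- simConfig(nFounders = 12, nGenerations = 3, nPerGeneration = 12,
                   consanguinityRate = 0.8, nChromosomes = 8,
                   chromosomeLengthMb = 100, snpSpacingKb = 1000, seed = 12)
  ped <- simulatePedigree(cfg)
  f <- computeFPed(ped)
  sel <- f > 0
  sums <- 0
  nRep <- 40
  for (r in seq_len(nRep))
    sums <- sums + geneDrop(ped, cfg, seed = 5000 + r)$truth$realized_ibd
  avg <- (sums / nRep)[sel]
  ## binomial-scale tolerance around the pedigree expectation
  expect_lt(max(abs(avg - f[sel])), 4 * sqrt(0.25 * 0.75 / nRep))
})
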