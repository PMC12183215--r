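test_that("parsePedigree builds founders from referenced parents and reports structure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("animal\tsire\tdam\tbirth_year",
               "C\tA\tB\t2001"), f)
  ped <- parsePedigree(f)
  expect_equal(nAnimals(ped), 3L)
  expect_equal(sum(isFounder(ped)), 2L)
  pp <- parentIds(ped)
  expect_equal(length(unique(na.omit(pp$sire))), 1L)
  expect_equal(length(unique(na.omit(pp$dam))), 1L)
  expect_equal(max(generationIndex(ped)), 1L)
  expect_equal(unname(birthYears(ped)[["C"]]), 2001L)
})

test_that("pedigree sorting is invariant to record order", {
  a <- Pedigree(c("X", "S", "D"), c("S", NA, NA), c("D", NA, NA))
  b <- Pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
  expect_equal(pedIds(a), pedIds(b))
  expect_equal(parentIds(a), parentIds(b))
  expect_equal(computeFPed(a), computeFPed(b))
})

test_that("parsed structure counts match a naive per-column tally", {
  df <- randomPedigree(20, seed = 101)
  ped <- Pedigree(df$animal, df$sire, df$dam)
  pp <- parentIds(ped)
  expect_equal(sum(isFounder(ped)), sum(is.na(pp$sire) & is.na(pp$dam)))
  expect_equal(length(unique(na.omit(pp$sire))),
               length(unique(na.omit(df$sire))))
  expect_equal(length(unique(na.omit(pp$dam))),
               length(unique(na.omit(df$dam))))
})

test_that("invalid pedigrees are hard errors", {
  expect_error(Pedigree(c("A", "A"), c(NA, NA), c(NA, NA)), "duplicate")
  expect_error(Pedigree(c("A", "B"), c("B", "A"), c(NA, NA)), "cycle")
  expect_error(Pedigree("A", "A", NA), "own parent")
})

test_that("computeFPed reproduces textbook inbreeding coefficients", {
  ## founders and animals with an unknown parent are non-inbred
  ped <- Pedigree(c("X"), sire = "S", dam = "0")
  expect_equal(unname(computeFPed(ped)), rep(0, 2))
  ## offspring of full sibs: F = 1/4
  fs <- Pedigree(c("S", "D", "X"), c("A", "A", "S"), c("B", "B", "D"))
  expect_equal(computeFPed(fs)[["X"]], 0.25)
  ## sire mated to his own daughter: F = 1/4
  po <- Pedigree(c("D", "X"), sire = c("S", "S"), dam = c("G", "D"))
  expect_equal(computeFPed(po)[["X"]], 0.25)
  ## offspring of half sibs: F = 1/8
  hs <- Pedigree(c("S", "D", "X"), c("A", "A", "S"), c("B", "C", "D"))
  expect_equal(computeFPed(hs)[["X"]], 0.125)
})

test_that("computeFPed agrees with Wright path counting and the tabular method", {
  for (seed in 1:40) {
    df <- randomPedigree(sample(4:8, 1), seed = seed)
    ped <- Pedigree(df$animal, df$sire, df$dam)
    f <- computeFPed(ped)
    dfo <- parentIds(ped)
    names(dfo) <- c("animal", "sire", "dam")
    expect_equal(f, wrightF(dfo)[pedIds(ped)], tolerance = 1e-12)
    expect_equal(f, tabularFOracle(dfo)[pedIds(ped)], tolerance = 1e-12)
  }
})

test_that("F depends only on the ancestor closure", {
  df <- randomPedigree(8, seed = 7)
  ped <- Pedigree(df$animal, df$sire, df$dam)
  f0 <- computeFPed(ped)
  ## adding an unrelated founder changes nothing
  ped2 <- Pedigree(c(df$animal, "zz"), c(df$sire, NA), c(df$dam, NA))
  expect_equal(computeFPed(ped2)[names(f0)], f0)
  ## pruning animals outside an animal's ancestor closure is a no-op
  target <- df$animal[max(which(!is.na(df$sire) | !is.na(df$dam)))]
  anc <- InbreedKit:::.ancestorClosure(ped, match(target, pedIds(ped)))
  keep <- pedIds(ped)[anc]
  sub <- df[df$animal %in% keep, ]
  ped3 <- Pedigree(sub$animal, sub$sire, sub$dam)
  expect_equal(computeFPed(ped3)[[target]], f0[[target]])
})

test_that("buildAMatrix follows the tabular recurrence", {
  ## two unrelated founders: identity
  ped <- Pedigree(c("A", "B"), c(NA, NA), c(NA, NA))
  expect_equal(unname(buildAMatrix(ped)), diag(2))
  ## founder pair plus offspring: parent-offspring relationship 1/2
  trio <- Pedigree("X", "A", "B")
  A <- buildAMatrix(trio)
  expect_equal(A["A", "X"], 0.5)
  expect_equal(A["X", "X"], 1.0)
  ## subsetting keeps the ancestor closure internally
  fs <- Pedigree(c("S", "D", "X"), c("A", "A", "S"), c("B", "B", "D"))
  expect_equal(unname(buildAMatrix(fs, "X")[1, 1]), 1.25)
  expect_error(buildAMatrix(fs, "nope"), "not in pedigree")
})

test_that("A diagonal equals 1 + F and A-inverse matches the dense inverse", {
  cfg <- simConfig(nFounders = 10, nGenerations = 3, consanguinityRate = 0.5,
                   seed = 5)
  ped <- simulatePedigree(cfg)
  A <- buildAMatrix(ped)
  f <- computeFPed(ped)
  expect_lt(max(abs(diag(A) - 1 - f)), 1e-12)
  expect_lt(max(abs(as.matrix(aInverse(ped, f)) - solve(A))), 1e-8)
})

test_that("summarizeFByYear aggregates by birth year and counts exclusions", {
  ped <- Pedigree(c("A", "B"), c(NA, NA), c(NA, NA), birthYear = c(2000, 2000))
  tab <- summarizeFByYear(c(A = 0, B = 0.25), ped)
  expect_equal(tab$mean, 0.125)
  expect_equal(tab$n, 2L)
  expect_equal(attr(tab, "excluded"), 0L)
  ## no birth years: empty table, everything excluded
  ped2 <- Pedigree(c("A", "B"), c(NA, NA), c(NA, NA))
  tab2 <- summarizeFByYear(c(A = 0, B = 0.25), ped2)
  expect_equal(nrow(tab2), 0L)
  expect_equal(attr(tab2, "excluded"), 2L)
})
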