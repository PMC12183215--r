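test_that("phenotype editing applies the contemporary-group rules", {
  ## a group of two records is removed outright
  ph <- data.frame(animal = c("a", "b", "c", "d", "e"),
                   y = c(10, 12, 11, 10, 12),
                   cg = c("g1", "g1", "g2", "g2", "g2"))
  out <- preparePhenotypes(ph, traitKind = "continuous")
  expect_equal(out$cg, rep("g2", 3))
  expect_equal(attr(out, "filterLog")[["small_groups"]], 2L)

  ## outlier removed iff |z| > 3.5 with the candidate included, n-1 sd
  grp <- data.frame(animal = letters[1:5], y = c(10, 10, 10, 10, 60),
                    cg = "g")
  z <- (60 - mean(grp$y)) / sd(grp$y)
  out2 <- preparePhenotypes(grp, traitKind = "continuous")
  if (abs(z) > 3.5) expect_false(60 %in% out2$y) else expect_true(60 %in% out2$y)
  ## a tie exactly at the limit is kept ("exceeding")
  y3 <- c(-1, -1, -1, -1, -1, -1, 2.5)
  y3 <- y3 * 3.5 / abs(scale(y3)[7])           # scale so |z| of last is 3.5
  grp3 <- data.frame(animal = letters[1:7], y = as.numeric(y3), cg = "g")
  expect_equal(nrow(preparePhenotypes(grp3, traitKind = "continuous")), 7L)
})

test_that("score traits additionally drop zero-variance groups", {
  ph <- data.frame(animal = letters[1:6],
                   y = c(3, 3, 3, 1, 2, 3),
                   cg = rep(c("g1", "g2"), each = 3))
  out <- preparePhenotypes(ph, traitKind = "score")
  expect_equal(unique(out$cg), "g2")
  expect_equal(attr(out, "filterLog")[["novar_groups"]], 3L)
})

test_that("count traits are log10-transformed with the 1.001 offset", {
  ph <- data.frame(animal = c("a", "b", "c"), y = c(0, 9, 99), cg = "g")
  out <- preparePhenotypes(ph, traitKind = "count")
  expect_equal(out$y[1], log10(1.001))
  expect_equal(out$y[2], log10(10.001))
  expect_error(preparePhenotypes(ph, traitKind = "weights"), "arg")
})

test_that("buildDesign assembles the requested random structures", {
  cfg <- simConfig(nFounders = 20, nGenerations = 3, nPerGeneration = 30,
                   consanguinityRate = 0.3, nRecordsPerAnimal = 3, seed = 9)
  ped <- simulatePedigree(cfg)
  f <- computeFPed(ped)
  ph <- simulatePhenotypes(ped, f, cfg)
  d1 <- buildDesign(ph, ped, "F", structure = "animal_only",
                    fixedFactors = "cg")
  expect_length(d1$random, 1L)
  expect_equal(colnames(d1$X)[ncol(d1$X)], "F")

  phm <- simulatePhenotypes(ped, f, cfg, structure = "animal_maternal_mpe")
  d2 <- buildDesign(phm, ped, "F", structure = "animal_maternal_mpe")
  expect_equal(vapply(d2$random, `[[`, "", "name"), c("a", "m", "mpe"))

  ## repeated records of an animal map to a single permanent-env level
  php <- simulatePhenotypes(ped, f, cfg, structure = "animal_pe")
  d3 <- buildDesign(php, ped, "F", structure = "animal_pe")
  Wpe <- d3$random[[2]]$Z
  expect_equal(nrow(Wpe), nrow(php))
  expect_equal(ncol(Wpe), length(unique(php$animal)))
  expect_true(all(Matrix::colSums(Wpe) == 3))

  ## constant inbreeding covariate is refused, not silently dropped
  ph0 <- ph; ph0$F <- 0.1
  expect_error(buildDesign(ph0, ped, "F"), "confounded")
  expect_error(buildDesign(transform(ph, animal = "ghost"), ped, "F"),
               "not in pedigree")
})

test_that("REML equals closed-form ANOVA on a balanced sire design", {
  set.seed(4)
  s <- 25; k <- 16
  sid <- rep(seq_len(s), each = k)
  y <- 10 + rnorm(s, 0, sqrt(40))[sid] + rnorm(s * k, 0, sqrt(60))
  X <- matrix(1, s * k, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- Matrix::sparseMatrix(i = seq_along(y), j = sid, x = 1)
  fit <- aiReml(y, X, list(list(Z = Z, Kinv = Matrix::Diagonal(s),
                                name = "s")), tol = 1e-10)
  msb <- k * var(tapply(y, sid, mean))
  msw <- sum((y - ave(y, sid))^2) / (s * (k - 1))
  expect_equal(unname(fit$varcomp[["sigma2_s"]]), (msb - msw) / k,
               tolerance = 1e-6)
  expect_equal(unname(fit$varcomp[["sigma2_e"]]), msw, tolerance = 1e-6)
})

test_that("with no random terms the fit reduces to ordinary least squares", {
  set.seed(8)
  n <- 150
  X <- cbind(1, rnorm(n), runif(n))
  colnames(X) <- c("(Intercept)", "x", "F")
  y <- as.numeric(X %*% c(2, 1, -3) + rnorm(n))
  r <- aiReml(y, X, list())
  lmf <- lm(y ~ X - 1)
  expect_equal(unname(r$beta), unname(coef(lmf)), tolerance = 1e-10)
  expect_equal(unname(r$seBeta), unname(sqrt(diag(vcov(lmf)))),
               tolerance = 1e-10)
})

test_that("the genetic variance vanishes under a no-genetics null", {
  cfg <- simConfig(nFounders = 150, nGenerations = 3, nPerGeneration = 300,
                   consanguinityRate = 0.3, sigma2a = 0, sigma2e = 100,
                   seed = 15)
  ped <- simulatePedigree(cfg)
  ph <- simulatePhenotypes(ped, computeFPed(ped), cfg)
  des <- buildDesign(ph, ped, "F", fixedFactors = "cg")
  fit <- suppressWarnings(remlFit(des))
  vc <- fit@varcomp
  expect_lt(vc[["sigma2_a"]] / sum(vc), 0.05)
})

test_that("rescaling phenotypes rescales beta but not percent depression", {
  cfg <- simConfig(nFounders = 40, nGenerations = 3, nPerGeneration = 80,
                   consanguinityRate = 0.5, sigma2a = 20, sigma2e = 40,
                   beta = -10, seed = 23)
  ped <- simulatePedigree(cfg)
  ph <- simulatePhenotypes(ped, computeFPed(ped), cfg)
  des1 <- buildDesign(ph, ped, "F", fixedFactors = "cg")
  ph2 <- ph; ph2$y <- 2 * ph$y
  des2 <- buildDesign(ph2, ped, "F", fixedFactors = "cg")
  f1 <- remlFit(des1); f2 <- remlFit(des2)
  expect_equal(f2@beta, 2 * f1@beta, tolerance = 1e-4)
  expect_equal(f2@se, 2 * f1@se, tolerance = 1e-4)
  expect_equal(percentDepression(f2), percentDepression(f1), tolerance = 1e-4)
})

test_that("percent depression is beta scaled by one percent of the mean", {
  fit <- new("DepressionFit", varcomp = c(sigma2_e = 1), beta = -0.5,
             se = 0.1, ci = c(-0.7, -0.3), significant = TRUE,
             covariate = "F", structure = "animal_only",
             fixedEffects = c(`(Intercept)` = 50), converged = TRUE,
             iterations = 5L, details = list(traitMean = 50))
  expect_equal(percentDepression(fit), -0.01)        # -0.5 kg on a 50 kg mean
  fit@beta <- 1.5
  expect_equal(percentDepression(fit, traitMean = 3), 0.5)
  fit@beta <- 0
  expect_equal(percentDepression(fit), 0)
  expect_error(percentDepression(fit, traitMean = -1), "positive")
})
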