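## Synthetic data with known ground truth: pedigrees with controllable
## consanguinity, gene-dropped genotypes with linkage (so ROH of graded
## length arise), and phenotypes generated under the animal models fitted by
## the package.

#' Simulation configuration
#'
#' Defaults describe a small beef-cattle-like design: discrete generations,
#' litters of two (so full sibs exist), a 29-autosome genome at 1 cM/Mb with
#' evenly spaced SNPs, and a moderately heritable trait.
#'
#' @param nFounders founders in generation 0 (half of each sex).
#' @param nGenerations number of discrete offspring generations.
#' @param nPerGeneration offspring per generation (even; litters of two).
#' @param consanguinityRate probability that a mating is between relatives.
#' @param matingWeights named weights for the consanguineous mating menu
#'   (\code{full_sib}, \code{half_sib}, \code{parent_offspring}; expected
#'   offspring F 0.25, 0.125, 0.25).
#' @param nChromosomes,chromosomeLengthMb,snpSpacingKb genome layout.
#' @param cMPerMb uniform genetic-map rate (default 1 cM/Mb, no crossover
#'   interference); 0 disables recombination entirely.
#' @param founderMafRange founder minor-allele frequencies are drawn
#'   uniformly from this range (the reference allele is the minor or major
#'   one with equal probability).
#' @param missingRate genotype missingness rate (missing completely at
#'   random).
#' @param mu,sigma2a,sigma2m,sigma2mpe,sigma2pe,sigma2e,sigma2cg trait mean
#'   and variance components (direct genetic, maternal genetic, maternal
#'   permanent environment, animal permanent environment, residual,
#'   contemporary group).
#' @param beta inbreeding-depression slope in trait units per unit F.
#' @param nRecordsPerAnimal repeated records per animal (used by the
#'   permanent-environment structure).
#' @param seed mandatory integer seed; every simulation function derives its
#'   randomness from it.
#' @return a list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nFounders = 40L, nGenerations = 4L,
                      nPerGeneration = nFounders,
                      consanguinityRate = 0.3,
                      matingWeights = c(full_sib = 0.5, half_sib = 0.25,
                                        parent_offspring = 0.25),
                      nChromosomes = 29L, chromosomeLengthMb = 100,
                      snpSpacingKb = 50, cMPerMb = 1, founderMafRange = c(0.1, 0.5),
                      missingRate = 0, mu = 100, sigma2a = 30, sigma2m = 0,
                      sigma2mpe = 0, sigma2pe = 0, sigma2e = 70,
                      sigma2cg = 25, beta = 0, nRecordsPerAnimal = 1L,
                      seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(nFounders >= 4L, consanguinityRate >= 0, consanguinityRate <= 1,
            all(c(sigma2a, sigma2m, sigma2mpe, sigma2pe, sigma2e,
                  sigma2cg) >= 0))
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a pedigree with controllable consanguinity
#'
#' Discrete generations; offspring are produced in litters of two so that
#' full sibs are always available.  With probability
#' \code{consanguinityRate} a mating pair is drawn from the consanguineous
#' menu (full sibs, half sibs, or parent-offspring, by
#' \code{matingWeights}); otherwise a male and a female sharing no parent
#' are drawn.  Infeasible requests fall back to the closest feasible type
#' (once-per-call warning).  Birth year is the generation index.
#'
#' @param cfg a [simConfig()].
#' @param seed seed override (default \code{cfg$seed}).
#' @return a \linkS4class{Pedigree}; the \code{"sex"} attribute maps animal
#'   id to "M"/"F".
#' @export
simulatePedigree <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  nf <- cfg$nFounders
  ids <- sprintf("G0_%04d", seq_len(nf))
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  year <- rep(0L, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  warned <- FALSE

  for (g in seq_len(cfg$nGenerations)) {
    isPrev <- year == g - 1L
    prevM <- ids[isPrev & sex == "M"]; prevF <- ids[isPrev & sex == "F"]
    if (!length(prevM) || !length(prevF))
      stop("a generation ran out of one sex; increase nPerGeneration")
    sOf <- setNames(sire, ids); dOf <- setNames(dam, ids)
    mS <- sOf[prevM]; mD <- dOf[prevM]          # parents of candidate mates
    fS <- sOf[prevF]; fD <- dOf[prevF]
    pairKeyM <- paste(mS, mD); pairKeyF <- paste(fS, fD)

    nOff <- cfg$nPerGeneration
    nPairs <- ceiling(nOff / 2)
    newId <- character(0); newS <- character(0); newD <- character(0)
    newSex <- character(0)
    ## founder-by-founder generations cannot contain related pairs
    conRate <- if (g == 1L) 0 else cfg$consanguinityRate
    for (pr in seq_len(nPairs)) {
      pair <- NULL
      if (runif(1) < conRate) {
        type <- sample(names(cfg$matingWeights), 1, prob = cfg$matingWeights)
        for (tryType in unique(c(type, names(cfg$matingWeights)))) {
          pair <- switch(tryType,
            full_sib = {
              ok <- which(!is.na(mS) & pairKeyM %in% pairKeyF)
              if (length(ok)) {
                m <- prevM[sample(rep(ok, 2), 1)]
                fs <- prevF[pairKeyF == paste(sOf[m], dOf[m])]
                c(m, fs[sample.int(length(fs), 1)])
              } else NULL
            },
            half_sib = {
              cand <- NULL
              for (mi in sample(seq_along(prevM))) {
                share <- (!is.na(mS[mi]) & !is.na(fS) & fS == mS[mi]) +
                         (!is.na(mD[mi]) & !is.na(fD) & fD == mD[mi])
                hs <- which(share == 1)
                if (length(hs)) {
                  cand <- c(prevM[mi], prevF[sample(rep(hs, 2), 1)])
                  break
                }
              }
              cand
            },
            parent_offspring = {
              ok <- which(!is.na(fS))
              if (length(ok)) {
                fi <- sample(rep(ok, 2), 1)
                c(unname(fS[fi]), prevF[fi])   # sire x daughter
              } else NULL
            })
          if (!is.null(pair)) break
        }
        if (is.null(pair) && !warned) {
          warning("infeasible mating constraints relaxed: no related pair available")
          warned <- TRUE
        }
      }
      if (is.null(pair)) {
        ## unrelated-as-possible: redraw until the pair shares no parent
        for (tries in 1:50) {
          mi <- sample.int(length(prevM), 1)
          fi <- sample.int(length(prevF), 1)
          shared <- sum(c(!is.na(mS[mi]) && !is.na(fS[fi]) && mS[mi] == fS[fi],
                          !is.na(mD[mi]) && !is.na(fD[fi]) && mD[mi] == fD[fi]))
          if (shared == 0) break
        }
        pair <- c(prevM[mi], prevF[fi])
      }
      litter <- min(2L, nOff - (pr - 1L) * 2L)
      k <- seq_len(litter)
      newId <- c(newId, sprintf("G%d_%04d", g, (pr - 1L) * 2L + k))
      newS <- c(newS, rep(pair[1], litter))
      newD <- c(newD, rep(pair[2], litter))
      newSex <- c(newSex, sample(c("M", "F"), litter, replace = TRUE))
    }
    ids <- c(ids, newId); sire <- c(sire, newS); dam <- c(dam, newD)
    year <- c(year, rep(g, length(newId))); sex <- c(sex, newSex)
  }
  ped <- Pedigree(ids, sire, dam, birthYear = year, missing = NA_character_)
  attr(ped, "sex") <- setNames(sex, ids)[pedIds(ped)]
  ped
}

## --- haplotype segment machinery (breaks = segment end positions, labs =
##     founder-haplotype labels; last break equals the chromosome length) ---

.extractInterval <- function(hap, a, b) {
  ## piece of `hap` covering (a, b]
  i1 <- findInterval(a, hap$breaks) + 1L
  i2 <- findInterval(b, hap$breaks, left.open = TRUE) + 1L
  idx <- i1:i2
  list(breaks = c(head(hap$breaks[idx], -1L), b), labs = hap$labs[idx])
}

.mergeSegments <- function(breaks, labs) {
  if (length(labs) > 1L) {
    same <- c(labs[-1L] == labs[-length(labs)], FALSE)
    keep <- !same
    breaks <- breaks[keep]; labs <- labs[keep]
  }
  list(breaks = breaks, labs = labs)
}

.meiosis <- function(hap1, hap2, lengthBp, cMPerMb = 1) {
  nXo <- rpois(1, lengthBp / 1e6 * cMPerMb / 100)
  xo <- sort(runif(nXo, 0, lengthBp))
  cuts <- c(xo, lengthBp)
  src <- ((sample(0:1, 1) + seq_along(cuts) - 1L) %% 2L) + 1L
  a <- 0
  breaks <- numeric(0); labs <- integer(0)
  for (s in seq_along(cuts)) {
    b <- cuts[s]
    if (b > a) {
      piece <- .extractInterval(if (src[s] == 1L) hap1 else hap2, a, b)
      breaks <- c(breaks, piece$breaks); labs <- c(labs, piece$labs)
      a <- b
    }
  }
  .mergeSegments(breaks, labs)
}

.ibdFraction <- function(hap1, hap2, lengthBp) {
  cuts <- sort(unique(c(hap1$breaks, hap2$breaks)))
  starts <- c(0, head(cuts, -1L))
  l1 <- hap1$labs[findInterval(starts, hap1$breaks) + 1L]
  l2 <- hap2$labs[findInterval(starts, hap2$breaks) + 1L]
  sum((cuts - starts)[l1 == l2]) / lengthBp
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders receive unique haplotype labels per chromosome plus biallelic
#' SNP states drawn from the founder allele-frequency distribution; each
#' meiosis recombines with Poisson(length in Morgans) crossovers placed
#' uniformly (1 cM/Mb, no interference).  Realized IBD is the proportion of
#' the genome where an individual's two founder-haplotype labels coincide
#' (computed on the exact segment structure, not the SNP grid).
#'
#' @param ped a \linkS4class{Pedigree} (topologically sorted, as built).
#' @param cfg a [simConfig()].
#' @param seed seed override (default \code{cfg$seed + 1}).
#' @return list with \code{geno} (a \linkS4class{GenotypeMatrix}),
#'   \code{truth} (data.frame: animal, realized IBD fraction, pedigree F).
#' @export
geneDrop <- function(ped, cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  n <- nAnimals(ped)
  nC <- cfg$nChromosomes
  Lbp <- cfg$chromosomeLengthMb * 1e6
  spac <- cfg$snpSpacingKb * 1000
  posList <- lapply(seq_len(nC), function(cc) seq(spac, Lbp, by = spac))
  nSnpChr <- lengths(posList)

  ## founder allele frequencies and haplotype SNP states
  nFounderHap <- 2L * sum(ped@founder)
  hapOfFounder <- matrix(seq_len(nFounderHap), nrow = 2L)
  maf <- lapply(nSnpChr, function(m) runif(m, cfg$founderMafRange[1],
                                           cfg$founderMafRange[2]))
  pRef <- lapply(maf, function(p) ifelse(runif(length(p)) < 0.5, p, 1 - p))
  founderAllele <- lapply(seq_len(nC), function(cc)
    matrix(rbinom(nFounderHap * nSnpChr[cc], 1L, rep(pRef[[cc]],
                                                     each = nFounderHap)),
           nrow = nFounderHap))

  haps <- vector("list", n)  # haps[[i]][[chrom]] = list(h1, h2)
  ibdLen <- numeric(n)
  dosage <- matrix(NA_integer_, nrow = sum(nSnpChr), ncol = n)
  fCount <- 0L
  rowOff <- c(0L, cumsum(nSnpChr))
  for (i in seq_len(n)) {
    haps[[i]] <- vector("list", nC)
    if (ped@founder[i]) fCount <- fCount + 1L
    for (cc in seq_len(nC)) {
      if (ped@founder[i]) {
        h1 <- list(breaks = Lbp, labs = hapOfFounder[1L, fCount])
        h2 <- list(breaks = Lbp, labs = hapOfFounder[2L, fCount])
      } else {
        ps <- haps[[ped@sire[i]]][[cc]]
        pd <- haps[[ped@dam[i]]][[cc]]
        h1 <- .meiosis(ps[[1]], ps[[2]], Lbp, cfg$cMPerMb)
        h2 <- .meiosis(pd[[1]], pd[[2]], Lbp, cfg$cMPerMb)
      }
      haps[[i]][[cc]] <- list(h1, h2)
      ibdLen[i] <- ibdLen[i] + .ibdFraction(h1, h2, Lbp) * Lbp
      pos <- posList[[cc]]
      lab1 <- h1$labs[findInterval(pos, h1$breaks, left.open = TRUE) + 1L]
      lab2 <- h2$labs[findInterval(pos, h2$breaks, left.open = TRUE) + 1L]
      idx <- seq.int(rowOff[cc] + 1L, rowOff[cc + 1L])
      al <- founderAllele[[cc]]
      dosage[idx, i] <- al[cbind(lab1, seq_along(pos))] +
        al[cbind(lab2, seq_along(pos))]
    }
  }
  if (cfg$missingRate > 0) {
    drop <- runif(length(dosage)) < cfg$missingRate
    dosage[drop] <- NA_integer_
  }
  map <- data.frame(
    chrom = rep(seq_len(nC), nSnpChr),
    pos = unlist(posList),
    id = sprintf("snp%d_%d", rep(seq_len(nC), nSnpChr), unlist(posList)))
  geno <- GenotypeMatrix(dosage, map, sampleIds = pedIds(ped))
  truth <- data.frame(animal = pedIds(ped),
                      realized_ibd = ibdLen / (nC * Lbp),
                      f_ped = unname(computeFPed(ped)),
                      stringsAsFactors = FALSE)
  list(geno = geno, truth = truth)
}

#' Simulate phenotypes under an animal model
#'
#' Breeding values follow the pedigree recursion a_i = (a_s + a_d)/2 + m_i
#' with Mendelian-sampling variance d_i sigma2a (d_i from parental
#' inbreeding, so the simulated covariance is exactly sigma2a A); maternal
#' genetic values use the same recursion with sigma2m.  Records are
#' generated for all non-founders as
#' y = mu + cg + sex + beta F + a + m(dam) + mpe(dam) + pe + e
#' with terms switched on by the requested structure.
#'
#' @param ped a \linkS4class{Pedigree} (with the \code{"sex"} attribute from
#'   [simulatePedigree()]; missing sexes are drawn at random).
#' @param inbreeding named per-animal covariate (e.g. [computeFPed()] output
#'   or an F_ROH column); missing animals get 0.
#' @param cfg a [simConfig()] carrying mu, the variance components and beta.
#' @param structure random structure to simulate under.
#' @param seed seed override (default \code{cfg$seed + 2}).
#' @return phenotype data.frame (animal, y, cg, sex, damAge, age, ageSq, F);
#'   the \code{"truth"} attribute holds the breeding values and beta.
#' @export
simulatePhenotypes <- function(ped, inbreeding, cfg,
                               structure = c("animal_only",
                                             "animal_maternal_mpe",
                                             "animal_pe"),
                               seed = cfg$seed + 2L) {
  structure <- match.arg(structure)
  set.seed(seed)
  n <- nAnimals(ped)
  f <- computeFPed(ped)
  d <- .mendelianD(ped, f)
  simBv <- function(s2) {
    a <- numeric(n)
    ms <- rnorm(n, 0, sqrt(d * s2))
    for (i in seq_len(n)) {
      pa <- c(if (!is.na(ped@sire[i])) a[ped@sire[i]] else 0,
              if (!is.na(ped@dam[i])) a[ped@dam[i]] else 0)
      a[i] <- sum(pa) / 2 + ms[i]
    }
    a
  }
  a <- if (cfg$sigma2a > 0) simBv(cfg$sigma2a) else numeric(n)
  m <- if (structure == "animal_maternal_mpe" && cfg$sigma2m > 0)
    simBv(cfg$sigma2m) else numeric(n)

  rec <- which(!ped@founder)
  if (structure == "animal_maternal_mpe" && anyNA(ped@dam[rec]))
    stop("maternal structure requires known dams for all phenotyped animals")
  nRec <- if (structure == "animal_pe") cfg$nRecordsPerAnimal else 1L
  idx <- rep(rec, each = nRec)
  ids <- pedIds(ped)[idx]

  fcov <- rep(0, n)
  if (!is.null(names(inbreeding))) {
    hit <- match(pedIds(ped), names(inbreeding))
    fcov[!is.na(hit)] <- inbreeding[hit[!is.na(hit)]]
  } else fcov <- rep_len(inbreeding, n)

  sex <- attr(ped, "sex")
  if (is.null(sex))
    sex <- setNames(sample(c("M", "F"), n, replace = TRUE), pedIds(ped))
  gen <- generationIndex(ped)[idx]
  cgSize <- 20L
  cg <- paste0("cg", gen, "_",
               ave(seq_along(idx), gen,
                   FUN = function(v) ceiling(sample(seq_along(v)) / cgSize)))
  cgLev <- unique(cg)
  cgEff <- setNames(rnorm(length(cgLev), 0, sqrt(cfg$sigma2cg)), cgLev)
  mpeEff <- setNames(rnorm(n, 0, sqrt(cfg$sigma2mpe)), pedIds(ped))
  peEff <- setNames(rnorm(n, 0, sqrt(cfg$sigma2pe)), pedIds(ped))
  age <- round(runif(length(idx), 175, 235))
  damAge <- sample(2:8, length(idx), replace = TRUE)

  y <- cfg$mu + cgEff[cg] + cfg$beta * fcov[idx] + a[idx] +
    rnorm(length(idx), 0, sqrt(cfg$sigma2e))
  if (structure == "animal_maternal_mpe")
    y <- y + m[ped@dam[idx]] + mpeEff[ped@dam[idx]]
  if (structure == "animal_pe")
    y <- y + peEff[idx]

  out <- data.frame(animal = ids, y = as.numeric(y), cg = cg,
                    sex = unname(sex[ids]), damAge = damAge, age = age,
                    ageSq = age^2, F = fcov[idx],
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(bv = setNames(a, pedIds(ped)),
                             maternal = setNames(m, pedIds(ped)),
                             beta = cfg$beta, structure = structure)
  out
}
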