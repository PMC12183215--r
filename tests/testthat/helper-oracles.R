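## Independent oracles and fixture builders shared across the test files.
## Everything here is deliberately naive (path enumeration, double loops,
## exhaustive window scans) and written against the definitions, not against
## the package internals.

## ---- Wright path-counting inbreeding oracle --------------------------------
## df: data.frame(animal, sire, dam) as characters, NA = unknown parent.
wrightF <- function(df) {
  sire <- setNames(df$sire, df$animal)
  dam <- setNames(df$dam, df$animal)
  memo <- new.env()
  paths <- function(id) {
    out <- list(id)
    for (p in c(sire[[id]], dam[[id]])) {
      if (!is.na(p)) out <- c(out, lapply(paths(p), function(pp) c(id, pp)))
    }
    out
  }
  Fx <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    s <- sire[[id]]; d <- dam[[id]]
    if (is.na(s) || is.na(d)) { memo[[id]] <- 0; return(0) }
    ps <- paths(s); pd <- paths(d)
    f <- 0
    for (p1 in ps) for (p2 in pd) {
      A <- p1[length(p1)]
      if (p2[length(p2)] != A) next
      if (length(intersect(p1[-length(p1)], p2[-length(p2)]))) next
      f <- f + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + Fx(A))
    }
    memo[[id]] <- f
    f
  }
  setNames(vapply(df$animal, Fx, numeric(1)), df$animal)
}

## ---- naive tabular-method oracle -------------------------------------------
## assumes df rows already ordered parents-before-offspring
tabularFOracle <- function(df) {
  n <- nrow(df)
  idx <- setNames(seq_len(n), df$animal)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- if (is.na(df$sire[i])) 0L else idx[[df$sire[i]]]
    d <- if (is.na(df$dam[i])) 0L else idx[[df$dam[i]]]
    if (i > 1) for (j in 1:(i - 1)) {
      A[j, i] <- A[i, j] <- 0.5 * ((if (s) A[j, s] else 0) +
                                   (if (d) A[j, d] else 0))
    }
    A[i, i] <- 1 + 0.5 * (if (s && d) A[s, d] else 0)
  }
  setNames(diag(A) - 1, df$animal)
}

## random small pedigree (possibly with one-known-parent records)
randomPedigree <- function(n, seed) {
  set.seed(seed)
  animal <- paste0("a", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < 0.7) {
      prev <- animal[seq_len(i - 1)]
      sire[i] <- sample(prev, 1)
      d <- sample(prev, 1)
      if (d != sire[i]) dam[i] <- d
      if (runif(1) < 0.15) sire[i] <- NA    # one known parent
    }
  }
  data.frame(animal = animal, sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

## ---- naive genomic-metric loops --------------------------------------------
## x: markers x individuals dosage with NAs; p: per-marker frequencies
naiveMetrics <- function(x, p) {
  nInd <- ncol(x)
  out <- matrix(NA_real_, nInd, 4,
                dimnames = list(colnames(x),
                                c("F_GRM", "F_HOM1", "F_HOM2", "F_UNI")))
  for (k in seq_len(nInd)) {
    num1 <- num2 <- num3 <- num4 <- den <- 0
    oh <- 0
    for (j in seq_len(nrow(x))) {
      xi <- x[j, k]
      if (is.na(xi) || is.na(p[j]) || p[j] <= 0 || p[j] >= 1) next
      den <- den + 2 * p[j] * (1 - p[j])
      num1 <- num1 + (xi - 2 * p[j])^2
      oh <- oh + (xi == 1)
      num3 <- num3 + xi * (2 - xi)
      num4 <- num4 + xi^2 - (1 + 2 * p[j]) * xi + 2 * p[j]^2
    }
    if (den > 0) {
      out[k, "F_GRM"] <- num1 / den - 1
      out[k, "F_HOM1"] <- (den - oh) / den
      out[k, "F_HOM2"] <- 1 - num3 / den
      out[k, "F_UNI"] <- num4 / den
    }
  }
  out
}

## ---- Hardy-Weinberg exact test by direct enumeration -----------------------
hweExactOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB; nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  ## unnormalised log conditional probability of h heterozygotes given the
  ## allele counts: -log(nAA! nAB! nBB!) + nAB log 2 (constants cancel)
  lp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    h * log(2) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  pObs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

## ---- genotype fixture builders ---------------------------------------------
mkGeno <- function(dos, pos = NULL, chrom = NULL, ids = NULL) {
  dos <- as.matrix(dos)
  S <- nrow(dos)
  if (is.null(pos)) pos <- seq_len(S) * 1000
  if (is.null(chrom)) chrom <- rep(1L, S)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(dos)))
  GenotypeMatrix(dos, data.frame(chrom = chrom, pos = pos,
                                 id = paste0("m", seq_len(S))), ids)
}

## random single-chromosome genotypes with autozygous stretches and gaps,
## exercising het, missing, gap and density edge cases
randChromGeno <- function(S, seed) {
  set.seed(seed)
  spac <- pmax(1000, round(rexp(S, 1 / 40000)))
  if (runif(1) < 0.3) spac[sample(S, 2)] <- 1.2e6
  pos <- cumsum(spac)
  pHet <- ifelse(runif(S) < 0.2, 0.02, 0.35)
  auto <- cumsum(rbinom(S, 1, 0.02)) %% 2 == 1
  pHet[auto] <- 0.01
  g <- ifelse(runif(S) < pHet, 1L, ifelse(runif(S) < 0.5, 0L, 2L))
  g[runif(S) < 0.02] <- NA
  mkGeno(matrix(g, ncol = 1), pos = pos)
}

## genotype matrix drawn under Hardy-Weinberg with no inbreeding
hweGeno <- function(n, M, seed, pRange = c(0.1, 0.9), missingRate = 0) {
  set.seed(seed)
  p <- runif(M, pRange[1], pRange[2])
  x <- matrix(rbinom(M * n, 2L, p), nrow = M, ncol = n)
  if (missingRate > 0) x[runif(length(x)) < missingRate] <- NA_integer_
  mkGeno(x)
}
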