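## Quality control: allele frequencies, Hardy-Weinberg exact test, and the
## two filtering regimes (ROH detection vs. frequency-based metrics).

#' Per-marker reference-allele frequencies
#'
#' p = (reference allele count) / (2 x non-missing individuals), computed per
#' marker.  Markers with no non-missing call get \code{NA} and are flagged in
#' the \code{"all_missing"} attribute.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return numeric vector of frequencies in [0, 1], named by marker id.
#' @export
alleleFrequencies <- function(g) {
  x <- dosage(g)
  nObs <- rowSums(!is.na(x))
  p <- rowSums(x, na.rm = TRUE) / (2 * nObs)
  p[nObs == 0L] <- NA_real_
  p <- setNames(as.numeric(p), rownames(x))
  attr(p, "all_missing") <- names(p)[nObs == 0L]
  p
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (covering both heterozygote excess and deficit).  Computed with the
#' standard recurrence over adjacent heterozygote counts, so it is stable for
#' thousands of individuals.  Monomorphic markers return p = 1.
#'
#' @param g a \linkS4class{GenotypeMatrix}, or \code{NULL} when
#'   \code{counts} is given.
#' @param marker marker id or row index into \code{g}.
#' @param counts optional length-3 integer vector (n_AA, n_Aa, n_aa) used
#'   instead of \code{g}.
#' @return p-value in (0, 1].
#' @export
hweExactTest <- function(g = NULL, marker = NULL, counts = NULL) {
  if (is.null(counts)) {
    x <- dosage(g)
    row <- if (is.character(marker)) match(marker, rownames(x)) else marker
    xi <- x[row, ]
    counts <- c(sum(xi == 2L, na.rm = TRUE), sum(xi == 1L, na.rm = TRUE),
                sum(xi == 0L, na.rm = TRUE))
  }
  nAA <- counts[1]; nAB <- counts[2]; nBB <- counts[3]
  n <- nAA + nAB + nBB
  nA <- 2L * nAA + nAB
  nB <- 2L * nBB + nAB
  if (n == 0L || nA == 0L || nB == 0L) return(1)
  rare <- min(nA, nB)
  ## heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  ## unnormalised probabilities by recurrence:
  ## P(h+2)/P(h) = (nA-h)(nB-h) / ((h+2)(h+1))  with homs from h
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    lp[k] <- lp[k - 1L] +
      log(rare - h) + log((nA + nB - rare) - h) - log(h + 2) - log(h + 1)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAB, hets)]
  if (is.na(pObs)) stop("impossible genotype configuration")
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

#' Apply genotype quality control
#'
#' Two regimes mirroring ROH-based versus frequency-based analyses:
#' \describe{
#'   \item{roh}{individual call rate > 0.95, then marker call rate > 0.95.}
#'   \item{freq}{additionally MAF >= 0.05 and Hardy-Weinberg exact-test
#'     p >= 1e-6 (markers below either threshold removed).}
#' }
#' Filters run in the order listed (individual call rate, marker call rate,
#' MAF, HWE); marker call rate is evaluated after low-call-rate individuals
#' are removed.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param regime "roh" or "freq".
#' @param callRate strict lower bound on call rate (default 0.95).
#' @param mafMin minimum minor-allele frequency kept in the freq regime.
#' @param hweMin minimum HWE p-value kept in the freq regime.
#' @return the filtered \linkS4class{GenotypeMatrix}; the \code{"qcReport"}
#'   attribute lists removed/retained counts per rule.
#' @export
applyQc <- function(g, regime = c("roh", "freq"), callRate = 0.95,
                    mafMin = 0.05, hweMin = 1e-6) {
  regime <- match.arg(regime)
  x <- dosage(g)
  nInd0 <- ncol(x); nMark0 <- nrow(x)

  indCR <- colMeans(!is.na(x))
  keepInd <- indCR > callRate
  if (!any(keepInd)) stop("QC removed every individual")
  x2 <- x[, keepInd, drop = FALSE]

  markCR <- rowMeans(!is.na(x2))
  keepMark <- markCR > callRate
  removedMaf <- removedHwe <- 0L
  if (regime == "freq") {
    nObs <- rowSums(!is.na(x2))
    p <- rowSums(x2, na.rm = TRUE) / (2 * pmax(nObs, 1L))
    maf <- pmin(p, 1 - p)
    failMaf <- keepMark & maf < mafMin
    removedMaf <- sum(failMaf)
    keepMark <- keepMark & !failMaf
    hweP <- vapply(which(keepMark), function(r) {
      xr <- x2[r, ]
      hweExactTest(counts = c(sum(xr == 2L, na.rm = TRUE),
                              sum(xr == 1L, na.rm = TRUE),
                              sum(xr == 0L, na.rm = TRUE)))
    }, numeric(1))
    failHwe <- which(keepMark)[hweP < hweMin]
    removedHwe <- length(failHwe)
    keepMark[failHwe] <- FALSE
  }
  if (!any(keepMark)) stop("QC removed every marker")
  out <- g[keepMark, keepInd]
  out <- new("GenotypeMatrix", out)
  report <- data.frame(
    rule = c("individual_call_rate", "marker_call_rate", "maf", "hwe"),
    removed = c(nInd0 - sum(keepInd),
                sum(markCR <= callRate),
                removedMaf, removedHwe),
    axis = c("individual", "marker", "marker", "marker"),
    stringsAsFactors = FALSE)
  attr(out, "qcReport") <- report
  attr(out, "retained") <- c(markers = sum(keepMark), individuals = sum(keepInd))
  out
}
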