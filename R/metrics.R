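## Frequency-based genomic inbreeding coefficients.  All four are ratios of
## per-individual sums restricted to that individual's non-missing markers;
## markers with p = 0 or p = 1 carry no information and are excluded.

.metricCore <- function(g, p, numFun) {
  x <- dosage(g)
  if (is.null(p)) p <- alleleFrequencies(g)
  usable <- !is.na(p) & p > 0 & p < 1
  x <- x[usable, , drop = FALSE]
  p <- p[usable]
  het2pq <- 2 * p * (1 - p)
  obs <- !is.na(x)
  denom <- crossprod(obs, het2pq)[, 1]
  num <- numFun(x, p, obs)
  out <- ifelse(denom > 0, num / denom, NA_real_)
  out[colSums(obs) == 0L] <- NA_real_
  structure(as.numeric(out), names = colnames(x),
            nMarkers = as.integer(colSums(obs)))
}

#' Genomic-relationship-matrix inbreeding (diagonal based)
#'
#' F = G_ii - 1 with G_ii = sum_j (x_ij - 2 p_j)^2 / sum_j 2 p_j (1 - p_j),
#' the self-relationship of the individual in the VanRaden genomic
#' relationship matrix; sums run over the individual's non-missing markers.
#'
#' @param g a \linkS4class{GenotypeMatrix} (freq-regime QC recommended).
#' @param p reference-allele frequencies (default: computed from \code{g}).
#' @return named numeric vector, one value per individual; the marker count
#'   used per individual is in the \code{"nMarkers"} attribute.
#' @export
fGrm <- function(g, p = NULL) {
  out <- .metricCore(g, p, function(x, p, obs) {
    z <- x - 2 * p            # recycled by column
    z[!obs] <- 0
    colSums(z * z)
  })
  out - 1
}

#' Observed-versus-expected homozygosity inbreeding
#'
#' F = (E_het - O_het) / E_het where E_het = sum_j 2 p_j (1 - p_j) and O_het
#' is the individual's observed heterozygote count, both over non-missing
#' markers.  Positive values mean fewer heterozygotes than expected under
#' Hardy-Weinberg, i.e. more homozygous than expected.
#'
#' @inheritParams fGrm
#' @return named numeric vector per individual.
#' @export
fHom1 <- function(g, p = NULL) {
  1 - .metricCore(g, p, function(x, p, obs) {
    h <- x == 1L
    h[!obs] <- FALSE
    colSums(h)
  })
}

#' Excess-homozygosity inbreeding from allele counts
#'
#' F = 1 - sum_j x_ij (2 - x_ij) / sum_j 2 p_j (1 - p_j); the numerator
#' counts heterozygous markers since x (2 - x) = 1 exactly when x = 1.
#'
#' @inheritParams fGrm
#' @return named numeric vector per individual.
#' @export
fHom2 <- function(g, p = NULL) {
  1 - .metricCore(g, p, function(x, p, obs) {
    v <- x * (2 - x)
    v[!obs] <- 0
    colSums(v)
  })
}

#' Inbreeding as the correlation between uniting gametes
#'
#' F = sum_j [x_ij^2 - (1 + 2 p_j) x_ij + 2 p_j^2] / sum_j 2 p_j (1 - p_j)
#' over the individual's non-missing markers.
#'
#' @inheritParams fGrm
#' @return named numeric vector per individual.
#' @export
fUni <- function(g, p = NULL) {
  .metricCore(g, p, function(x, p, obs) {
    v <- x * x - (1 + 2 * p) * x + 2 * p * p
    v[!obs] <- 0
    colSums(v)
  })
}

#' All four frequency-based genomic inbreeding coefficients
#'
#' Convenience wrapper computing [fGrm()], [fHom1()], [fHom2()] and [fUni()]
#' on a shared frequency vector (estimated once from the supplied, already
#' QC'd cohort).
#'
#' @inheritParams fGrm
#' @return data.frame with columns \code{animal}, \code{F_GRM},
#'   \code{F_HOM1}, \code{F_HOM2}, \code{F_UNI}, \code{n_markers}.
#' @export
genomicInbreeding <- function(g, p = NULL) {
  if (is.null(p)) p <- alleleFrequencies(g)
  grm <- fGrm(g, p)
  data.frame(
    animal = names(grm),
    F_GRM = as.vector(grm),
    F_HOM1 = as.vector(fHom1(g, p)),
    F_HOM2 = as.vector(fHom2(g, p)),
    F_UNI = as.vector(fUni(g, p)),
    n_markers = attr(grm, "nMarkers"),
    stringsAsFactors = FALSE)
}
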