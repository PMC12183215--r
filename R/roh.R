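## Runs of homozygosity: PLINK-style sliding-window detector, a brute-force
## reference scanner used as a testing oracle, and F_ROH with length-class
## decomposition.

.ROH_CLASSES <- c("<2Mb", "2-4Mb", "4-8Mb", "8-16Mb", ">16Mb")

.rohClass <- function(lengthBp) {
  ## half-open classes [lower, upper): a run of exactly 2.0 Mb is "2-4Mb"
  cut(lengthBp, breaks = c(0, 2e6, 4e6, 8e6, 16e6, Inf),
      labels = .ROH_CLASSES, right = FALSE)
}

#' ROH scanner parameters
#'
#' @param windowSnps,minSnps,minLengthKb,minDensityKbPerSnp,maxGapKb,windowHitThreshold,maxHetPerWindow,maxMissingPerWindow
#'   see \linkS4class{RohParams} for meanings and defaults.
#' @return a \linkS4class{RohParams} object.
#' @export
rohParams <- function(windowSnps = 50L, minSnps = 30L, minLengthKb = 500,
                      minDensityKbPerSnp = 50, maxGapKb = 1000,
                      windowHitThreshold = 0.05, maxHetPerWindow = 1L,
                      maxMissingPerWindow = 1L) {
  new("RohParams",
      windowSnps = as.integer(windowSnps), minSnps = as.integer(minSnps),
      minLengthKb = minLengthKb, minDensityKbPerSnp = minDensityKbPerSnp,
      maxGapKb = maxGapKb, windowHitThreshold = windowHitThreshold,
      maxHetPerWindow = as.integer(maxHetPerWindow),
      maxMissingPerWindow = as.integer(maxMissingPerWindow))
}

## shared run-level filtering: split candidate stretches at large gaps, then
## apply the SNP-count / length / density thresholds
.emitRuns <- function(candIdx, pos, params) {
  if (!length(candIdx)) return(NULL)
  brk <- which(diff(candIdx) > 1L |
               diff(pos[candIdx]) > params@maxGapKb * 1000)
  starts <- candIdx[c(1L, brk + 1L)]
  ends <- candIdx[c(brk, length(candIdx))]
  keep <- logical(length(starts))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    a <- starts[r]; b <- ends[r]
    nSnp <- b - a + 1L
    len <- pos[b] - pos[a] + 1
    if (nSnp >= params@minSnps &&
        len >= params@minLengthKb * 1000 &&
        len / nSnp <= params@minDensityKbPerSnp * 1000) {
      keep[r] <- TRUE
      out[[r]] <- c(start = pos[a], end = pos[b], n_snps = nSnp, length_bp = len)
    }
  }
  if (!any(keep)) return(NULL)
  do.call(rbind, out[keep])
}

## per-SNP fraction of qualifying ("hit") windows, vectorised with
## cumulative sums; truncated chromosomes (< windowSnps SNPs) are scanned
## with a single whole-chromosome window
.snpHitFraction <- function(het, mis, params) {
  S <- length(het)
  w <- min(params@windowSnps, S)
  nWin <- S - w + 1L
  cumHet <- c(0L, cumsum(het))
  cumMis <- c(0L, cumsum(mis))
  s <- seq_len(nWin)
  hit <- (cumHet[s + w] - cumHet[s]) <= params@maxHetPerWindow &
         (cumMis[s + w] - cumMis[s]) <= params@maxMissingPerWindow
  cumHit <- c(0L, cumsum(hit))
  i <- seq_len(S)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nWin)
  (cumHit[hi + 1L] - cumHit[lo]) / (hi - lo + 1L)
}

.scanChromosome <- function(geno, pos, params, hitFractionFun) {
  geno <- unname(geno)
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  frac <- hitFractionFun(het, mis, params)
  candIdx <- unname(which(frac >= params@windowHitThreshold))
  .emitRuns(candIdx, pos, params)
}

.rohScan <- function(g, params, hitFractionFun) {
  x <- dosage(g)
  map <- markerMap(g)
  ids <- sampleIds(g)
  chroms <- unique(map$chrom)
  res <- list()
  for (k in seq_along(ids)) {
    for (cc in chroms) {
      sel <- map$chrom == cc
      runs <- .scanChromosome(x[sel, k], map$pos[sel], params, hitFractionFun)
      if (!is.null(runs))
        res[[length(res) + 1L]] <-
          data.frame(animal = ids[k], chrom = cc,
                     start = runs[, "start"], end = runs[, "end"],
                     n_snps = as.integer(runs[, "n_snps"]),
                     length_bp = runs[, "length_bp"],
                     stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(animal = character(0), chrom = integer(0), start = numeric(0),
               end = numeric(0), n_snps = integer(0), length_bp = numeric(0),
               stringsAsFactors = FALSE)
  out$length_class <- .rohClass(out$length_bp)
  rownames(out) <- NULL
  out
}

#' Detect runs of homozygosity
#'
#' Slides a window of \code{windowSnps} SNPs along each chromosome of each
#' individual; a window "hits" when it contains at most
#' \code{maxHetPerWindow} heterozygous and \code{maxMissingPerWindow} missing
#' calls.  A SNP is a run candidate when the fraction of hitting windows
#' among the windows containing it reaches \code{windowHitThreshold}.
#' Maximal candidate stretches are split at inter-SNP gaps larger than
#' \code{maxGapKb} and reported when they satisfy the SNP-count, length and
#' density thresholds.  Chromosomes with fewer SNPs than the window size are
#' scanned with a single truncated window.
#'
#' @param g a \linkS4class{GenotypeMatrix} (ROH-regime QC recommended).
#' @param params a \linkS4class{RohParams} (defaults are the standard
#'   50K-panel settings).
#' @return data.frame of segments: \code{animal}, \code{chrom}, \code{start},
#'   \code{end}, \code{n_snps}, \code{length_bp} (= end - start + 1), and
#'   \code{length_class} with half-open bins <2 / 2-4 / 4-8 / 8-16 / >16 Mb.
#' @seealso [bruteForceRoh()] for the exhaustive reference implementation,
#'   [fRoh()] for genome-fraction coefficients.
#' @export
detectRoh <- function(g, params = rohParams()) {
  .rohScan(g, params, .snpHitFraction)
}

## exhaustive per-SNP hit fraction: visits every (window, SNP) pair
.snpHitFractionNaive <- function(het, mis, params) {
  S <- length(het)
  w <- min(params@windowSnps, S)
  nWin <- S - w + 1L
  hits <- integer(S)
  tot <- integer(S)
  for (s in seq_len(nWin)) {
    win <- s:(s + w - 1L)
    ok <- sum(het[win]) <= params@maxHetPerWindow &&
          sum(mis[win]) <= params@maxMissingPerWindow
    tot[win] <- tot[win] + 1L
    if (ok) hits[win] <- hits[win] + 1L
  }
  hits / tot
}

#' Brute-force ROH reference scanner
#'
#' Same run definition as [detectRoh()] but with the per-SNP window-hit
#' fractions computed exhaustively (every window inspected for every SNP).
#' Intended as an independent oracle on small inputs (<= 5,000 SNPs per
#' chromosome); not for production use.
#'
#' @inheritParams detectRoh
#' @return segment data.frame in the same format as [detectRoh()].
#' @export
bruteForceRoh <- function(g, params = rohParams()) {
  .rohScan(g, params, .snpHitFractionNaive)
}

#' ROH-based inbreeding coefficients
#'
#' F_ROH = (summed ROH length) / (total autosomal genome length), overall
#' and within each length class.  The genome length is the sum over
#' chromosomes of the maximum mapped position, taken from the same marker
#' map used for detection.
#'
#' @param segments output of [detectRoh()].
#' @param map marker map (data.frame with \code{chrom}, \code{pos}) defining
#'   the autosomal genome length.
#' @param animals cohort individual ids; animals without segments get 0.
#'   Defaults to the animals present in \code{segments}.
#' @return data.frame with columns \code{animal}, \code{F_ROH}, and one
#'   \code{F_ROH_<class>} column per length class; the genome length used is
#'   stored in the \code{"autosome_length_bp"} attribute.
#' @export
fRoh <- function(segments, map, animals = NULL) {
  if (nrow(map) == 0L) stop("empty marker map")
  genomeBp <- sum(tapply(map$pos, map$chrom, max))
  if (is.null(animals)) animals <- unique(segments$animal)
  classCols <- paste0("F_ROH_", c("lt2Mb", "2_4Mb", "4_8Mb", "8_16Mb", "gt16Mb"))
  out <- data.frame(animal = animals, F_ROH = 0, stringsAsFactors = FALSE)
  for (cl in classCols) out[[cl]] <- 0
  if (nrow(segments)) {
    tot <- tapply(segments$length_bp, segments$animal, sum) / genomeBp
    out$F_ROH[match(names(tot), out$animal)] <- as.numeric(tot)
    for (ci in seq_along(.ROH_CLASSES)) {
      sel <- segments$length_class == .ROH_CLASSES[ci]
      if (any(sel)) {
        s <- tapply(segments$length_bp[sel], segments$animal[sel], sum) / genomeBp
        out[[classCols[ci]]][match(names(s), out$animal)] <- as.numeric(s)
      }
    }
  }
  attr(out, "autosome_length_bp") <- genomeBp
  out
}
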