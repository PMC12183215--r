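#' @import methods
#' @import Matrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd var qnorm rnorm rbinom runif rpois model.matrix
#'   na.omit setNames aggregate ave reformulate lm.fit
#' @importFrom utils write.table packageVersion
#' @useDynLib InbreedKit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Pedigree of a livestock population
#'
#' An S4 container holding a topologically sorted pedigree: every parent
#' precedes its offspring.  Parents that were referenced but never listed as
#' animals are added as founders during construction.  Unknown parents are
#' stored as \code{NA}; founders have both parents unknown.
#'
#' @slot ids character vector of unique animal identifiers, in topological
#'   order.
#' @slot sire,dam integer indices into \code{ids} (\code{NA} = unknown).
#' @slot birthYear integer birth year per animal (\code{NA} = unknown).
#' @slot founder logical, \code{TRUE} when both parents are unknown.
#' @slot generation integer generation index: 0 for founders, otherwise
#'   1 + the maximum parental generation (longest path to a founder).
#'
#' @seealso [parsePedigree()], [computeFPed()], [buildAMatrix()]
#' @export
setClass("Pedigree",
  representation(
    ids        = "character",
    sire       = "integer",
    dam        = "integer",
    birthYear  = "integer",
    founder    = "logical",
    generation = "integer"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@ids)
  msgs <- character()
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "animal ids must be unique")
  for (s in c("sire", "dam", "birthYear", "founder", "generation")) {
    if (length(slot(object, s)) != n)
      msgs <- c(msgs, sprintf("slot '%s' must have length %d", s, n))
  }
  if (length(msgs)) return(msgs)
  ok <- is.na(object@sire) | object@sire < seq_len(n)
  if (!all(ok))
    msgs <- c(msgs, "pedigree is not topologically sorted (a sire follows its offspring)")
  ok <- is.na(object@dam) | object@dam < seq_len(n)
  if (!all(ok))
    msgs <- c(msgs, "pedigree is not topologically sorted (a dam follows its offspring)")
  if (!all(object@founder == (is.na(object@sire) & is.na(object@dam))))
    msgs <- c(msgs, "founder flags inconsistent with parent links")
  if (length(msgs)) msgs else TRUE
})

#' Genotype dosage matrix with a marker map
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment}: rows are biallelic
#' autosomal SNPs (with \code{chrom}, \code{pos}, \code{id} in the row data),
#' columns are individuals, and the single assay \code{"dosage"} stores the
#' count of reference-allele copies (0, 1, 2, or \code{NA} for a missing
#' call).  Markers are kept sorted by (chromosome, position).
#'
#' @seealso [readGenotypes()], [applyQc()], [detectRoh()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "id")
  if (!all(need %in% colnames(rd)))
    return(sprintf("row data must contain columns: %s", paste(need, collapse = ", ")))
  x <- SummarizedExperiment::assay(object, "dosage")
  v <- x[!is.na(x)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    msgs <- c(msgs, "dosage values must be 0, 1, 2 or NA")
  if (any(rd$pos < 0))
    msgs <- c(msgs, "marker positions must be nonnegative")
  o <- order(rd$chrom, rd$pos)
  if (!identical(o, seq_len(nrow(rd))) && nrow(rd) > 1L)
    msgs <- c(msgs, "markers must be sorted by (chromosome, position)")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the sliding-window ROH scanner
#'
#' Defaults follow common practice for 50K-density bovine panels: a
#' 50-SNP sliding window allowing at most one heterozygous and one missing
#' call, a per-SNP hit-fraction threshold of 0.05, and run-level filters of
#' at least 30 SNPs, 500 kb length, 1 SNP per 50 kb density, and a maximum
#' 1,000 kb gap between consecutive SNPs.
#'
#' @slot windowSnps integer, SNPs per sliding window.
#' @slot minSnps integer, minimum SNPs in an accepted run.
#' @slot minLengthKb numeric, minimum run length (kb).
#' @slot minDensityKbPerSnp numeric, maximum kb per SNP inside a run.
#' @slot maxGapKb numeric, maximum gap between consecutive SNPs in a run (kb).
#' @slot windowHitThreshold numeric in (0, 1], minimum fraction of
#'   homozygous-looking windows covering a SNP for it to be a candidate.
#' @slot maxHetPerWindow,maxMissingPerWindow integer caps per window.
#'
#' @seealso [rohParams()], [detectRoh()]
#' @export
setClass("RohParams",
  representation(
    windowSnps          = "integer",
    minSnps             = "integer",
    minLengthKb         = "numeric",
    minDensityKbPerSnp  = "numeric",
    maxGapKb            = "numeric",
    windowHitThreshold  = "numeric",
    maxHetPerWindow     = "integer",
    maxMissingPerWindow = "integer"
  ),
  prototype(
    windowSnps          = 50L,
    minSnps             = 30L,
    minLengthKb         = 500,
    minDensityKbPerSnp  = 50,
    maxGapKb            = 1000,
    windowHitThreshold  = 0.05,
    maxHetPerWindow     = 1L,
    maxMissingPerWindow = 1L
  )
)

setValidity("RohParams", function(object) {
  vals <- c(object@windowSnps, object@minSnps, object@minLengthKb,
            object@minDensityKbPerSnp, object@maxGapKb)
  if (any(vals <= 0)) return("all ROH parameters must be positive")
  if (object@windowHitThreshold <= 0 || object@windowHitThreshold > 1)
    return("windowHitThreshold must lie in (0, 1]")
  if (object@maxHetPerWindow < 0 || object@maxMissingPerWindow < 0)
    return("per-window het/missing caps must be nonnegative")
  TRUE
})

#' Fitted inbreeding-depression model
#'
#' Result of [remlFit()]: variance components of the chosen animal-model
#' structure, the regression of the phenotype on the inbreeding covariate
#' (beta, its standard error, the 95\% normal confidence interval
#' beta +/- 1.96 se), and convergence diagnostics of the AI-REML run.
#'
#' @slot varcomp named numeric vector of variance components (always ends in
#'   \code{sigma2_e}).
#' @slot beta,se numeric scalars: slope on the inbreeding covariate and its
#'   standard error.
#' @slot ci numeric length-2: 95\% confidence interval for beta.
#' @slot significant logical: \code{TRUE} when the CI excludes zero.
#' @slot covariate name of the inbreeding covariate that was fitted.
#' @slot structure random-effect structure used.
#' @slot fixedEffects estimates of all fixed-effect coefficients.
#' @slot converged,iterations convergence flag and iteration count.
#' @slot details list with the iteration trace, boundary flags, problem sizes.
#' @export
setClass("DepressionFit",
  representation(
    varcomp      = "numeric",
    beta         = "numeric",
    se           = "numeric",
    ci           = "numeric",
    significant  = "logical",
    covariate    = "character",
    structure    = "character",
    fixedEffects = "numeric",
    converged    = "logical",
    iterations   = "integer",
    details      = "list"
  )
)

setValidity("DepressionFit", function(object) {
  if (length(object@ci) != 2L) return("ci must have length 2")
  if (any(object@varcomp < 0)) return("variance components must be nonnegative")
  TRUE
})
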