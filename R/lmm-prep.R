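## Phenotype preparation and animal-model design assembly for the
## inbreeding-depression regressions.

#' Prepare phenotypes for analysis
#'
#' Applies the standard editing rules for field records: contemporary-group
#' outlier removal for continuous traits (records beyond \code{sdLimit}
#' standard deviations of their group mean, z computed with the candidate
#' record included and an n-1 denominator; ties at the limit are kept),
#' removal of groups smaller than \code{minGroupSize}, and, for score
#' traits, removal of groups with no within-group variance.  Count traits
#' are first transformed to \code{log10(count + countOffset)}.
#'
#' @param pheno data.frame with at least the trait and group columns.
#' @param ped optional \linkS4class{Pedigree}; when given, records for
#'   animals absent from the pedigree are an error.
#' @param traitKind "continuous", "score", or "count".
#' @param trait,group,animalCol column names of the trait value, the
#'   contemporary group, and the animal id.
#' @param sdLimit outlier threshold in within-group SD units (default 3.5).
#' @param minGroupSize minimum contemporary-group size kept (default 3).
#' @param countOffset constant added before the log10 transform of counts
#'   (default 1.001, so a zero count maps to log10(1.001)).
#' @return the filtered data.frame; removal counts per rule are in the
#'   \code{"filterLog"} attribute.
#' @export
preparePhenotypes <- function(pheno, ped = NULL,
                              traitKind = c("continuous", "score", "count"),
                              trait = "y", group = "cg", animalCol = "animal",
                              sdLimit = 3.5, minGroupSize = 3L,
                              countOffset = 1.001) {
  traitKind <- match.arg(traitKind)
  stopifnot(trait %in% names(pheno), group %in% names(pheno))
  if (!is.null(ped)) {
    missing <- setdiff(pheno[[animalCol]], pedIds(ped))
    if (length(missing))
      stop("phenotyped animal(s) absent from pedigree: ",
           paste(head(missing, 5), collapse = ", "))
  }
  log <- c(outliers = 0L, small_groups = 0L, novar_groups = 0L)
  if (traitKind == "count")
    pheno[[trait]] <- log10(pheno[[trait]] + countOffset)

  if (traitKind %in% c("continuous", "count")) {
    gmean <- ave(pheno[[trait]], pheno[[group]], FUN = mean)
    gsd <- ave(pheno[[trait]], pheno[[group]], FUN = sd)
    z <- ifelse(is.na(gsd) | gsd == 0, 0,
                (pheno[[trait]] - gmean) / gsd)
    keep <- abs(z) <= sdLimit          # "exceeding": ties at the limit kept
    log["outliers"] <- sum(!keep)
    pheno <- pheno[keep, , drop = FALSE]
  }
  cnt <- ave(seq_len(nrow(pheno)), pheno[[group]], FUN = length)
  keep <- cnt >= minGroupSize
  log["small_groups"] <- sum(!keep)
  pheno <- pheno[keep, , drop = FALSE]
  if (traitKind == "score") {
    gvar <- ave(pheno[[trait]], pheno[[group]], FUN = var)
    keep <- !is.na(gvar) & gvar > 0
    log["novar_groups"] <- sum(!keep)
    pheno <- pheno[keep, , drop = FALSE]
  }
  rownames(pheno) <- NULL
  attr(pheno, "filterLog") <- log
  pheno
}

#' Assemble animal-model design matrices
#'
#' Builds the fixed-effects design (intercept, declared factors and
#' covariates, with the inbreeding coefficient as the last column), the
#' incidence matrices of the requested random structure, and the inverse
#' relationship matrix by Henderson's rules (accounting for inbreeding).
#' Aliased fixed-effect columns are dropped with a message; a constant
#' inbreeding covariate is an error because its slope would be confounded
#' with the intercept.
#'
#' Random structures: \code{animal_only} (additive genetic effect only),
#' \code{animal_maternal_mpe} (adds a maternal genetic effect and a maternal
#' permanent-environment effect, both indexed by the record's dam), and
#' \code{animal_pe} (adds a permanent-environment effect over repeated
#' records of the same animal).
#'
#' @param pheno prepared phenotype data.frame (see [preparePhenotypes()]).
#' @param ped a \linkS4class{Pedigree} covering all phenotyped animals.
#' @param covariate name of the inbreeding-coefficient column.
#' @param structure one of \code{"animal_only"}, \code{"animal_maternal_mpe"},
#'   \code{"animal_pe"}.
#' @param fixedFactors columns treated as categorical fixed effects.
#' @param covariates columns treated as numeric covariates (e.g. age; add a
#'   squared column yourself for quadratic terms).
#' @param trait,animalCol trait and animal-id column names.
#' @return list with \code{y}, \code{X}, \code{random} (for [aiReml()]),
#'   bookkeeping in \code{meta}.
#' @export
buildDesign <- function(pheno, ped, covariate,
                        structure = c("animal_only", "animal_maternal_mpe",
                                      "animal_pe"),
                        fixedFactors = character(), covariates = character(),
                        trait = "y", animalCol = "animal") {
  structure <- match.arg(structure)
  y <- pheno[[trait]]
  n <- length(y)
  aIdx <- match(pheno[[animalCol]], pedIds(ped))
  if (anyNA(aIdx))
    stop("animal(s) not in pedigree: ",
         paste(head(unique(pheno[[animalCol]][is.na(aIdx)]), 5), collapse = ", "))
  fvals <- pheno[[covariate]]
  if (is.null(fvals)) stop("inbreeding covariate '", covariate, "' not found")
  if (sd(fvals) == 0)
    stop("inbreeding covariate '", covariate,
         "' is constant: its slope is confounded with the intercept")

  df <- pheno
  for (f in fixedFactors) df[[f]] <- factor(df[[f]])
  form <- stats::reformulate(c("1", fixedFactors, covariates, covariate))
  X <- stats::model.matrix(form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    if (covariate %in% dropped)
      stop("inbreeding covariate '", covariate,
           "' is aliased with other fixed effects")
    message("dropping aliased fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }

  f <- computeFPed(ped)
  Ainv <- aInverse(ped, f)
  nA <- nAnimals(ped)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = aIdx, x = 1,
                             dims = c(n, nA))
  random <- list(list(Z = Za, Kinv = Ainv, name = "a"))

  if (structure == "animal_maternal_mpe") {
    damIdx <- ped@dam[aIdx]
    if (anyNA(damIdx))
      stop("maternal-effect model requires a known dam for every record")
    Wm <- Matrix::sparseMatrix(i = seq_len(n), j = damIdx, x = 1,
                               dims = c(n, nA))
    damLev <- sort(unique(damIdx))
    Cm <- Matrix::sparseMatrix(i = seq_len(n), j = match(damIdx, damLev),
                               x = 1, dims = c(n, length(damLev)))
    random <- c(random,
                list(list(Z = Wm, Kinv = Ainv, name = "m")),
                list(list(Z = Cm, Kinv = Matrix::Diagonal(length(damLev)),
                          name = "mpe")))
  } else if (structure == "animal_pe") {
    peLev <- sort(unique(aIdx))
    Wpe <- Matrix::sparseMatrix(i = seq_len(n), j = match(aIdx, peLev),
                                x = 1, dims = c(n, length(peLev)))
    random <- c(random,
                list(list(Z = Wpe, Kinv = Matrix::Diagonal(length(peLev)),
                          name = "pe")))
  }
  list(y = y, X = X, random = random,
       meta = list(structure = structure, covariate = covariate,
                   n = n, p = ncol(X), animals = pheno[[animalCol]],
                   traitMean = mean(y)))
}

#' Estimate inbreeding depression by animal-model REML
#'
#' Fits the assembled design with [aiReml()] and reports the regression of
#' the phenotype on the inbreeding covariate: beta, its standard error, the
#' 95\% confidence interval beta +/- 1.96 se, and whether the interval
#' excludes zero.
#'
#' @param design output of [buildDesign()].
#' @param ... passed to [aiReml()] (tolerance, iteration limits, start
#'   values).
#' @return a \linkS4class{DepressionFit}.
#' @export
remlFit <- function(design, ...) {
  fit <- aiReml(design$y, design$X, design$random, ...)
  cov <- design$meta$covariate
  j <- match(cov, colnames(design$X))
  beta <- unname(fit$beta[j])
  se <- unname(fit$seBeta[j])
  ci <- beta + c(-1.96, 1.96) * se
  new("DepressionFit",
      varcomp = fit$varcomp,
      beta = beta, se = se, ci = ci,
      significant = ci[1] > 0 || ci[2] < 0,
      covariate = cov,
      structure = design$meta$structure,
      fixedEffects = fit$beta,
      converged = fit$converged,
      iterations = as.integer(fit$iterations),
      details = list(boundaryFlags = fit$boundaryFlags,
                     trace = fit$trace,
                     n = design$meta$n, p = design$meta$p,
                     traitMean = design$meta$traitMean))
}

#' Percent depression per 1\% increase in inbreeding
#'
#' 100 x (beta x 0.01) / trait mean: the percent change of the trait mean
#' caused by one percentage point of inbreeding.  The mean defaults to the
#' post-filter mean of the analysed records (stored in the fit).
#'
#' @param fit a \linkS4class{DepressionFit}.
#' @param traitMean trait mean used as the denominator; must be positive
#'   (traits on a transformed scale should be reported as beta per 0.01 F
#'   instead).
#' @return percent change per 1\% inbreeding (sign preserved).
#' @export
percentDepression <- function(fit, traitMean = fit@details$traitMean) {
  if (is.null(traitMean) || !is.finite(traitMean) || traitMean <= 0)
    stop("trait mean must be positive; report beta per 0.01 F for transformed traits")
  100 * (fit@beta * 0.01) / traitMean
}
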