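#' @rdname Pedigree-class
#' @param x,object a \linkS4class{Pedigree}.
#' @export
setGeneric("pedIds", function(x) standardGeneric("pedIds"))

#' @rdname Pedigree-class
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname Pedigree-class
#' @export
setGeneric("isFounder", function(x) standardGeneric("isFounder"))

#' @rdname Pedigree-class
#' @export
setGeneric("generationIndex", function(x) standardGeneric("generationIndex"))

#' @rdname Pedigree-class
#' @export
setGeneric("birthYears", function(x) standardGeneric("birthYears"))

#' @rdname Pedigree-class
#' @export
setGeneric("parentIds", function(x) standardGeneric("parentIds"))

#' @rdname GenotypeMatrix-class
#' @param x,object a \linkS4class{GenotypeMatrix}.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

setMethod("pedIds", "Pedigree", function(x) x@ids)
setMethod("nAnimals", "Pedigree", function(x) length(x@ids))
setMethod("isFounder", "Pedigree", function(x) setNames(x@founder, x@ids))
setMethod("generationIndex", "Pedigree", function(x) setNames(x@generation, x@ids))
setMethod("birthYears", "Pedigree", function(x) setNames(x@birthYear, x@ids))

#' @describeIn Pedigree-class data.frame of (animal, sire, dam) identifiers,
#'   \code{NA} for unknown parents.
setMethod("parentIds", "Pedigree", function(x) {
  data.frame(
    animal = x@ids,
    sire   = ifelse(is.na(x@sire), NA_character_, x@ids[x@sire]),
    dam    = ifelse(is.na(x@dam), NA_character_, x@ids[x@dam]),
    stringsAsFactors = FALSE
  )
})

setMethod("show", "Pedigree", function(object) {
  n <- nAnimals(object)
  cat(sprintf("Pedigree with %d animals\n", n))
  cat(sprintf("  founders: %d | sires: %d | dams: %d | max generation: %d\n",
              sum(object@founder),
              length(unique(na.omit(object@sire))),
              length(unique(na.omit(object@dam))),
              if (n) max(object@generation) else 0L))
  yr <- object@birthYear
  if (any(!is.na(yr)))
    cat(sprintf("  birth years: %d-%d (%d unknown)\n",
                min(yr, na.rm = TRUE), max(yr, na.rm = TRUE), sum(is.na(yr))))
  invisible(object)
})

setMethod("dosage", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypeMatrix-class marker map as a data.frame with columns
#'   \code{chrom}, \code{pos}, \code{id}, one row per SNP in matrix order.
setMethod("markerMap", "GenotypeMatrix", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(chrom = rd$chrom, pos = rd$pos, id = rd$id,
             stringsAsFactors = FALSE)
})

setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))

setMethod("show", "GenotypeMatrix", function(object) {
  x <- dosage(object)
  cat(sprintf("GenotypeMatrix: %d SNPs x %d individuals\n",
              nrow(x), ncol(x)))
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("  chromosomes: %s | missing calls: %.2f%%\n",
              paste(range(rd$chrom), collapse = "-"),
              100 * mean(is.na(x))))
  invisible(object)
})

setMethod("show", "RohParams", function(object) {
  cat("RohParams:\n")
  cat(sprintf("  window %d SNPs (<= %d het, <= %d missing), hit threshold %.3g\n",
              object@windowSnps, object@maxHetPerWindow,
              object@maxMissingPerWindow, object@windowHitThreshold))
  cat(sprintf("  run filters: >= %d SNPs, >= %g kb, <= %g kb/SNP, gap <= %g kb\n",
              object@minSnps, object@minLengthKb, object@minDensityKbPerSnp,
              object@maxGapKb))
  invisible(object)
})

setMethod("show", "DepressionFit", function(object) {
  cat(sprintf("DepressionFit (%s structure, covariate '%s')\n",
              object@structure, object@covariate))
  vc <- object@varcomp
  cat("  variance components:\n")
  for (nm in names(vc)) cat(sprintf("    %-10s %.6g\n", nm, vc[[nm]]))
  cat(sprintf("  beta = %.6g (se %.4g), 95%% CI [%.6g, %.6g]%s\n",
              object@beta, object@se, object@ci[1], object@ci[2],
              if (object@significant) " *" else ""))
  cat(sprintf("  %s in %d iterations\n",
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
  invisible(object)
})
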