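## End-to-end driver: simulate (or read) a cohort, run both QC regimes, all
## six inbreeding metrics, ROH detection, concordance reporting, and the
## inbreeding-depression regressions, writing every result as TSV/JSON.

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete inbreeding analysis
#'
#' Either simulates a cohort from \code{cfg} (writing the pedigree,
#' genotypes and phenotypes as plain files first, then reading them back
#' through the package parsers so the file interfaces are exercised) or
#' consumes user-supplied files.  Produces, under \code{outDir}: QC reports,
#' per-animal coefficients for every metric, ROH segments (BED-like TSV),
#' the joined inbreeding table, summary statistics, Pearson concordance,
#' top-decile overlap, per-year trends, depression fits (TSV + JSON), and a
#' JSON run log with the seed and parameters.
#'
#' @param outDir output directory (created if needed).
#' @param cfg optional [simConfig()] used to simulate the cohort.
#' @param pedigreePath,genotypePath,phenotypePath input files used when
#'   \code{cfg} is \code{NULL} (delimited pedigree; .ped or .vcf genotypes;
#'   phenotype table with columns animal, y, cg).
#' @param covariates inbreeding covariates to regress phenotypes on
#'   (default \code{c("F_PED", "F_ROH")}).
#' @param structure random structure for the depression fits.
#' @param rohArgs list of [rohParams()] overrides.
#' @return invisibly, a named list of all result objects.
#' @export
runPipeline <- function(outDir, cfg = NULL, pedigreePath = NULL,
                        genotypePath = NULL, phenotypePath = NULL,
                        covariates = c("F_PED", "F_ROH"),
                        structure = "animal_only", rohArgs = list()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg)) {
    inDir <- file.path(outDir, "inputs")
    dir.create(inDir, showWarnings = FALSE)
    ped0 <- simulatePedigree(cfg)
    drop <- geneDrop(ped0, cfg)
    pheno0 <- simulatePhenotypes(ped0, setNames(computeFPed(ped0), pedIds(ped0)),
                                 cfg, structure = structure)
    pedigreePath <- file.path(inDir, "pedigree.tsv")
    pp <- parentIds(ped0)
    pp[is.na(pp)] <- "0"
    pp$birth_year <- unname(birthYears(ped0))
    names(pp)[1] <- "animal"
    .writeTsv(pp, pedigreePath)
    genotypePath <- file.path(inDir, "cohort.ped")
    writePedMap(drop$geno, file.path(inDir, "cohort"))
    phenotypePath <- file.path(inDir, "phenotypes.tsv")
    .writeTsv(pheno0, phenotypePath)
    jsonlite::write_json(drop$truth, file.path(inDir, "truth.json"),
                         digits = NA)
  }
  ped <- parsePedigree(pedigreePath)
  geno <- suppressWarnings(readGenotypes(genotypePath))
  pheno <- data.table::fread(phenotypePath, data.table = FALSE)

  gRoh <- applyQc(geno, "roh")
  gFreq <- applyQc(geno, "freq")
  .writeTsv(attr(gRoh, "qcReport"), file.path(outDir, "qc_report_roh.tsv"))
  .writeTsv(attr(gFreq, "qcReport"), file.path(outDir, "qc_report_freq.tsv"))

  fped <- computeFPed(ped)
  .writeTsv(data.frame(animal = names(fped), F_PED = unname(fped)),
            file.path(outDir, "pedigree_inbreeding.tsv"))
  genomic <- genomicInbreeding(gFreq)
  .writeTsv(genomic, file.path(outDir, "genomic_inbreeding.tsv"))

  params <- do.call(rohParams, rohArgs)
  segments <- detectRoh(gRoh, params)
  .writeTsv(segments, file.path(outDir, "roh_segments.tsv"))
  roh <- fRoh(segments, markerMap(gRoh), animals = sampleIds(gRoh))
  .writeTsv(roh, file.path(outDir, "roh_inbreeding.tsv"))

  tab <- inbreedingTable(fped, genomic, roh, ped)
  .writeTsv(tab, file.path(outDir, "inbreeding_table.tsv"))
  summ <- metricSummary(tab)
  .writeTsv(summ, file.path(outDir, "metric_summary.tsv"))
  corr <- metricCorrelations(tab)
  .writeTsv(data.frame(metric = rownames(corr), corr, check.names = FALSE),
            file.path(outDir, "metric_correlations.tsv"))
  ovl <- topDecileOverlap(tab)
  .writeTsv(data.frame(metric = rownames(ovl$pairwise), ovl$pairwise,
                       check.names = FALSE),
            file.path(outDir, "top_decile_overlap.tsv"))
  trend <- trendByYear(tab)
  .writeTsv(trend, file.path(outDir, "trend_by_year.tsv"))

  fits <- list()
  fitRows <- list()
  for (cv in covariates) {
    ph <- merge(pheno, tab[c("animal", cv)], by = "animal")
    ph <- ph[!is.na(ph[[cv]]), , drop = FALSE]
    des <- buildDesign(ph, ped, covariate = cv, structure = structure,
                       fixedFactors = intersect("cg", names(ph)))
    fit <- remlFit(des)
    fits[[cv]] <- fit
    fitRows[[cv]] <- data.frame(
      covariate = cv, beta = fit@beta, se = fit@se,
      ci_lower = fit@ci[1], ci_upper = fit@ci[2],
      significant = fit@significant,
      percent_per_1pct = percentDepression(fit),
      stringsAsFactors = FALSE)
  }
  fitTab <- do.call(rbind, fitRows)
  .writeTsv(fitTab, file.path(outDir, "depression_fits.tsv"))
  jsonlite::write_json(
    lapply(fits, function(f)
      list(varcomp = as.list(f@varcomp), beta = f@beta, se = f@se,
           ci = f@ci, significant = f@significant,
           iterations = f@iterations)),
    file.path(outDir, "depression_fits.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(package = "InbreedKit",
         version = as.character(utils::packageVersion("InbreedKit")),
         seed = if (!is.null(cfg)) cfg$seed else NA,
         time = format(Sys.time(), tz = "UTC"),
         covariates = covariates, structure = structure),
    file.path(outDir, "run_log.json"), auto_unbox = TRUE)

  invisible(list(pedigree = ped, genotypes = geno, fped = fped,
                 genomic = genomic, segments = segments, roh = roh,
                 table = tab, summary = summ, correlations = corr,
                 overlap = ovl, trend = trend, fits = fits,
                 fitTable = fitTab))
}
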