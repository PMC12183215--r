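## Genotype input/output: PLINK-text (.ped/.map) and VCF, plus writers used
## by the simulator so the pipeline can be exercised through real files.

#' Construct a GenotypeMatrix from a dosage matrix and marker map
#'
#' @param dosage integer matrix, markers x individuals, values 0/1/2/NA
#'   (reference-allele copies).
#' @param map data.frame with columns \code{chrom}, \code{pos}, \code{id},
#'   one row per marker.
#' @param sampleIds individual identifiers (default: dosage colnames).
#' @return a \linkS4class{GenotypeMatrix}, markers sorted by
#'   (chromosome, position).
#' @export
GenotypeMatrix <- function(dosage, map, sampleIds = colnames(dosage)) {
  stopifnot(nrow(dosage) == nrow(map))
  if (is.null(sampleIds))
    sampleIds <- paste0("ind", seq_len(ncol(dosage)))
  mode(dosage) <- "integer"
  o <- order(map$chrom, map$pos)
  dosage <- dosage[o, , drop = FALSE]
  map <- map[o, , drop = FALSE]
  rownames(dosage) <- map$id
  colnames(dosage) <- sampleIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(chrom = as.integer(map$chrom),
                                   pos = as.numeric(map$pos),
                                   id = as.character(map$id)))
  new("GenotypeMatrix", se)
}

.readPedMap <- function(pedPath, mapPath, nAutosomes) {
  map <- data.table::fread(mapPath, header = FALSE)
  if (ncol(map) == 3L) map <- map[, c(1, 2, 2, 3), with = FALSE]
  if (ncol(map) != 4L)
    stop(".map file must have 3 or 4 columns (chrom, id[, cM], bp): ", mapPath)
  names(map) <- c("chrom", "id", "cm", "pos")
  chrom <- suppressWarnings(as.integer(sub("^chr", "", map$chrom)))
  nMark <- nrow(map)

  lines <- readLines(pedPath)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  dosage <- matrix(NA_integer_, nrow = nMark, ncol = n)
  ids <- character(n)
  refAllele <- rep(NA_character_, nMark)
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(fields) != 6L + 2L * nMark)
      stop(sprintf(".ped line %d has %d fields, expected %d (6 + 2 x %d markers)",
                   k, length(fields), 6L + 2L * nMark, nMark))
    ids[k] <- fields[2]
    a1 <- fields[seq(7L, by = 2L, length.out = nMark)]
    a2 <- fields[seq(8L, by = 2L, length.out = nMark)]
    miss <- a1 == "0" | a2 == "0"
    newRef <- is.na(refAllele) & !miss
    refAllele[newRef] <- a1[newRef]
    dosage[, k] <- ifelse(miss, NA_integer_,
                          (a1 == refAllele) + (a2 == refAllele))
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", pedPath)
  warning("reference allele for .ped input taken as the first allele observed per marker")
  list(dosage = dosage,
       map = data.frame(chrom = chrom, pos = as.numeric(map$pos),
                        id = as.character(map$id)),
       ids = ids, ref = refAllele)
}

.readVcfGenotypes <- function(path, nAutosomes) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix[, "ALT"])
  chrom <- suppressWarnings(as.integer(sub("^chr", "", fix[, "CHROM"])))
  keepIdx <- which(!multi)
  alleleCount <- function(g) {
    out <- rep(NA_integer_, length(g))
    g <- sub("\\|", "/", g)
    ok <- g %in% c("0/0", "0/1", "1/0", "1/1")
    ## dosage counts the REF allele (allele code 0)
    out[g == "0/0"] <- 2L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 0L
    out
  }
  dosage <- apply(gt[keepIdx, , drop = FALSE], 2, alleleCount)
  dosage <- matrix(as.integer(dosage), nrow = length(keepIdx),
                   dimnames = list(NULL, colnames(gt)))
  list(dosage = dosage,
       map = data.frame(chrom = chrom[keepIdx],
                        pos = as.numeric(fix[keepIdx, "POS"]),
                        id = as.character(fix[keepIdx, "ID"])),
       ids = colnames(gt),
       dropped_multiallelic = sum(multi))
}

#' Read genotypes from PLINK-text or VCF
#'
#' Accepts either a paired \code{.ped}/\code{.map} fileset or a VCF (plain or
#' bgzipped) with a GT field.  Only biallelic SNPs on autosomes 1..29 are
#' retained; multiallelic and non-autosomal records are dropped and counted
#' in the \code{"dropped"} attribute.  Dosage counts copies of the reference
#' allele: the VCF REF allele, or (with a warning) the first allele observed
#' per marker for \code{.ped} input.
#'
#' @param path path to a \code{.ped} or \code{.vcf}/\code{.vcf.gz} file; for
#'   PLINK text the matching \code{.map} is found by extension substitution
#'   unless \code{mapPath} is given.
#' @param mapPath optional explicit \code{.map} path.
#' @param nAutosomes number of autosomes retained (default 29, cattle).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, mapPath = NULL, nAutosomes = 29L) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    raw <- .readVcfGenotypes(path, nAutosomes)
  } else if (grepl("\\.ped$", path)) {
    if (is.null(mapPath)) mapPath <- sub("\\.ped$", ".map", path)
    if (!file.exists(mapPath)) stop("matching .map file not found: ", mapPath)
    raw <- .readPedMap(path, mapPath, nAutosomes)
  } else {
    stop("unrecognised genotype file (expect .ped or .vcf[.gz]): ", path)
  }
  auto <- !is.na(raw$map$chrom) & raw$map$chrom >= 1L & raw$map$chrom <= nAutosomes
  g <- GenotypeMatrix(raw$dosage[auto, , drop = FALSE],
                      raw$map[auto, , drop = FALSE], raw$ids)
  attr(g, "dropped") <- c(non_autosomal = sum(!auto),
                          multiallelic = raw$dropped_multiallelic %||% 0L)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GenotypeMatrix as PLINK-text .ped/.map
#'
#' Alleles are written as A (reference) and B; missing calls as 0.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param prefix output path prefix (writes \code{prefix.ped} and
#'   \code{prefix.map}).
#' @return invisibly, the two file paths.
#' @export
writePedMap <- function(g, prefix) {
  map <- markerMap(g)
  x <- dosage(g)
  data.table::fwrite(data.table::data.table(map$chrom, map$id, 0, map$pos),
                     paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  ids <- sampleIds(g)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  a1 <- c("B", "A", "A"); a2 <- c("B", "B", "A")
  for (k in seq_along(ids)) {
    xk <- x[, k]
    al1 <- ifelse(is.na(xk), "0", a1[xk + 1L])
    al2 <- ifelse(is.na(xk), "0", a2[xk + 1L])
    geno <- character(2L * length(xk))
    geno[c(TRUE, FALSE)] <- al1
    geno[c(FALSE, TRUE)] <- al2
    writeLines(paste(c("FAM", ids[k], "0", "0", "0", "-9", geno),
                     collapse = " "), con)
  }
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotype columns (REF = A, ALT = B) so
#' the cohort round-trips through [readGenotypes()].
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeVcf <- function(g, path) {
  map <- markerMap(g)
  x <- dosage(g)
  gtCode <- c("1/1", "0/1", "0/0")  # dosage 0,1,2 reference copies
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(map$chrom), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(g)), collapse = "\t")), con)
  gt <- matrix("./.", nrow = nrow(x), ncol = ncol(x))
  ok <- !is.na(x)
  gt[ok] <- gtCode[x[ok] + 1L]
  body <- cbind(map$chrom, map$pos, map$id, "A", "B", ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
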