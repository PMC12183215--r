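## Cross-metric concordance and summary reporting.

#' Assemble the per-animal inbreeding table
#'
#' Joins pedigree F, the four genomic coefficients, and the ROH-based
#' coefficients into one row per animal (missing values propagated, never
#' imputed), with birth year when a pedigree is supplied.
#'
#' @param fped named [computeFPed()] output (optional).
#' @param genomic [genomicInbreeding()] output (optional).
#' @param roh [fRoh()] output (optional).
#' @param ped optional \linkS4class{Pedigree} contributing birth years.
#' @return data.frame keyed by \code{animal} with one column per metric.
#' @export
inbreedingTable <- function(fped = NULL, genomic = NULL, roh = NULL,
                            ped = NULL) {
  pieces <- list()
  if (!is.null(fped))
    pieces$fped <- data.frame(animal = names(fped), F_PED = unname(fped),
                              stringsAsFactors = FALSE)
  if (!is.null(genomic)) pieces$genomic <- genomic[setdiff(names(genomic),
                                                           "n_markers")]
  if (!is.null(roh)) pieces$roh <- roh
  if (!length(pieces)) stop("at least one metric source is required")
  out <- Reduce(function(a, b) merge(a, b, by = "animal", all = TRUE), pieces)
  if (!is.null(ped)) {
    yr <- birthYears(ped)
    out$birth_year <- unname(yr[match(out$animal, names(yr))])
  }
  out
}

.metricCols <- function(table) {
  setdiff(names(table), c("animal", "birth_year"))
}

#' Per-metric summary statistics
#'
#' n, min, max, mean and SD (n-1 denominator) over non-missing values of
#' each metric column; an all-missing column is reported with n = 0.
#'
#' @param table an [inbreedingTable()].
#' @return data.frame with one row per metric.
#' @export
metricSummary <- function(table) {
  stopifnot(nrow(table) > 0L)
  cols <- .metricCols(table)
  do.call(rbind, lapply(cols, function(cl) {
    v <- table[[cl]][!is.na(table[[cl]])]
    data.frame(metric = cl, n = length(v),
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else
                 if (length(v) == 1) 0 else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Pairwise Pearson correlations between metrics
#'
#' Pairwise-complete Pearson correlations (so a missing pedigree F does not
#' discard an animal's genomic metrics); cells with fewer than
#' \code{minPairs} complete pairs are set to \code{NA}.
#'
#' @param table an [inbreedingTable()].
#' @param minPairs minimum complete pairs per cell (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
metricCorrelations <- function(table, minPairs = 3L) {
  cols <- .metricCols(table)
  m <- as.matrix(table[cols])
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(m))
  r[npair < minPairs] <- NA_real_
  diag(r) <- 1
  r
}

#' Overlap of the most inbred animals across metrics
#'
#' For each metric, the top decile is the \code{ceiling(fraction * n)}
#' animals with the highest coefficients among non-missing values (ties
#' broken by the stable animal order of the table).  Returns pairwise
#' intersection counts and the size of the intersection across all metrics.
#'
#' @param table an [inbreedingTable()].
#' @param metrics metric columns to compare (default: all).
#' @param fraction top fraction per metric (default 0.10).
#' @return list with \code{deciles} (named list of animal-id vectors),
#'   \code{pairwise} (count matrix) and \code{all} (count in every decile).
#' @export
topDecileOverlap <- function(table, metrics = .metricCols(table),
                             fraction = 0.10) {
  absent <- setdiff(metrics, names(table))
  if (length(absent)) stop("metric(s) absent: ", paste(absent, collapse = ", "))
  deciles <- lapply(metrics, function(cl) {
    v <- table[[cl]]
    ok <- which(!is.na(v))
    if (length(ok) < 10L)
      stop("metric '", cl, "' has fewer than 10 non-missing values")
    k <- ceiling(fraction * length(ok))
    top <- ok[order(-v[ok], ok)][seq_len(k)]
    table$animal[top]
  })
  names(deciles) <- metrics
  pw <- outer(seq_along(metrics), seq_along(metrics),
              Vectorize(function(i, j)
                length(intersect(deciles[[i]], deciles[[j]]))))
  dimnames(pw) <- list(metrics, metrics)
  list(deciles = deciles, pairwise = pw,
       all = length(Reduce(intersect, deciles)))
}

#' Per-year means of every metric
#'
#' @param table an [inbreedingTable()] with a \code{birth_year} column.
#' @return long-format data.frame (\code{metric}, \code{year}, \code{n},
#'   \code{mean}); rows with unknown year are excluded.
#' @export
trendByYear <- function(table) {
  stopifnot("birth_year" %in% names(table))
  cols <- .metricCols(table)
  out <- list()
  for (cl in cols) {
    ok <- !is.na(table[[cl]]) & !is.na(table$birth_year)
    if (!any(ok)) next
    agg <- aggregate(list(mean = table[[cl]][ok]),
                     by = list(year = table$birth_year[ok]), FUN = mean)
    nn <- aggregate(list(n = table[[cl]][ok]),
                    by = list(year = table$birth_year[ok]), FUN = length)
    agg <- merge(agg, nn, by = "year")
    out[[cl]] <- data.frame(metric = cl, year = agg$year, n = agg$n,
                            mean = agg$mean, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$metric, res$year), ]
}
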