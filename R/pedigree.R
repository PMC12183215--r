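## Pedigree construction, pedigree-based inbreeding and relationship matrices.

#' Build a Pedigree from identifier vectors
#'
#' Animals referenced only as parents are appended as founders.  Records are
#' topologically sorted (Kahn's algorithm, ties broken by input order) so
#' that parents always precede offspring; a cycle is a hard error naming the
#' animals involved.
#'
#' @param animal,sire,dam character vectors of equal length; unknown parents
#'   are \code{NA}, the empty string, or the value of \code{missing}.
#' @param birthYear optional integer vector of birth years (\code{NA} unknown).
#' @param missing sentinel string treated as an unknown parent (default "0").
#' @return a \linkS4class{Pedigree}.
#' @examples
#' ped <- Pedigree(c("C"), sire = "A", dam = "B")
#' nAnimals(ped)  # 3: A and B added as founders
#' @export
Pedigree <- function(animal, sire, dam, birthYear = NULL, missing = "0") {
  animal <- as.character(animal)
  clean <- function(p) {
    p <- as.character(p)
    p[p %in% c(missing, "", "NA") | is.na(p)] <- NA_character_
    p
  }
  sire <- clean(sire); dam <- clean(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (is.null(birthYear)) birthYear <- rep(NA_integer_, length(animal))
  birthYear <- as.integer(birthYear)

  ## parents never listed as animals become founders, in order of appearance
  extra <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    birthYear <- c(birthYear, rep(NA_integer_, length(extra)))
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- unname(idx[sire]); di <- unname(idx[dam])
  if (any(!is.na(si) & si == idx) || any(!is.na(di) & di == idx))
    stop("animal recorded as its own parent: ",
         animal[which((!is.na(si) & si == idx) | (!is.na(di) & di == idx))[1]])

  ## Kahn topological sort, deterministic tie-break on input order
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)  # ascending = input order
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(order_out) < n) {
    cyc <- animal[setdiff(idx, order_out)]
    stop("pedigree cycle detected involving: ", paste(cyc, collapse = ", "))
  }
  pos <- integer(n); pos[order_out] <- seq_len(n)
  remap <- function(p) ifelse(is.na(p), NA_integer_, pos[p])
  newSire <- remap(si)[order_out]
  newDam  <- remap(di)[order_out]
  gen <- integer(n)
  for (i in seq_len(n)) {
    g <- c(if (!is.na(newSire[i])) gen[newSire[i]],
           if (!is.na(newDam[i]))  gen[newDam[i]])
    gen[i] <- if (length(g)) max(g) + 1L else 0L
  }
  new("Pedigree",
      ids        = animal[order_out],
      sire       = as.integer(newSire),
      dam        = as.integer(newDam),
      birthYear  = birthYear[order_out],
      founder    = is.na(newSire) & is.na(newDam),
      generation = gen)
}

#' Read a pedigree from delimited text
#'
#' Expects three or four columns: animal, sire, dam and (optionally) birth
#' year.  Column names and the unknown-parent sentinel are configurable; any
#' parent appearing only in the sire/dam columns is added as a founder.
#'
#' @param path path to a delimited text file with a header line.
#' @param columns named character vector mapping the roles \code{animal},
#'   \code{sire}, \code{dam} and (optionally) \code{year} to column names in
#'   the file.
#' @param sep field delimiter, passed to [data.table::fread()] ("auto" by
#'   default).
#' @param missing unknown-parent sentinel (default "0").
#' @return a \linkS4class{Pedigree}; the counts printed by [show()] include
#'   founders, distinct sires/dams, and the maximum generation depth.
#' @export
parsePedigree <- function(path,
                          columns = c(animal = "animal", sire = "sire",
                                      dam = "dam", year = "birth_year"),
                          sep = "auto", missing = "0") {
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          na.strings = c("NA", ""))
  for (role in c("animal", "sire", "dam")) {
    if (!columns[[role]] %in% names(dt))
      stop(sprintf("column '%s' (role %s) not found in %s",
                   columns[[role]], role, path))
  }
  yr <- NULL
  if ("year" %in% names(columns) && columns[["year"]] %in% names(dt))
    yr <- suppressWarnings(as.integer(dt[[columns[["year"]]]]))
  Pedigree(dt[[columns[["animal"]]]], dt[[columns[["sire"]]]],
           dt[[columns[["dam"]]]], birthYear = yr, missing = missing)
}

## Mendelian-sampling variance term d_i used both by the Meuwissen-Luo
## recursion and by Henderson's A-inverse rules; unknown parents contribute
## as unrelated non-inbred founders.
.mendelianD <- function(ped, f) {
  s <- ped@sire; d <- ped@dam
  fs <- ifelse(is.na(s), 0, f[s])
  fd <- ifelse(is.na(d), 0, f[d])
  0.5 - 0.25 * (fs + fd) + 0.25 * (is.na(s) + is.na(d))
}

#' Pedigree inbreeding coefficients
#'
#' Computes F for every animal with the Meuwissen-Luo recursion, which
#' reconstructs, one animal at a time, the row of the Cholesky factor of the
#' additive relationship matrix A and returns the diagonal A_ii - 1.
#' Founders, and animals with an unknown parent, get F = 0 (unknown parents
#' are treated as unrelated, non-inbred founders).
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return named numeric vector of inbreeding coefficients in [0, 1).
#' @examples
#' # offspring of a sire mated to his own daughter: F = 0.25
#' ped <- Pedigree(c("D", "X"), sire = c("S", "S"), dam = c("G", "D"))
#' computeFPed(ped)[["X"]]
#' @export
computeFPed <- function(ped) {
  s <- ped@sire; d <- ped@dam
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  setNames(.fped_ml(s, d), ped@ids)
}

## indices of the ancestor closure of `idx` (sorted ascending)
.ancestorClosure <- function(ped, idx) {
  inset <- logical(nAnimals(ped))
  inset[idx] <- TRUE
  for (i in rev(seq_len(nAnimals(ped)))) {
    if (inset[i]) {
      if (!is.na(ped@sire[i])) inset[ped@sire[i]] <- TRUE
      if (!is.na(ped@dam[i]))  inset[ped@dam[i]]  <- TRUE
    }
  }
  which(inset)
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' Builds A over the full ancestor closure of \code{subset} with the tabular
#' recurrence a_ij = 0.5 (a_j,sire(i) + a_j,dam(i)) and
#' A_ii = 1 + 0.5 a_sire(i),dam(i), then extracts the requested block.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param subset animal ids to retain (default: all animals).
#' @return dense symmetric matrix with animal ids as dimnames; the diagonal
#'   equals 1 + F.
#' @export
buildAMatrix <- function(ped, subset = pedIds(ped)) {
  pos <- match(subset, ped@ids)
  if (anyNA(pos))
    stop("animal(s) not in pedigree: ",
         paste(subset[is.na(pos)], collapse = ", "))
  keep <- .ancestorClosure(ped, pos)
  m <- length(keep)
  loc <- integer(nAnimals(ped)); loc[keep] <- seq_len(m)
  A <- matrix(0, m, m)
  for (ii in seq_len(m)) {
    i <- keep[ii]
    si <- ped@sire[i]; di <- ped@dam[i]
    sl <- if (is.na(si)) 0L else loc[si]
    dl <- if (is.na(di)) 0L else loc[di]
    if (ii > 1L) {
      jj <- seq_len(ii - 1L)
      aj <- 0.5 * ((if (sl) A[jj, sl] else 0) + (if (dl) A[jj, dl] else 0))
      A[jj, ii] <- aj
      A[ii, jj] <- aj
    }
    A[ii, ii] <- 1 + 0.5 * (if (sl && dl) A[sl, dl] else 0)
  }
  dimnames(A) <- list(ped@ids[keep], ped@ids[keep])
  A[subset, subset, drop = FALSE]
}

#' Inverse of the relationship matrix by Henderson's rules
#'
#' Builds A^-1 directly as a sparse matrix, accounting for inbreeding: each
#' animal contributes 1/d_i on the pattern \{animal, sire, dam\} where d_i is
#' the Mendelian-sampling variance computed from parental F.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param f optional precomputed [computeFPed()] output.
#' @return sparse symmetric \code{\link[Matrix]{Matrix}} with animal dimnames.
#' @export
aInverse <- function(ped, f = computeFPed(ped)) {
  n <- nAnimals(ped)
  d <- .mendelianD(ped, f)
  alpha <- 1 / d
  s <- ped@sire; dm <- ped@dam
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  idx <- seq_len(n)
  push(idx, idx, alpha)
  hasS <- !is.na(s); hasD <- !is.na(dm)
  push(idx[hasS], s[hasS], -0.5 * alpha[hasS])
  push(s[hasS], idx[hasS], -0.5 * alpha[hasS])
  push(idx[hasD], dm[hasD], -0.5 * alpha[hasD])
  push(dm[hasD], idx[hasD], -0.5 * alpha[hasD])
  push(s[hasS], s[hasS], 0.25 * alpha[hasS])
  push(dm[hasD], dm[hasD], 0.25 * alpha[hasD])
  both <- hasS & hasD
  push(s[both], dm[both], 0.25 * alpha[both])
  push(dm[both], s[both], 0.25 * alpha[both])
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), dimnames = list(ped@ids, ped@ids))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Mean inbreeding by birth year
#'
#' @param coeffs named per-animal values (names = animal ids) or an unnamed
#'   vector aligned with \code{pedIds(ped)}.
#' @param ped a \linkS4class{Pedigree} supplying birth years.
#' @return data.frame with one row per year (\code{year}, \code{n},
#'   \code{mean}); animals with an unknown birth year are excluded and their
#'   count reported in the \code{"excluded"} attribute.
#' @export
summarizeFByYear <- function(coeffs, ped) {
  if (is.null(names(coeffs))) {
    stopifnot(length(coeffs) == nAnimals(ped))
    names(coeffs) <- pedIds(ped)
  }
  yr <- birthYears(ped)[names(coeffs)]
  keep <- !is.na(yr)
  out <- if (any(keep)) {
    agg <- aggregate(list(mean = unname(coeffs[keep])),
                     by = list(year = unname(yr[keep])), FUN = mean)
    cnt <- as.data.frame(table(year = unname(yr[keep])), stringsAsFactors = FALSE)
    agg$n <- cnt$Freq[match(agg$year, as.integer(cnt$year))]
    agg[order(agg$year), c("year", "n", "mean")]
  } else {
    data.frame(year = integer(0), n = integer(0), mean = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(!keep)
  out
}
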