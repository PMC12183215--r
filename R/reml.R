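## Average-information REML on sparse mixed-model equations.
##
## Model: y = X b + sum_i Z_i u_i + e,  u_i ~ N(0, K_i s2_i),  e ~ N(0, I s2_e).
## The coefficient matrix is kept in variance-ratio form,
##   C(lambda) = W'W + blockdiag(0, Kinv_i * lambda_i),  lambda_i = s2_e/s2_i,
## factorised once symbolically and updated numerically each iteration.
## Trace terms tr(Kinv_i C^{ii}) come from a Takahashi selected inverse of the
## Cholesky factor (exact entries of C^{-1} on the factor's pattern, which
## contains every structural nonzero of Kinv_i and the full diagonal).

#' Fit variance components by AI-REML
#'
#' Average-information restricted maximum likelihood for a Gaussian mixed
#' model with independent random terms (each with a known covariance
#' structure K, e.g. the pedigree relationship matrix or the identity) and an
#' iid residual.  The first \code{emIterations} rounds use EM updates for
#' stability, after which Newton steps with the average-information matrix
#' are taken (falling back to EM whenever a step would leave the parameter
#' space).  Components shrinking below \code{boundary} times the phenotypic
#' variance are pinned there and flagged.
#'
#' @param y numeric response vector.
#' @param X dense fixed-effects design matrix (full column rank).
#' @param random list of random terms, each
#'   \code{list(Z = <sparse n x q incidence>, Kinv = <sparse q x q inverse
#'   structure>, name = <label>)}; may be empty, in which case the model
#'   reduces to ordinary least squares.
#' @param start optional numeric vector of starting values (one per random
#'   term plus the residual); default splits \code{var(y)} equally.
#' @param tol convergence tolerance on the maximum relative parameter change.
#' @param maxit maximum number of iterations.
#' @param emIterations number of initial EM iterations.
#' @param boundary lower bound for a variance component, as a fraction of
#'   \code{var(y)}.
#' @return list with \code{varcomp} (named, residual last), \code{beta},
#'   \code{seBeta} (per fixed effect), \code{converged}, \code{iterations},
#'   \code{boundaryFlags}, and \code{trace} (per-iteration parameter values).
#' @export
aiReml <- function(y, X, random = list(), start = NULL, tol = 1e-8,
                   maxit = 200L, emIterations = 3L, boundary = 1e-8) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < p)
    stop("fixed-effects design is rank deficient; resolve aliasing in buildDesign()")
  k <- length(random)
  termNames <- vapply(seq_len(k), function(i)
    random[[i]]$name %||% paste0("u", i), character(1))
  vcNames <- c(paste0("sigma2_", termNames), "sigma2_e")

  if (k == 0L) {
    fit <- stats::lm.fit(X, y)
    s2e <- sum(fit$residuals^2) / (n - p)
    XtXinv <- chol2inv(chol(crossprod(X)))
    return(list(varcomp = setNames(s2e, "sigma2_e"),
                beta = setNames(fit$coefficients, colnames(X)),
                seBeta = setNames(sqrt(diag(XtXinv) * s2e), colnames(X)),
                converged = TRUE, iterations = 0L,
                boundaryFlags = setNames(logical(0), character(0)),
                trace = NULL))
  }

  q <- vapply(random, function(r) ncol(r$Z), numeric(1))
  offs <- c(0, cumsum(q))[seq_len(k)]   # offsets inside the random block
  mU <- sum(q)
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  Z <- do.call(cbind, lapply(random, `[[`, "Z"))
  XtX <- as.matrix(Matrix::crossprod(Xs))
  ZtX <- Matrix::crossprod(Z, Xs)       # mU x p
  ZtZ <- Matrix::forceSymmetric(Matrix::crossprod(Z))
  Xty <- as.numeric(Matrix::crossprod(Xs, y))
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  yty <- sum(y * y)

  ## per-term Kinv embedded into the random block, plus trace bookkeeping
  Dmat <- vector("list", k)
  kinfo <- vector("list", k)
  for (i in seq_len(k)) {
    Ki <- as(as(Matrix::forceSymmetric(random[[i]]$Kinv), "generalMatrix"),
             "CsparseMatrix")
    tr <- Matrix::summary(Ki)           # i, j, x triplets
    keep <- tr$i >= tr$j                # lower triangle incl. diagonal
    kinfo[[i]] <- list(r = tr$i[keep] + offs[i], c = tr$j[keep] + offs[i],
                       x = tr$x[keep],
                       w = ifelse(tr$i[keep] == tr$j[keep], 1, 2),
                       Kinv = Matrix::forceSymmetric(random[[i]]$Kinv))
    Dmat[[i]] <- Matrix::sparseMatrix(i = tr$i[keep] + offs[i],
                                      j = tr$j[keep] + offs[i],
                                      x = tr$x[keep], dims = c(mU, mU),
                                      symmetric = TRUE)
  }

  vy <- stats::var(y)
  theta <- if (is.null(start)) rep(vy / (k + 1), k + 1) else as.numeric(start)
  if (length(theta) != k + 1L || any(theta <= 0))
    stop("start must give a positive value per random term plus the residual")
  floorVal <- boundary * vy
  pinned <- rep(FALSE, k + 1L)

  buildCuu <- function(theta) {
    lam <- theta[k + 1L] / theta[seq_len(k)]
    C <- ZtZ
    for (i in seq_len(k)) C <- C + lam[i] * Dmat[[i]]
    Matrix::forceSymmetric(C)
  }
  Ch <- Matrix::Cholesky(buildCuu(theta), LDL = FALSE, perm = TRUE,
                         super = FALSE)
  perm <- Ch@perm + 1L                  # Cuu[perm, perm] = L L'
  invperm <- order(perm)
  for (i in seq_len(k)) {
    pr <- invperm[kinfo[[i]]$r]; pc <- invperm[kinfo[[i]]$c]
    swap <- pr < pc
    kinfo[[i]]$pr <- as.integer(ifelse(swap, pc, pr))
    kinfo[[i]]$pc <- as.integer(ifelse(swap, pr, pc))
  }

  ## solve the full MME through the Schur complement on the fixed block:
  ## S = X'X - X'Z Cuu^{-1} Z'X;  b = S^{-1}(X'y - Y' Z'y);  u = Cuu^{-1}(Z'y - Z'X b)
  trace <- matrix(NA_real_, 0, k + 1L, dimnames = list(NULL, vcNames))
  converged <- FALSE
  iter <- 0L
  seFixed <- rep(NA_real_, p)
  bhat <- rep(NA_real_, p)

  repeat {
    iter <- iter + 1L
    Ch <- update(Ch, buildCuu(theta), mult = 0)
    Y <- as.matrix(Matrix::solve(Ch, as.matrix(ZtX), system = "A"))
    Smat <- XtX - as.matrix(Matrix::crossprod(ZtX, Y))
    Schol <- chol((Smat + t(Smat)) / 2)
    Sinv <- chol2inv(Schol)
    bhat <- as.numeric(Sinv %*% (Xty - crossprod(Y, Zty)))
    uhat <- as.numeric(Matrix::solve(Ch, Zty - as.numeric(ZtX %*% bhat),
                                     system = "A"))
    s2e <- theta[k + 1L]
    lam <- s2e / theta[seq_len(k)]
    ehat <- y - as.numeric(Xs %*% bhat) - as.numeric(Z %*% uhat)
    seFixed <- sqrt(pmax(diag(Sinv), 0) * s2e)

    ## traces tr(Kinv_i C^{uu}): Takahashi selected inverse of Cuu plus the
    ## Woodbury rank-p correction C^{uu} = Cuu^{-1} + Y S^{-1} Y'
    L <- Matrix::expand(Ch)$L
    Sx <- .takahashi_inverse(L@p, L@i, L@x, mU)
    Tvec <- numeric(k); uKu <- numeric(k)
    for (i in seq_len(k)) {
      ki <- kinfo[[i]]
      svals <- .sparse_lookup(L@p, L@i, Sx, ki$pr, ki$pc)
      KY <- as.matrix(ki$Kinv %*% Y[(offs[i] + 1L):(offs[i] + q[i]), ,
                                    drop = FALSE])
      corr <- sum(Sinv * crossprod(Y[(offs[i] + 1L):(offs[i] + q[i]), ,
                                     drop = FALSE], KY))
      Tvec[i] <- sum(ki$w * ki$x * svals) + corr
      ui <- uhat[(offs[i] + 1L):(offs[i] + q[i])]
      uKu[i] <- as.numeric(ui %*% (ki$Kinv %*% ui))
    }

    ## updates
    emTheta <- c((uKu + s2e * Tvec) / q,
                 (yty - sum(bhat * Xty) - sum(uhat * Zty)) / (n - p))
    useEM <- iter <= emIterations
    if (!useEM) {
      score <- c(-0.5 * (q / theta[seq_len(k)] -
                           (s2e * Tvec + uKu) / theta[seq_len(k)]^2),
                 -0.5 * ((n - p - sum(q) + sum(lam * Tvec)) / s2e -
                           sum(ehat^2) / s2e^2))
      Fmat <- matrix(0, n, k + 1L)
      for (i in seq_len(k)) {
        ui <- uhat[(offs[i] + 1L):(offs[i] + q[i])]
        Fmat[, i] <- as.numeric(random[[i]]$Z %*% ui) / theta[i]
      }
      Fmat[, k + 1L] <- ehat / s2e
      ## P f = (f - X b_f - Z u_f)/s2e with (b_f, u_f) solving the MME at f
      rx <- crossprod(X, Fmat)
      ru <- as.matrix(Matrix::crossprod(Z, Fmat))
      bF <- Sinv %*% (rx - crossprod(Y, ru))
      uF <- as.matrix(Matrix::solve(Ch, ru - as.matrix(ZtX %*% bF),
                                    system = "A"))
      PF <- (Fmat - X %*% bF - as.matrix(Z %*% uF)) / s2e
      AI <- 0.5 * crossprod(Fmat, PF)
      AI <- (AI + t(AI)) / 2
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      newTheta <- NULL
      if (!is.null(step)) {
        fac <- 1
        for (h in 1:5) {
          cand <- theta + fac * step
          if (all(cand > 0)) { newTheta <- cand; break }
          fac <- fac / 2
        }
        if (is.null(newTheta)) {
          ## a component is heading for the boundary: pin it there and keep
          ## the Newton update for the rest
          cand <- theta + step
          cand[cand <= floorVal] <- floorVal
          newTheta <- cand
        }
      }
      if (is.null(newTheta)) newTheta <- emTheta
    } else {
      newTheta <- emTheta
    }
    low <- newTheta < floorVal
    newTheta[low] <- floorVal
    pinned <- pinned | low

    rel <- max(abs(newTheta - theta) / pmax(abs(theta), floorVal))
    trace <- rbind(trace, setNames(newTheta, vcNames))
    theta <- newTheta
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  if (!converged) {
    cond <- simpleError("AI-REML did not converge; see 'trace' attribute")
    attr(cond, "trace") <- trace
    stop(cond)
  }
  if (any(pinned))
    warning("variance component(s) pinned at the boundary: ",
            paste(vcNames[pinned], collapse = ", "))

  list(varcomp = setNames(theta, vcNames),
       beta = setNames(bhat, colnames(X)),
       seBeta = setNames(seFixed, colnames(X)),
       converged = converged, iterations = iter,
       boundaryFlags = setNames(pinned, vcNames),
       trace = as.data.frame(trace))
}
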