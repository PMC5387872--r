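#' Bregmanian bi-stochastication of a similarity matrix
#'
#' Projects a symmetric nonnegative affinity matrix A onto the set of
#' symmetric doubly stochastic matrices under the squared Frobenius
#' divergence: the nearest W with `W >= 0`, `W 1 = 1`, `W = t(W)`. Double
#' stochasticity caps the spectral radius at 1, the condition under which the
#' label propagation iteration converges for any mu in (0, 1).
#'
#' The projection is computed by Dykstra alternating projections between the
#' affine set \{row sums = 1, column sums = 1\} (closed-form orthogonal
#' projection) and the nonnegative orthant (elementwise clipping, with the
#' Dykstra correction term that makes the alternation converge to the true
#' joint projection rather than merely a feasible point). Symmetry is
#' re-imposed after every sweep, which is exact up to floating point since
#' both projections preserve it.
#'
#' @param a a [DrugSimilarity-class] (or symmetric nonnegative matrix with
#'   drug-ID dimnames).
#' @param tol convergence tolerance on the worst row/column-sum deviation
#'   (default 1e-8).
#' @param maxIter maximum number of projection sweeps (default 10000).
#' @return a [StochasticSimilarity-class].
#' @examples
#' a <- matrix(c(1, .4, .4, 1), 2, dimnames = list(c("D1","D2"), c("D1","D2")))
#' bbsNormalize(DrugSimilarity(a))
#' @export
bbsNormalize <- function(a, tol = 1e-8, maxIter = 10000) {
  if (is(a, "DrugSimilarity")) a <- a@values
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-12)))
    stop("bbsNormalize: input must be symmetric")
  if (any(a < 0)) stop("bbsNormalize: input must be nonnegative")
  zr <- which(rowSums(a) == 0)
  if (length(zr) > 0)
    stop("bbsNormalize: drug '", rownames(a)[zr[1]],
         "' has zero similarity to every drug (all-zero row)")
  n <- nrow(a)
  if (n == 1) {
    return(StochasticSimilarity(matrix(1, 1, 1, dimnames = dimnames(a))))
  }
  projAffine <- function(x) {
    r <- rowSums(x); cs <- colSums(x); s <- sum(x)
    x + (1 / n + s / n^2) - outer(r, rep(1, n)) / n - outer(rep(1, n), cs) / n
  }
  x <- a
  p <- matrix(0, n, n)   # Dykstra increment for the orthant projection
  converged <- FALSE
  res <- Inf
  for (it in seq_len(maxIter)) {
    y <- projAffine(x)
    y <- (y + t(y)) / 2
    z <- y + p
    x <- pmax(z, 0)
    p <- z - x
    res <- max(abs(rowSums(x) - 1), abs(colSums(x) - 1))
    if (res < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("bbsNormalize: no convergence in %d iterations (residual %.3g > tol %.3g)",
                 maxIter, res, tol))
  x <- (x + t(x)) / 2
  dimnames(x) <- dimnames(a)
  StochasticSimilarity(x)
}

#' Verify double stochasticity
#'
#' @param w square matrix (or a matrix-backed container).
#' @param tol tolerance on row/column sums and symmetry (default 1e-8).
#' @return list with `ok` (logical) and the worst deviations:
#'   `maxRowDev`, `maxColDev`, `maxAsym`, `minEntry`.
#' @export
checkBistochastic <- function(w, tol = 1e-8) {
  if (!is.matrix(w)) w <- simValues(w)
  if (nrow(w) != ncol(w)) stop("checkBistochastic: matrix must be square")
  rep <- list(maxRowDev = max(abs(rowSums(w) - 1)),
              maxColDev = max(abs(colSums(w) - 1)),
              maxAsym = max(abs(w - t(w))),
              minEntry = min(w))
  rep$ok <- rep$maxRowDev <= tol && rep$maxColDev <= tol &&
    rep$maxAsym <= tol && rep$minEntry >= -tol
  rep
}
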