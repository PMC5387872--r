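#' Label propagation over a single similarity network
#'
#' Spreads known interaction labels Y over a symmetric doubly stochastic
#' drug network W. At each sweep every drug absorbs a fraction mu of its
#' neighbours' current scores and retains a fraction (1 - mu) of its initial
#' labels:
#'
#'   F <- mu * W %*% F + (1 - mu) * Y,  starting from F = Y.
#'
#' Because the spectral radius of W is at most 1 and 0 < mu < 1, the
#' iteration contracts to the unique fixed point
#' `F = (1 - mu) * solve(I - mu * W) %*% Y`, which
#' [propagateClosedForm()] computes directly by a linear solve. All n
#' per-drug prediction tasks are handled at once through the matrix
#' right-hand side.
#'
#' @param w a [StochasticSimilarity-class].
#' @param y an [InteractionMatrix-class] on the same drugs.
#' @param mu influence parameter, strictly in (0, 1): the weight of network
#'   smoothness relative to fidelity to the known labels.
#' @param tol convergence tolerance on the max-abs elementwise change
#'   (default 1e-9).
#' @param maxIter iteration cap (default 10000).
#' @return a [PredictionMatrix-class] of interaction scores.
#' @export
propagateIterative <- function(w, y, mu, tol = 1e-9, maxIter = 10000) {
  .checkPropagateArgs(w, y, mu)
  wm <- w@values; ym <- y@values
  f <- ym
  for (it in seq_len(maxIter)) {
    fNew <- mu * (wm %*% f) + (1 - mu) * ym
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) {
      dimnames(f) <- dimnames(ym)
      return(PredictionMatrix(f))
    }
  }
  stop(sprintf("propagateIterative: no convergence in %d iterations (last change %.3g > tol %.3g)",
               maxIter, delta, tol))
}

#' @rdname propagateIterative
#' @export
propagateClosedForm <- function(w, y, mu) {
  .checkPropagateArgs(w, y, mu)
  wm <- w@values; ym <- y@values
  n <- nrow(wm)
  f <- tryCatch((1 - mu) * solve(diag(n) - mu * wm, ym),
                error = function(e)
                  stop("propagateClosedForm: singular system (is W a valid ",
                       "doubly stochastic matrix?): ", conditionMessage(e)))
  dimnames(f) <- dimnames(ym)
  PredictionMatrix(f)
}

#' Label propagation objective
#'
#' The propagation fixed point minimizes
#' `J(F) = mu * tr(t(F) (I - W) F) + (1 - mu) * ||F - Y||_F^2`:
#' a smoothness term penalizing predictions that vary across strong network
#' edges, plus a fitting term anchoring predictions to the known labels.
#'
#' @param f a [PredictionMatrix-class] (or matrix) to evaluate.
#' @inheritParams propagateIterative
#' @return the scalar objective value (nonnegative for doubly stochastic W).
#' @export
lpObjective <- function(w, y, f, mu) {
  wm <- if (is.matrix(w)) w else w@values
  ym <- if (is.matrix(y)) y else y@values
  fm <- if (is.matrix(f)) f else f@values
  stopifnot(all(dim(wm) == dim(fm)), all(dim(ym) == dim(fm)))
  mu * .smoothnessCost(fm, wm) + (1 - mu) * sum((fm - ym)^2)
}

.checkPropagateArgs <- function(w, y, mu) {
  stopifnot(is(w, "StochasticSimilarity"), is(y, "InteractionMatrix"))
  .assertSameDrugs(w, y)
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 0 || mu >= 1)
    stop("mu must lie strictly in (0, 1)")
  invisible(TRUE)
}
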