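#' Convex combination of doubly stochastic similarity networks
#'
#' Returns `sum_k alpha_k W_k`. A convex combination of symmetric doubly
#' stochastic matrices is itself symmetric doubly stochastic, so the result
#' is again a valid propagation operator.
#'
#' @param ws list of [StochasticSimilarity-class] objects on the same drugs.
#' @param weights a [SourceWeights-class] (or bare simplex vector) of
#'   length `length(ws)`.
#' @return a [StochasticSimilarity-class].
#' @export
combineSimilarities <- function(ws, weights) {
  alpha <- if (is(weights, "SourceWeights")) weights@alpha else weights
  stopifnot(length(ws) == length(alpha))
  for (k in seq_along(ws)[-1]) .assertSameDrugs(ws[[1]], ws[[k]])
  m <- Reduce(`+`, Map(function(w, a) a * w@values, ws, alpha))
  m <- (m + t(m)) / 2
  dimnames(m) <- dimnames(ws[[1]]@values)
  StochasticSimilarity(m)
}

#' Per-source smoothness costs
#'
#' For each source k computes `c_k = tr(t(F) (I - W_k) F)`, the smoothness
#' cost of the current predictions on network k, without ever forming
#' `I - W_k`. These costs drive the source-weight update: cheaper (smoother)
#' sources earn larger weights.
#'
#' @param f a [PredictionMatrix-class] (or matrix).
#' @param ws list of [StochasticSimilarity-class] objects.
#' @return named numeric vector of costs, one per source.
#' @export
sourceCosts <- function(f, ws) {
  fm <- if (is.matrix(f)) f else f@values
  out <- vapply(ws, function(w) .smoothnessCost(fm, w@values), numeric(1))
  if (is.null(names(out)))
    names(out) <- paste0("source", seq_along(out))
  out
}

#' Euclidean projection onto the probability simplex
#'
#' Solves `argmin_a ||a - v||_2^2` subject to `a >= 0, sum(a) = 1` by the
#' standard sort-and-threshold algorithm: the solution is
#' `pmax(v + theta, 0)` for the unique shift theta making the positive part
#' sum to one.
#'
#' @param v numeric vector with finite entries.
#' @return nonnegative vector of the same length summing to 1.
#' @examples
#' projectSimplex(c(0.6, 0.2))  # c(0.7, 0.3)
#' @export
projectSimplex <- function(v) {
  if (length(v) < 1 || any(!is.finite(v)))
    stop("projectSimplex: input must be a non-empty finite vector")
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u + (1 - css) / j > 0])
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Exact source-weight update
#'
#' With predictions fixed, the weight sub-problem
#' `min_a mu * sum(a * costs) + delta * sum(a^2)` over the simplex is, up to
#' a constant, the Euclidean projection of `-(mu / (2 * delta)) * costs`
#' onto the simplex; this computes that exact minimizer.
#'
#' @param costs named numeric vector from [sourceCosts()].
#' @param mu influence parameter in (0, 1).
#' @param delta regularization parameter, strictly positive; large delta
#'   pulls the weights toward uniform, small delta lets the cheapest source
#'   take all the weight.
#' @return a [SourceWeights-class].
#' @export
updateAlpha <- function(costs, mu, delta) {
  if (delta <= 0) stop("delta must be strictly positive")
  a <- projectSimplex(-(mu / (2 * delta)) * costs)
  names(a) <- if (is.null(names(costs)))
    paste0("source", seq_along(costs)) else names(costs)
  SourceWeights(a)
}

#' Integrated label propagation over multiple similarity networks (LP-AllSim)
#'
#' Jointly learns interaction predictions F and simplex-constrained source
#' weights alpha over K drug similarity networks by minimizing
#'
#'   J(F, alpha) = mu * sum_k alpha_k * tr(t(F) (I - W_k) F)
#'                 + (1 - mu) * ||F - Y||_F^2 + delta * ||alpha||_2^2
#'
#' via block coordinate descent. Starting from uniform alpha, each outer
#' iteration (i) solves the single-network propagation with
#' `W = sum_k alpha_k W_k` in closed form, then (ii) updates alpha by the
#' exact simplex-projected minimizer [updateAlpha()]. Both block steps are
#' global minimizers of their sub-problems, so the objective trace is
#' non-increasing; an increase beyond 1e-9 aborts with an error since it can
#' only indicate an implementation fault.
#'
#' @param ws named list of [StochasticSimilarity-class] networks sharing one
#'   drug universe.
#' @param y an [InteractionMatrix-class] of known interactions.
#' @param mu influence parameter in (0, 1).
#' @param delta weight-regularization parameter (> 0, default 1).
#' @param bcdTol stop when the relative objective decrease falls below this
#'   (default 1e-7).
#' @param bcdMaxIter outer-iteration cap (default 200).
#' @return an [AllSimFit-class] with the converged predictions, the learned
#'   weights and the per-iteration objective values.
#' @export
fitAllSim <- function(ws, y, mu, delta = 1, bcdTol = 1e-7, bcdMaxIter = 200) {
  stopifnot(length(ws) >= 1, is(y, "InteractionMatrix"))
  if (delta <= 0) stop("delta must be strictly positive")
  if (is.null(names(ws)) || any(names(ws) == ""))
    names(ws) <- paste0("source", seq_along(ws))
  for (w in ws) .assertSameDrugs(w, y)
  k <- length(ws)
  alpha <- SourceWeights(structure(rep(1 / k, k), names = names(ws)))
  trace <- numeric(0)
  prev <- Inf
  f <- NULL
  for (it in seq_len(bcdMaxIter)) {
    wBar <- combineSimilarities(ws, alpha)
    f <- propagateClosedForm(wBar, y, mu)
    costs <- sourceCosts(f, ws)
    alpha <- updateAlpha(costs, mu, delta)
    obj <- allSimObjective(ws, y, f, alpha, mu, delta)
    if (obj > prev + 1e-9)
      stop(sprintf("fitAllSim: objective increased (%.12g -> %.12g); this indicates an implementation fault",
                   prev, obj))
    trace <- c(trace, obj)
    if (is.finite(prev) && (prev - obj) < bcdTol * max(1, abs(prev))) break
    prev <- obj
  }
  new("AllSimFit", scores = f, weights = alpha, objective = trace,
      mu = mu, delta = delta)
}

#' @rdname fitAllSim
#' @param f a [PredictionMatrix-class] (or matrix) at which to evaluate.
#' @param weights a [SourceWeights-class] (or simplex vector).
#' @return `allSimObjective`: the scalar composite objective.
#' @export
allSimObjective <- function(ws, y, f, weights, mu, delta) {
  alpha <- if (is(weights, "SourceWeights")) weights@alpha else weights
  ym <- if (is.matrix(y)) y else y@values
  fm <- if (is.matrix(f)) f else f@values
  costs <- sourceCosts(fm, ws)
  mu * sum(alpha * costs) + (1 - mu) * sum((fm - ym)^2) +
    delta * sum(alpha^2)
}

#' Integrated predictions for drugs with unequal source coverage
#'
#' When some drugs lack some information sources, predictions are computed
#' per source-availability stratum: for every distinct set of sources shared
#' by at least one drug pair, [fitAllSim()] is run on the sub-universe of
#' drugs covered by all sources in that set (with known interactions
#' restricted to it), and each pair takes its score from the largest source
#' set covering both of its drugs. No zero-imputation of missing profiles is
#' performed.
#'
#' @param sims named list of [DrugSimilarity-class] matrices, one per
#'   source, each covering only the drugs that source knows.
#' @param universe a [DrugUniverse-class] from [alignUniverse()].
#' @param y an [InteractionMatrix-class] over the full universe.
#' @inheritParams fitAllSim
#' @return a [PredictionMatrix-class] over the full universe; a pair whose
#'   drugs share no source scores 0 (no evidence either way).
#' @export
predictStratified <- function(sims, universe, y, mu, delta = 1, ...) {
  stopifnot(is(universe, "DrugUniverse"))
  av <- universe@availability
  stopifnot(identical(colnames(av), names(sims)))
  ids <- universe@drugIds
  .assertSameDrugs(universe, y)
  n <- length(ids)
  scores <- matrix(0, n, n, dimnames = list(ids, ids))
  # distinct source sets realized by at least one drug
  keys <- apply(av, 1, function(r) paste(colnames(av)[r], collapse = "|"))
  pairKey <- function(i, j) {
    common <- colnames(av)[av[i, ] & av[j, ]]
    paste(common, collapse = "|")
  }
  # enumerate the common source set of every pair, group pairs by it
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  pk <- vapply(seq_len(nrow(idx)),
               function(r) pairKey(idx[r, 1], idx[r, 2]), character(1))
  for (key in setdiff(unique(pk), "")) {
    srcs <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- ids[rowSums(av[, srcs, drop = FALSE]) == length(srcs)]
    ws <- lapply(sims[srcs], function(s) {
      m <- s@values[sub, sub, drop = FALSE]
      bbsNormalize(DrugSimilarity(m))
    })
    ySub <- InteractionMatrix(y@values[sub, sub, drop = FALSE])
    fit <- fitAllSim(ws, ySub, mu = mu, delta = delta, ...)
    fm <- fit@scores@values
    sel <- idx[pk == key, , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      i <- ids[sel[r, 1]]; j <- ids[sel[r, 2]]
      scores[i, j] <- fm[i, j]
      scores[j, i] <- fm[j, i]
    }
  }
  PredictionMatrix(scores)
}
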