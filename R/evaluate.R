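#' Drug-level hold-out split
#'
#' Samples `round(fraction * n)` drugs (banker's rounding, floored at 1)
#' uniformly without replacement as the test set. Holding out drugs, rather
#' than individual interactions, mimics prediction for a new drug with no
#' known interaction record. The split is deterministic given the seed and
#' leaves the caller's RNG state untouched.
#'
#' @param ids character vector of drug IDs (n >= 3).
#' @param fraction test fraction, strictly in (0, 1).
#' @param seed integer seed.
#' @return a [HoldoutSplit-class].
#' @export
holdoutSplit <- function(ids, fraction, seed) {
  n <- length(ids)
  if (n < 3) stop("holdoutSplit needs at least 3 drugs")
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly in (0, 1)")
  nTest <- max(1L, as.integer(round(fraction * n)))
  if (nTest >= n)
    stop("fraction ", fraction, " leaves no training drugs (n = ", n, ")")
  test <- withSeed(seed, sample(ids, nTest))
  new("HoldoutSplit", trainDrugs = sort(setdiff(ids, test)),
      testDrugs = sort(test), seed = as.integer(seed))
}

#' Remove all interactions of held-out drugs from the label matrix
#'
#' Every row and column belonging to a test drug is zeroed, so no test
#' interaction can influence model fitting; training entries are untouched.
#'
#' @param y an [InteractionMatrix-class].
#' @param split a [HoldoutSplit-class] whose drugs all occur in `y`.
#' @return the masked [InteractionMatrix-class].
#' @export
maskLabels <- function(y, split) {
  stopifnot(is(y, "InteractionMatrix"), is(split, "HoldoutSplit"))
  ids <- drugIds(y)
  bad <- setdiff(c(split@trainDrugs, split@testDrugs), ids)
  if (length(bad) > 0)
    stop("split mentions drugs absent from the interaction matrix: ", bad[1])
  m <- y@values
  m[split@testDrugs, ] <- 0
  m[, split@testDrugs] <- 0
  suppressWarnings(InteractionMatrix(m))
}

#' Enumerate scored test pairs
#'
#' Collects every unordered drug pair with at least one held-out drug (or,
#' with `pairs = "test-train"`, exactly one), labelled by the full
#' interaction matrix and scored by the symmetrized prediction
#' `(scores[i, j] + scores[j, i]) / 2`.
#'
#' @param split a [HoldoutSplit-class].
#' @param y the full (unmasked) [InteractionMatrix-class].
#' @param scores a [PredictionMatrix-class].
#' @param pairs `"test-any"` (default) to include test-test pairs, or
#'   `"test-train"` to score only pairs of one test and one train drug.
#' @return data.frame with columns `drug1`, `drug2`, `score`, `label`.
#' @export
testPairs <- function(split, y, scores, pairs = c("test-any", "test-train")) {
  pairs <- match.arg(pairs)
  .assertSameDrugs(y, scores)
  ids <- drugIds(y)
  isTest <- ids %in% split@testDrugs
  ym <- y@values
  sm <- (scores@values + t(scores@values)) / 2
  ut <- which(upper.tri(ym), arr.ind = TRUE)
  keep <- if (pairs == "test-any")
    isTest[ut[, 1]] | isTest[ut[, 2]]
  else
    xor(isTest[ut[, 1]], isTest[ut[, 2]])
  ut <- ut[keep, , drop = FALSE]
  data.frame(drug1 = ids[ut[, 1]], drug2 = ids[ut[, 2]],
             score = sm[ut], label = ym[ut],
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' outscores a random negative, with ties counted 1/2.
#'
#' @param score numeric prediction scores.
#' @param label binary labels (1 = known interaction).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  .checkLabeledScores(score, label, needNeg = TRUE)
  pos <- label == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: thresholds sweep the distinct scores from
#' high to low and each recall increment is weighted by the precision at
#' that threshold (no linear interpolation between PR points).
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(score, label) {
  .checkLabeledScores(score, label, needNeg = FALSE)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; l <- label[o]
  # cut at the last index of each distinct score (ties enter together)
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(l)[last]
  np <- last                        # predicted positives at each threshold
  prec <- tp / np
  rec <- tp / sum(label)
  sum(diff(c(0, rec)) * prec)
}

.checkLabeledScores <- function(score, label, needNeg) {
  stopifnot(length(score) == length(label), all(label %in% c(0, 1)))
  if (sum(label == 1) == 0)
    stop("no positive pairs in the evaluation set")
  if (needNeg && sum(label == 0) == 0)
    stop("no negative pairs in the evaluation set")
  invisible(TRUE)
}

#' F1-optimal decision cutoff
#'
#' Scans candidate thresholds (the minimum score plus the midpoints between
#' adjacent distinct scores; predictions at or above the threshold are
#' called interactions) and returns the one maximizing
#' `F1 = 2 * precision * recall / (precision + recall)`. Ties break toward
#' the higher threshold, i.e. the smaller predicted-positive set.
#'
#' @inheritParams auroc
#' @return the selected threshold (numeric scalar).
#' @export
selectCutoffF1 <- function(score, label) {
  .checkLabeledScores(score, label, needNeg = TRUE)
  u <- sort(unique(score))
  cand <- c(u[1], if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)
  f1 <- vapply(cand, function(t) {
    pred <- score >= t
    tp <- sum(pred & label == 1)
    if (tp == 0) return(0)
    p <- tp / sum(pred)
    r <- tp / sum(label == 1)
    2 * p * r / (p + r)
  }, numeric(1))
  best <- max(f1)
  max(cand[f1 >= best - 1e-12])
}

#' Tune the influence parameter by inner drug-level cross-validation
#'
#' Splits the training drugs into folds, masks each fold in turn, fits the
#' requested method at every candidate mu and keeps the mu with the best
#' mean AUROC over folds. Only training information is used, matching a
#' protocol in which test labels are never seen during tuning.
#'
#' @param fitFun function(yTrain, mu) returning a [PredictionMatrix-class].
#' @param y training-masked [InteractionMatrix-class].
#' @param trainDrugs drugs available for tuning.
#' @param muGrid candidate values in (0, 1).
#' @param folds number of inner folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return the selected mu.
#' @export
tuneMu <- function(fitFun, y, trainDrugs, muGrid, folds = 5, seed = 1) {
  foldId <- withSeed(seed,
                     sample(rep_len(seq_len(folds), length(trainDrugs))))
  perf <- vapply(muGrid, function(mu) {
    aucs <- c()
    for (fd in seq_len(folds)) {
      held <- trainDrugs[foldId == fd]
      if (length(held) == 0) next
      inner <- new("HoldoutSplit",
                   trainDrugs = sort(setdiff(trainDrugs, held)),
                   testDrugs = sort(held), seed = as.integer(seed))
      yInner <- maskLabels(y, inner)
      sc <- fitFun(yInner, mu)
      tp <- testPairs(inner, y, sc)
      tp <- tp[tp$drug1 %in% trainDrugs & tp$drug2 %in% trainDrugs, ]
      if (length(unique(tp$label)) < 2) next
      aucs <- c(aucs, auroc(tp$score, tp$label))
    }
    if (length(aucs) == 0) NA_real_ else mean(aucs)
  }, numeric(1))
  if (all(is.na(perf))) return(muGrid[ceiling(length(muGrid) / 2)])
  muGrid[which.max(perf)]
}

#' Repeated drug-level hold-out evaluation
#'
#' Runs the full protocol - split, mask, fit, score held-out pairs, compute
#' AUROC and AUPR - for `nRepeats` random drug divisions with seeds
#' `baseSeed, baseSeed + 1, ...`, and summarizes with means and sample
#' (n - 1 denominator) standard deviations. A repeat whose test pairs are
#' single-class is redrawn with the next unused seed (and noted in the
#' details attribute).
#'
#' @param data named list with elements `similarity` (a
#'   [DrugSimilarity-class] for `method = "nn"`), `w` (a
#'   [StochasticSimilarity-class] for `"lp"`) or `ws` (list of them, for
#'   `"allsim"`), and `y` (the full [InteractionMatrix-class]).
#' @param method `"nn"`, `"lp"` or `"allsim"`.
#' @param fraction held-out drug fraction in (0, 1).
#' @param nRepeats number of random divisions (>= 2).
#' @param baseSeed first seed of the repeat sequence.
#' @param mu influence parameter; ignored by `"nn"`. If `muGrid` is supplied
#'   (length > 1) mu is instead tuned per repeat by [tuneMu()] on the
#'   training drugs only.
#' @param delta LP-AllSim regularization parameter.
#' @param muGrid optional candidate grid for inner-CV tuning of mu.
#' @param innerFolds folds for [tuneMu()] (default 5).
#' @param pairs passed to [testPairs()].
#' @return one-row data.frame (method, fraction, nRepeats, aurocMean,
#'   aurocSd, auprMean, auprSd, baseSeed) with attribute `"details"`: a list
#'   of per-repeat seeds, AUROC/AUPR values, chosen mu, and (for
#'   `"allsim"`) the per-repeat alpha matrix.
#' @export
repeatedHoldout <- function(data, method = c("lp", "nn", "allsim"),
                            fraction, nRepeats, baseSeed,
                            mu = 0.5, delta = 1, muGrid = NULL,
                            innerFolds = 5, pairs = "test-any") {
  method <- match.arg(method)
  if (nRepeats < 2) stop("nRepeats must be at least 2")
  y <- data$y
  ids <- drugIds(y)
  fitOnce <- switch(method,
    nn = function(yTr, mu) nnScores(data$similarity, yTr),
    lp = function(yTr, mu) propagateClosedForm(data$w, yTr, mu),
    allsim = function(yTr, mu)
      fitAllSim(data$ws, yTr, mu = mu, delta = delta))
  aurocs <- auprs <- mus <- seeds <- numeric(0)
  alphas <- NULL
  redrawn <- 0
  seed <- baseSeed
  while (length(aurocs) < nRepeats) {
    split <- holdoutSplit(ids, fraction, seed)
    yTrain <- maskLabels(y, split)
    muUse <- mu
    if (!is.null(muGrid) && length(muGrid) > 1 && method != "nn")
      muUse <- tuneMu(function(yI, m) fitOnce(yI, m), yTrain,
                      split@trainDrugs, muGrid, folds = innerFolds,
                      seed = seed)
    fit <- fitOnce(yTrain, muUse)
    sc <- if (is(fit, "AllSimFit")) fit@scores else fit
    tp <- testPairs(split, y, sc, pairs = pairs)
    if (length(unique(tp$label)) < 2) {
      redrawn <- redrawn + 1
      seed <- seed + 1
      if (redrawn > 5 * nRepeats)
        stop("too many single-class repeats; check the interaction density")
      next
    }
    aurocs <- c(aurocs, auroc(tp$score, tp$label))
    auprs <- c(auprs, aupr(tp$score, tp$label))
    mus <- c(mus, muUse)
    seeds <- c(seeds, seed)
    if (is(fit, "AllSimFit"))
      alphas <- rbind(alphas, fit@weights@alpha)
    seed <- seed + 1
  }
  out <- data.frame(method = method, fraction = fraction,
                    nRepeats = nRepeats,
                    aurocMean = mean(aurocs), aurocSd = stats::sd(aurocs),
                    auprMean = mean(auprs), auprSd = stats::sd(auprs),
                    baseSeed = baseSeed, stringsAsFactors = FALSE)
  attr(out, "details") <- list(seeds = seeds, auroc = aurocs, aupr = auprs,
                               mu = mus, alpha = alphas, redrawn = redrawn)
  out
}
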