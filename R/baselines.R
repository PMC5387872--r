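#' Nearest-neighbour interaction scoring
#'
#' The one-hop similarity baseline: a candidate drug i is scored against a
#' reference drug r by the similarity of i to the most similar training drug
#' known to interact with r,
#'
#'   score(i, r) = max over j != i with yTrain\[j, r\] = 1 of a\[i, j\],
#'
#' or 0 when r has no known interactors. Unlike label propagation, the score
#' never looks beyond immediate neighbours, so similarity transitivity is
#' ignored. Self-pairs score 0.
#'
#' @param a a [DrugSimilarity-class] (raw, unnormalized affinities).
#' @param yTrain an [InteractionMatrix-class] holding training labels only
#'   (rows/columns of held-out drugs zeroed).
#' @return a [PredictionMatrix-class].
#' @export
nnScores <- function(a, yTrain) {
  stopifnot(is(a, "DrugSimilarity"), is(yTrain, "InteractionMatrix"))
  .assertSameDrugs(a, yTrain)
  am <- a@values
  ym <- yTrain@values
  n <- nrow(am)
  a2 <- am
  diag(a2) <- -Inf          # j != i: a drug's own label cannot vouch for it
  s <- matrix(0, n, n, dimnames = dimnames(am))
  for (r in seq_len(n)) {
    cand <- which(ym[, r] == 1)
    if (length(cand) == 0) next
    mx <- apply(a2[, cand, drop = FALSE], 1, max)
    mx[!is.finite(mx)] <- 0
    s[, r] <- pmax(mx, 0)
  }
  diag(s) <- 0
  PredictionMatrix(s)
}
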