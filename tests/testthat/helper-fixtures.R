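# shared fixture builders; everything is generated in code under fixed seeds

drugNames <- function(n) sprintf("D%02d", seq_len(n))

# random symmetric nonnegative affinity with positive row sums
randomAffinity <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n, 0.05, 1), n)
    a <- (a + t(a)) / 2
    dimnames(a) <- list(drugNames(n), drugNames(n))
    a
  })
}

# random binary symmetric interaction matrix with zero diagonal
randomInteractions <- function(n, seed, p = 0.2) {
  withr::with_seed(seed, {
    y <- matrix(as.numeric(runif(n * n) < p), n)
    y[lower.tri(y, diag = TRUE)] <- 0
    y <- y + t(y)
    dimnames(y) <- list(drugNames(n), drugNames(n))
    suppressWarnings(InteractionMatrix(y))
  })
}

randomStochastic <- function(n, seed) {
  bbsNormalize(DrugSimilarity(randomAffinity(n, seed)))
}

# 2-drug fixed point of the worked propagation example
swapNetwork <- function() {
  w <- matrix(c(0, 1, 1, 0), 2,
              dimnames = list(c("D01", "D02"), c("D01", "D02")))
  StochasticSimilarity(w)
}

# independent QP oracle: projection onto the simplex via pracma::quadprog
simplexOracle <- function(v) {
  k <- length(v)
  res <- pracma::quadprog(diag(k), -v,
                          Aeq = matrix(1, 1, k), beq = 1,
                          lb = rep(0, k))
  res$xmin
}

# independent QP oracle: nearest symmetric doubly stochastic matrix
bistochasticOracle <- function(a) {
  n <- nrow(a)
  nv <- n * n
  aeq <- matrix(0, 2 * n, nv)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    aeq[i, (j - 1) * n + i] <- 1   # row sums
    aeq[n + j, (j - 1) * n + i] <- 1   # column sums
  }
  # the last column-sum constraint is implied by the others (rank 2n - 1);
  # keeping it makes the QP solver reject the system as inconsistent
  aeq <- aeq[-(2 * n), , drop = FALSE]
  res <- pracma::quadprog(diag(nv), -as.vector(a),
                          Aeq = aeq, beq = rep(1, 2 * n - 1), lb = rep(0, nv))
  matrix(res$xmin, n, dimnames = dimnames(a))
}

# brute-force rank statistics for metric oracles
bruteAuroc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

bruteAupr <- function(score, label) {
  # enumerate every distinct threshold from high to low (average precision)
  ths <- sort(unique(score), decreasing = TRUE)
  ap <- 0; prevRec <- 0
  for (t in ths) {
    pred <- score >= t
    tp <- sum(pred & label == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(label == 1)
    ap <- ap + (rec - prevRec) * prec
    prevRec <- rec
  }
  ap
}

# benchmark similarity pipeline used in the evaluation experiments:
# no self-loops, so source weighting compares genuine cross-drug structure
benchNetworks <- function(bench) {
  aInf <- similarityMatrix(bench$informative, diagonal = "zero")
  wsRaw <- c(list(informative = aInf),
             lapply(bench$noise,
                    function(p) similarityMatrix(p, diagonal = "zero")))
  list(raw = wsRaw, stochastic = lapply(wsRaw, bbsNormalize))
}
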