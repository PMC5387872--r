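test_that("holdoutSplit draws the right sizes deterministically", {
  ids <- drugNames(10)
  s <- holdoutSplit(ids, 0.5, seed = 3)
  expect_length(s@testDrugs, 5)
  expect_length(s@trainDrugs, 5)
  expect_length(intersect(s@trainDrugs, s@testDrugs), 0)
  expect_setequal(c(s@trainDrugs, s@testDrugs), ids)
  expect_identical(holdoutSplit(ids, 0.5, seed = 3)@testDrugs, s@testDrugs)
  expect_false(identical(holdoutSplit(ids, 0.5, seed = 4)@testDrugs,
                         s@testDrugs))
  # banker's rounding: round(1.5) == 2
  expect_length(holdoutSplit(ids, 0.15, seed = 1)@testDrugs, 2)
  expect_error(holdoutSplit(ids, 1.2, 1), "fraction")
  expect_error(holdoutSplit(drugNames(2), 0.5, 1), "at least 3")
  expect_error(holdoutSplit(drugNames(4), 0.95, 1), "no training drugs")
})

test_that("holdoutSplit leaves the caller's RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  holdoutSplit(drugNames(10), 0.5, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("maskLabels zeroes all pairs touching test drugs", {
  ids <- drugNames(4)
  y <- matrix(0, 4, 4, dimnames = list(ids, ids))
  y["D01", "D02"] <- y["D02", "D01"] <- 1
  y["D01", "D03"] <- y["D03", "D01"] <- 1
  y["D03", "D04"] <- y["D04", "D03"] <- 1
  Y <- InteractionMatrix(y)
  # masking D01 removes its 2 interactions and leaves exactly 1 positive pair
  sp <- new("HoldoutSplit", trainDrugs = c("D02", "D03", "D04"),
            testDrugs = "D01", seed = 1L)
  masked <- simValues(maskLabels(Y, sp))
  expect_equal(sum(masked) / 2, 1)
  expect_equal(masked["D03", "D04"], 1)
  expect_equal(sum(masked["D01", ]), 0)
  # masking everything yields the zero matrix
  spAll <- new("HoldoutSplit", trainDrugs = "X", testDrugs = ids, seed = 1L)
  expect_error(maskLabels(Y, spAll), "absent")
  spAll <- new("HoldoutSplit", trainDrugs = "D01", testDrugs = ids[-1],
               seed = 1L)
  expect_lte(sum(simValues(maskLabels(Y, spAll))), 0)
  # a test drug with no interactions changes nothing
  spNone <- new("HoldoutSplit", trainDrugs = ids[-4], testDrugs = "D04",
                seed = 1L)
  yNo <- y; yNo["D03", "D04"] <- yNo["D04", "D03"] <- 0
  expect_equal(simValues(maskLabels(InteractionMatrix(yNo), spNone)), yNo)
})

test_that("testPairs enumerates held-out pairs with symmetrized scores", {
  ids <- drugNames(4)
  y <- matrix(0, 4, 4, dimnames = list(ids, ids))
  y["D01", "D02"] <- y["D02", "D01"] <- 1
  Y <- InteractionMatrix(y)
  withr::with_seed(6, sc <- matrix(runif(16), 4, dimnames = list(ids, ids)))
  pred <- PredictionMatrix(sc)
  sp <- new("HoldoutSplit", trainDrugs = c("D02", "D03", "D04"),
            testDrugs = "D01", seed = 1L)
  tp <- testPairs(sp, Y, pred)
  expect_equal(nrow(tp), 3)   # one test drug among n=4: n-1 pairs
  expect_setequal(tp$drug2[tp$drug1 == "D01"], c("D02", "D03", "D04"))
  expect_equal(tp$score[tp$drug2 == "D02"],
               (sc["D01", "D02"] + sc["D02", "D01"]) / 2)
  expect_equal(tp$label[tp$drug2 == "D02"], 1)
  expect_equal(sum(tp$label), 1)
  # test-train mode drops test-test pairs
  sp2 <- new("HoldoutSplit", trainDrugs = c("D03", "D04"),
             testDrugs = c("D01", "D02"), seed = 1L)
  expect_equal(nrow(testPairs(sp2, Y, pred, pairs = "test-any")), 5)
  expect_equal(nrow(testPairs(sp2, Y, pred, pairs = "test-train")), 4)
})

test_that("auroc matches hand counts, tie conventions and oracles", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # 3 of 4 pos-neg pairs concordant
  expect_equal(auroc(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(c(1, 2), c(1, 1)), "negative")
  expect_error(auroc(c(1, 2), c(0, 0)), "positive")
  withr::with_seed(7, {
    for (i in 1:10) {
      m <- sample(10:50, 1)
      sc <- round(runif(m), 2)   # force ties
      lb <- rbinom(m, 1, 0.4)
      if (length(unique(lb)) < 2) next
      expect_equal(auroc(sc, lb), bruteAuroc(sc, lb), tolerance = 1e-12)
    }
  })
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    sc <- runif(60); lb <- rbinom(60, 1, 0.3)
  })
  expect_equal(auroc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("aupr matches the average-precision enumeration oracle", {
  expect_equal(aupr(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  # single positive ranked last among m: AP = 1/m
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 1 / 4)
  expect_error(aupr(c(1, 2), c(0, 0)), "positive")
  withr::with_seed(9, {
    for (i in 1:10) {
      m <- sample(10:50, 1)
      sc <- round(runif(m), 2)
      lb <- rbinom(m, 1, 0.3)
      if (sum(lb) == 0) next
      expect_equal(aupr(sc, lb), bruteAupr(sc, lb), tolerance = 1e-12)
    }
  })
})

test_that("selectCutoffF1 maximizes F1 with ties toward fewer positives", {
  # perfectly separated: the returned threshold achieves F1 = 1
  sc <- c(0.9, 0.8, 0.3, 0.2); lb <- c(1, 1, 0, 0)
  t1 <- selectCutoffF1(sc, lb)
  expect_gt(t1, 0.3); expect_lte(t1, 0.8)
  pred <- as.numeric(sc >= t1)
  expect_equal(pred, lb)
  # enumeration oracle on an imperfect ranking
  sc2 <- c(0.9, 0.8, 0.3, 0.2); lb2 <- c(1, 0, 1, 0)
  cands <- c(min(sc2), (sort(unique(sc2))[-1] +
                          sort(unique(sc2))[-4]) / 2)
  f1s <- sapply(cands, function(t) {
    tp <- sum(sc2 >= t & lb2 == 1)
    if (tp == 0) return(0)
    p <- tp / sum(sc2 >= t); r <- tp / sum(lb2)
    2 * p * r / (p + r)
  })
  got <- selectCutoffF1(sc2, lb2)
  expect_equal(max(f1s), {
    tp <- sum(sc2 >= got & lb2 == 1)
    p <- tp / sum(sc2 >= got); r <- tp / sum(lb2)
    2 * p * r / (p + r)
  })
  expect_equal(got, max(cands[f1s >= max(f1s) - 1e-12]))
  expect_error(selectCutoffF1(c(1, 2), c(1, 1)), "negative")
})

test_that("repeatedHoldout is reproducible and summarizes correctly", {
  bench <- generateBenchmark(synthConfig(nDrugs = 24,
                                         seed = 10))
  nets <- benchNetworks(bench)
  data <- list(y = bench$interactions, similarity = nets$raw$informative,
               w = nets$stochastic$informative, ws = nets$stochastic)
  r1 <- repeatedHoldout(data, "lp", fraction = 0.25, nRepeats = 3,
                        baseSeed = 50)
  r2 <- repeatedHoldout(data, "lp", fraction = 0.25, nRepeats = 3,
                        baseSeed = 50)
  expect_identical(r1, r2)
  expect_true(r1$aurocMean >= 0 && r1$aurocMean <= 1)
  expect_gte(r1$aurocSd, 0)
  d <- attr(r1, "details")
  expect_length(d$auroc, 3)
  expect_equal(stats::sd(d$auroc), r1$aurocSd)   # sample (n-1) convention
  expect_error(repeatedHoldout(data, "lp", 0.25, 1, 1), "at least 2")
  # allsim path records per-repeat weights
  r3 <- repeatedHoldout(data, "allsim", fraction = 0.25, nRepeats = 2,
                        baseSeed = 60)
  expect_equal(dim(attr(r3, "details")$alpha), c(2, 2))
})

test_that("mu tuning picks from the grid using training drugs only", {
  bench <- generateBenchmark(synthConfig(nDrugs = 24,
                                         seed = 11))
  nets <- benchNetworks(bench)
  y <- bench$interactions
  sp <- holdoutSplit(drugIds(y), 0.25, seed = 1)
  yTr <- maskLabels(y, sp)
  mu <- tuneMu(function(yI, m) propagateClosedForm(nets$stochastic$informative,
                                                   yI, m),
               yTr, sp@trainDrugs, muGrid = c(0.2, 0.5, 0.8), folds = 3,
               seed = 2)
  expect_true(mu %in% c(0.2, 0.5, 0.8))
})
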