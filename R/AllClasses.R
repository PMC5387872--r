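#' @import methods
NULL

.checkBinaryMatrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    return("values must be a numeric matrix")
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    return(sprintf("non-binary entry at row %d, column %d (value %g)",
                   bad[1, 1], bad[1, 2], m[bad[1, 1], bad[1, 2]]))
  NULL
}

#' DrugProfiles: binary drug-by-feature profile matrix
#'
#' Holds an n-drug by d-feature binary matrix, the raw representation of a
#' drug information source such as an 881-bit chemical substructure
#' fingerprint or a side-effect presence/absence profile. Row names are drug
#' identifiers, column names are feature identifiers; both must be unique.
#'
#' @slot profiles numeric matrix with entries in \{0, 1\}, dimnames set.
#' @seealso [loadProfiles()], [similarityMatrix()]
#' @export
setClass("DrugProfiles", representation(profiles = "matrix"))

setValidity("DrugProfiles", function(object) {
  m <- object@profiles
  msg <- .checkBinaryMatrix(m)
  if (!is.null(msg)) return(msg)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("profiles must have drug IDs as rownames and feature IDs as colnames")
  if (anyDuplicated(rownames(m)))
    return(sprintf("duplicate drug ID: %s",
                   rownames(m)[duplicated(rownames(m))][1]))
  if (anyDuplicated(colnames(m)))
    return(sprintf("duplicate feature ID: %s",
                   colnames(m)[duplicated(colnames(m))][1]))
  TRUE
})

#' @describeIn DrugProfiles-class constructor from a binary matrix with
#'   dimnames; rows and columns are reordered lexicographically so that all
#'   downstream matrices are reproducible regardless of input row order.
#' @param profiles binary matrix, drug IDs as rownames, feature IDs as colnames
#' @export
DrugProfiles <- function(profiles) {
  profiles <- profiles[order(rownames(profiles)),
                       order(colnames(profiles)), drop = FALSE]
  new("DrugProfiles", profiles = profiles)
}

#' DrugSimilarity: symmetric drug-drug affinity matrix
#'
#' An n-by-n symmetric matrix of pairwise drug similarities with entries in
#' \[0, 1\] (Tanimoto coefficients when built by [similarityMatrix()]).
#'
#' @slot values symmetric numeric matrix, drug IDs as dimnames.
#' @export
setClass("DrugSimilarity", representation(values = "matrix"))

setValidity("DrugSimilarity", function(object) {
  m <- object@values
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    return("values must be a square numeric matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("values must carry identical drug-ID rownames and colnames")
  if (anyDuplicated(rownames(m)))
    return("duplicate drug IDs")
  if (!identical(m, t(m)))
    return("similarity matrix must be exactly symmetric")
  if (any(!is.finite(m)) || any(m < -1e-12) || any(m > 1 + 1e-6))
    return("similarity entries must lie in [0, 1]")
  TRUE
})

#' @describeIn DrugSimilarity-class constructor from a symmetric matrix
#' @param values symmetric numeric matrix with drug-ID dimnames
#' @export
DrugSimilarity <- function(values) new("DrugSimilarity", values = values)

#' StochasticSimilarity: symmetric doubly stochastic propagation operator
#'
#' The normalized similarity matrix W produced by [bbsNormalize()]:
#' symmetric, nonnegative, with every row and column summing to 1. Double
#' stochasticity bounds the spectral radius by 1, which guarantees the label
#' propagation iteration converges for any influence parameter mu in (0, 1).
#'
#' @export
setClass("StochasticSimilarity", contains = "DrugSimilarity")

setValidity("StochasticSimilarity", function(object) {
  m <- object@values
  if (any(m < -1e-12)) return("entries must be nonnegative")
  if (max(abs(rowSums(m) - 1)) > 1e-6 || max(abs(colSums(m) - 1)) > 1e-6)
    return("row and column sums must equal 1")
  TRUE
})

#' @describeIn StochasticSimilarity-class constructor (validates sums)
#' @param values symmetric doubly stochastic matrix with drug-ID dimnames
#' @export
StochasticSimilarity <- function(values)
  new("StochasticSimilarity", values = values)

#' InteractionMatrix: known drug-drug interactions
#'
#' Binary symmetric n-by-n matrix Y with zero diagonal; entry (i, j) is 1
#' when drugs i and j are known to interact.
#'
#' @slot values binary symmetric matrix, zero diagonal, drug-ID dimnames.
#' @export
setClass("InteractionMatrix", representation(values = "matrix"))

setValidity("InteractionMatrix", function(object) {
  m <- object@values
  if (!is.matrix(m) || nrow(m) != ncol(m))
    return("values must be a square matrix")
  msg <- .checkBinaryMatrix(m)
  if (!is.null(msg)) return(msg)
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("values must carry identical drug-ID rownames and colnames")
  if (!identical(m, t(m))) return("interaction matrix must be symmetric")
  if (any(diag(m) != 0)) return("diagonal must be zero (no self-interaction)")
  TRUE
})

#' @describeIn InteractionMatrix-class constructor; warns (does not error)
#'   when the matrix carries no positive label at all, since propagation from
#'   an empty label set is uninformative.
#' @param values binary symmetric matrix with zero diagonal
#' @export
InteractionMatrix <- function(values) {
  obj <- new("InteractionMatrix", values = values)
  if (sum(values) == 0)
    warning("interaction matrix has no positive entries; propagation will be uninformative")
  obj
}

#' PredictionMatrix: propagated interaction scores
#'
#' Real-valued n-by-n matrix F of predicted interaction scores. With a
#' doubly stochastic W, binary Y and mu in (0, 1) every score lies in
#' \[0, 1\], but the class only requires finiteness.
#'
#' @slot values finite numeric matrix with drug-ID dimnames.
#' @export
setClass("PredictionMatrix", representation(values = "matrix"))

setValidity("PredictionMatrix", function(object) {
  m <- object@values
  if (!is.matrix(m) || nrow(m) != ncol(m))
    return("values must be a square matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("values must carry identical drug-ID rownames and colnames")
  if (any(!is.finite(m))) return("scores must be finite")
  TRUE
})

#' @describeIn PredictionMatrix-class constructor
#' @param values numeric matrix of scores with drug-ID dimnames
#' @export
PredictionMatrix <- function(values) new("PredictionMatrix", values = values)

#' SourceWeights: simplex-constrained information-source weights
#'
#' The weight vector alpha over K similarity sources learned by
#' [fitAllSim()]: nonnegative, summing to 1, named by source.
#'
#' @slot alpha named nonnegative numeric vector summing to 1.
#' @export
setClass("SourceWeights", representation(alpha = "numeric"))

setValidity("SourceWeights", function(object) {
  a <- object@alpha
  if (length(a) < 1 || is.null(names(a)) || anyDuplicated(names(a)))
    return("alpha must be a named vector with unique source names")
  if (any(a < -1e-10)) return("alpha components must be nonnegative")
  if (abs(sum(a) - 1) > 1e-8) return("alpha must sum to 1")
  TRUE
})

#' @describeIn SourceWeights-class constructor
#' @param alpha named nonnegative numeric vector summing to 1
#' @export
SourceWeights <- function(alpha) new("SourceWeights", alpha = alpha)

#' DrugUniverse: union of drugs across sources with availability masks
#'
#' Records which of K information sources covers each drug in the merged
#' (lexicographically ordered) drug universe; used to stratify integrated
#' predictions when some drugs lack some sources.
#'
#' @slot drugIds character vector of the merged drug universe.
#' @slot availability n-by-K logical matrix; `availability[i, k]` is TRUE
#'   when source k covers drug i.
#' @export
setClass("DrugUniverse",
         representation(drugIds = "character", availability = "matrix"))

setValidity("DrugUniverse", function(object) {
  av <- object@availability
  if (!is.logical(av) || nrow(av) != length(object@drugIds))
    return("availability must be a logical matrix with one row per drug")
  if (!identical(rownames(av), object@drugIds))
    return("availability rownames must match drugIds")
  if (any(rowSums(av) == 0))
    return(sprintf("drug %s is covered by no source",
                   object@drugIds[which(rowSums(av) == 0)[1]]))
  TRUE
})

#' HoldoutSplit: drug-level train/test partition
#'
#' @slot trainDrugs,testDrugs disjoint character vectors covering the universe.
#' @slot seed integer seed that produced the split.
#' @export
setClass("HoldoutSplit",
         representation(trainDrugs = "character", testDrugs = "character",
                        seed = "integer"))

setValidity("HoldoutSplit", function(object) {
  if (length(intersect(object@trainDrugs, object@testDrugs)) > 0)
    return("train and test drugs must be disjoint")
  if (length(object@testDrugs) < 1 || length(object@trainDrugs) < 1)
    return("both train and test sets must be non-empty")
  TRUE
})

#' AllSimFit: result of multi-source label propagation
#'
#' Bundles the converged prediction matrix, the learned source weights and
#' the block-coordinate-descent objective trace of [fitAllSim()].
#'
#' @slot scores [PredictionMatrix-class] of integrated scores.
#' @slot weights [SourceWeights-class] alpha over the sources.
#' @slot objective numeric vector, objective value after each outer iteration.
#' @slot mu,delta the influence and regularization parameters used.
#' @export
setClass("AllSimFit",
         representation(scores = "PredictionMatrix",
                        weights = "SourceWeights",
                        objective = "numeric",
                        mu = "numeric", delta = "numeric"))

## ---- generics & accessors ----

#' Drug identifiers of an object
#' @param x a ddiProp container object
#' @return character vector of drug IDs
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugProfiles", function(x) rownames(x@profiles))
#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugSimilarity", function(x) rownames(x@values))
#' @rdname drugIds
#' @export
setMethod("drugIds", "InteractionMatrix", function(x) rownames(x@values))
#' @rdname drugIds
#' @export
setMethod("drugIds", "PredictionMatrix", function(x) rownames(x@values))
#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugUniverse", function(x) x@drugIds)
#' @rdname drugIds
#' @export
setMethod("drugIds", "AllSimFit", function(x) drugIds(x@scores))

#' Extract the numeric matrix held by a container
#' @param x a matrix-backed ddiProp object
#' @return the underlying numeric matrix (a copy)
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))
#' @rdname simValues
#' @export
setMethod("simValues", "DrugSimilarity", function(x) x@values)
#' @rdname simValues
#' @export
setMethod("simValues", "InteractionMatrix", function(x) x@values)
#' @rdname simValues
#' @export
setMethod("simValues", "PredictionMatrix", function(x) x@values)
#' @rdname simValues
#' @export
setMethod("simValues", "DrugProfiles", function(x) x@profiles)

#' @describeIn AllSimFit-class integrated prediction matrix
#' @param x an `AllSimFit`
#' @export
fittedScores <- function(x) x@scores

#' @describeIn AllSimFit-class learned source weight vector (named numeric)
#' @export
sourceAlpha <- function(x) {
  if (is(x, "AllSimFit")) x@weights@alpha else x@alpha
}

#' @describeIn AllSimFit-class objective value after each BCD iteration
#' @export
objectiveTrace <- function(x) x@objective

#' @describeIn DrugUniverse-class logical availability mask (drugs x sources)
#' @param x a `DrugUniverse`
#' @export
availability <- function(x) x@availability

setMethod("show", "DrugProfiles", function(object) {
  cat(sprintf("DrugProfiles: %d drugs x %d binary features (density %.3f)\n",
              nrow(object@profiles), ncol(object@profiles),
              mean(object@profiles)))
})

setMethod("show", "DrugSimilarity", function(object) {
  cat(sprintf("%s: %d drugs, similarity range [%.3f, %.3f]\n",
              class(object), nrow(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "InteractionMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf("InteractionMatrix: %d drugs, %d interacting pairs (%.1f%% of pairs)\n",
              n, sum(object@values) / 2,
              100 * sum(object@values) / (n * (n - 1))))
})

setMethod("show", "PredictionMatrix", function(object) {
  cat(sprintf("PredictionMatrix: %d drugs, score range [%.4f, %.4f]\n",
              nrow(object@values), min(object@values), max(object@values)))
})

setMethod("show", "SourceWeights", function(object) {
  cat("SourceWeights (alpha):\n")
  print(round(object@alpha, 4))
})

setMethod("show", "AllSimFit", function(object) {
  cat(sprintf("AllSimFit: %d drugs, %d sources, mu = %.3g, delta = %.3g\n",
              nrow(object@scores@values), length(object@weights@alpha),
              object@mu, object@delta))
  cat(sprintf("  BCD iterations: %d, final objective: %.6g\n",
              length(object@objective),
              object@objective[length(object@objective)]))
  show(object@weights)
})

setMethod("show", "HoldoutSplit", function(object) {
  cat(sprintf("HoldoutSplit: %d train / %d test drugs (seed %d)\n",
              length(object@trainDrugs), length(object@testDrugs),
              object@seed))
})

setMethod("show", "DrugUniverse", function(object) {
  cat(sprintf("DrugUniverse: %d drugs across %d sources\n",
              length(object@drugIds), ncol(object@availability)))
})
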