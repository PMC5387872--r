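#' Load a binary drug profile matrix from TSV/CSV
#'
#' Reads a delimited file whose header row lists feature IDs, whose first
#' column holds drug IDs, and whose cells are 0/1 presence flags (e.g. a
#' substructure fingerprint or a side-effect profile). Rows and columns are
#' re-ordered lexicographically so downstream similarity matrices do not
#' depend on file row order.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a [DrugProfiles-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("drug\tf1\tf2\tf3", "D1\t1\t1\t0", "D2\t0\t1\t1"), tf)
#' loadProfiles(tf)
#' @export
loadProfiles <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("profile file not found: ", path)
  if (file.size(path) == 0) stop("profile file is empty: ", path)
  x <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "",
                         quote = "")
  if (nrow(x) == 0 || ncol(x) < 2)
    stop("profile file must have at least one drug row and one feature column: ",
         path)
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids))
    stop("duplicate drug ID in ", path, ": ", ids[duplicated(ids)][1])
  feats <- colnames(x)[-1]
  if (anyDuplicated(feats))
    stop("duplicate feature ID in ", path, ": ", feats[duplicated(feats)][1])
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric cell in ", path)
  bad <- which(!(vals == 0 | vals == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary cell in %s at drug '%s', feature '%s' (value %s)",
                 path, ids[bad[1, 1]], feats[bad[1, 2]],
                 format(vals[bad[1, 1], bad[1, 2]])))
  dimnames(vals) <- list(ids, feats)
  DrugProfiles(vals)
}

#' Tanimoto coefficient between two binary vectors
#'
#' TC(a, b) = |a intersect b| / |a union b|, the Jaccard index on the sets of
#' set bits. Two all-zero vectors score 0 (the 0/0 case is defined as zero so
#' that no NaN can enter an affinity matrix).
#'
#' @param a,b binary vectors of equal length.
#' @return a similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0), c(1, 0, 1))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("tanimoto: vectors differ in length (", length(a), " vs ",
         length(b), ")")
  if (any(!(a %in% c(0, 1))) || any(!(b %in% c(0, 1))))
    stop("tanimoto: vectors must be binary")
  un <- sum(a == 1 | b == 1)
  if (un == 0) return(0)
  sum(a == 1 & b == 1) / un
}

#' All-pairs Tanimoto similarity matrix
#'
#' Computes the n-by-n affinity matrix A whose (i, j) cell is the Tanimoto
#' coefficient between the profile rows of drugs i and j. Intersection and
#' union sizes are integer counts, so the result is exactly symmetric.
#'
#' @param p a [DrugProfiles-class] object with at least 2 drugs.
#' @param diagonal `"keep"` (default; self-similarity is 1 for any drug with
#'   at least one feature, 0 for an all-zero profile) or `"zero"` (diagonal
#'   forced to 0 before normalization).
#' @return a [DrugSimilarity-class] object.
#' @export
similarityMatrix <- function(p, diagonal = c("keep", "zero")) {
  diagonal <- match.arg(diagonal)
  stopifnot(is(p, "DrugProfiles"))
  m <- p@profiles
  if (nrow(m) < 2) stop("similarityMatrix needs at least 2 drugs")
  inter <- tcrossprod(m)                    # integer-valued intersections
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, "+") - inter    # |A| + |B| - |A^B|
  sim <- ifelse(un > 0, inter / un, 0)
  if (diagonal == "zero") diag(sim) <- 0
  dimnames(sim) <- list(rownames(m), rownames(m))
  DrugSimilarity(sim)
}

#' Merge drug universes across information sources
#'
#' Builds the union of drug IDs over a list of profile sources (in
#' lexicographic order) together with a per-source availability mask used to
#' stratify integrated predictions for drugs missing some sources.
#'
#' @param sources named list of [DrugProfiles-class] objects.
#' @return a [DrugUniverse-class] object.
#' @export
alignUniverse <- function(sources) {
  if (length(sources) < 1) stop("alignUniverse needs at least one source")
  if (is.null(names(sources)) || any(names(sources) == ""))
    names(sources) <- paste0("source", seq_along(sources))
  ids <- sort(unique(unlist(lapply(sources, drugIds))))
  if (length(ids) == 0) stop("empty drug universe: no source contains drugs")
  av <- vapply(sources, function(s) ids %in% drugIds(s),
               logical(length(ids)))
  av <- matrix(av, nrow = length(ids),
               dimnames = list(ids, names(sources)))
  new("DrugUniverse", drugIds = ids, availability = av)
}

## ---- TSV I/O for matrices and pair lists ----

#' Write / read a drug-drug matrix as TSV
#'
#' Matrices are written with drug IDs as both header and first column, values
#' at 10 significant digits (sufficient for 1e-9 round-trip comparisons).
#'
#' @param x a [DrugSimilarity-class], [InteractionMatrix-class],
#'   [PredictionMatrix-class], or plain matrix with drug-ID dimnames.
#' @param path output file.
#' @export
writeMatrixTSV <- function(x, path) {
  m <- if (is.matrix(x)) x else simValues(x)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = 10, format = "g")), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("drug", colnames(m)), collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @param class one of `"similarity"`, `"stochastic"`, `"interaction"`,
#'   `"prediction"`, `"matrix"`: the container to return.
#' @export
readMatrixTSV <- function(path, class = c("similarity", "stochastic",
                                          "interaction", "prediction",
                                          "matrix")) {
  class <- match.arg(class)
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  m <- (m + t(m)) / 2   # restore exact symmetry lost to text rounding
  switch(class,
         similarity = DrugSimilarity(m),
         stochastic = StochasticSimilarity(m),
         interaction = InteractionMatrix(m),
         prediction = PredictionMatrix(m),
         matrix = m)
}

#' Read / write drug-pair lists
#'
#' Pair lists are 2-column TSVs with header `drug1 drug2`, stored unordered
#' and de-duplicated with the lexicographically smaller ID first. Self-pairs
#' are rejected on read.
#'
#' @param path file path.
#' @return `readPairsTSV`: a data.frame with columns `drug1`, `drug2`.
#' @export
readPairsTSV <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  if (ncol(x) != 2) stop("pair list must have exactly 2 columns: ", path)
  if (any(x[[1]] == x[[2]]))
    stop("self-pair in ", path, ": ", x[[1]][x[[1]] == x[[2]]][1])
  canonicalPairs(data.frame(drug1 = x[[1]], drug2 = x[[2]],
                            stringsAsFactors = FALSE))
}

#' @rdname readPairsTSV
#' @param pairs data.frame with two character columns of drug IDs.
#' @export
writePairsTSV <- function(pairs, path) {
  pairs <- canonicalPairs(pairs)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("drug1", "drug2"))
  invisible(path)
}

#' @rdname readPairsTSV
#' @export
canonicalPairs <- function(pairs) {
  a <- pmin(pairs[[1]], pairs[[2]])
  b <- pmax(pairs[[1]], pairs[[2]])
  out <- unique(data.frame(drug1 = a, drug2 = b, stringsAsFactors = FALSE))
  out[order(out$drug1, out$drug2), , drop = FALSE]
}

#' Expand a pair list into a symmetric interaction matrix
#'
#' @param pairs data.frame of interacting drug-ID pairs.
#' @param ids drug universe (default: drugs occurring in `pairs`).
#' @return an [InteractionMatrix-class].
#' @export
interactionsFromPairs <- function(pairs, ids = NULL) {
  pairs <- canonicalPairs(pairs)
  if (is.null(ids)) ids <- sort(unique(c(pairs$drug1, pairs$drug2)))
  unknown <- setdiff(c(pairs$drug1, pairs$drug2), ids)
  if (length(unknown) > 0)
    stop("pair list mentions drugs outside the universe: ", unknown[1])
  y <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$drug1, ids); j <- match(pairs$drug2, ids)
  y[cbind(i, j)] <- 1
  y[cbind(j, i)] <- 1
  InteractionMatrix(y)
}
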