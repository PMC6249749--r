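# Sample-level host-label-shuffle null models and relative (z-score)
# indices. Randomized species matrices are obtained by permuting the host
# plant labels across samples within a forest (every sample keeps its OTU
# count vector) and re-aggregating, so per-sample read totals, per-OTU
# prevalence and the number of samples per plant are all conserved.

# Permute labels in a canonical (sorted-by-sample-id) order so that the
# result is invariant to the row order of the input table.
.shuffledLabels <- function(ids, labels, seed) {
  ord <- order(ids)
  shuffled <- withSeed(seed, sample(labels[ord]))
  out <- labels
  out[ord] <- shuffled
  out
}

#' Shuffle host plant labels across samples
#'
#' Returns a copy of the sample table whose plant labels are a uniformly
#' random permutation of the original labels; every sample's OTU counts are
#' untouched, so the label multiset, per-sample read totals and per-OTU
#' prevalence are all preserved. The permutation is drawn in a canonical
#' sample-id order, making the result independent of row order.
#'
#' @param x A [SampleTable].
#' @param seed Integer seed.
#' @return A [SampleTable] with permuted plant labels.
#' @export
shuffleHostLabels <- function(x, seed) {
  stopifnot(is(x, "SampleTable"))
  SampleTable(countMatrix(x),
              .shuffledLabels(sampleIds(x), plantLabels(x), seed),
              forestId(x))
}

.metricFun <- function(metric) {
  switch(metric,
         h2prime = .h2prime,
         wnodf = .wnodf,
         cscore = .cscore,
         stop("unknown metric: ", metric, call. = FALSE))
}

# Shared machinery for the observed statistic and the null ensemble:
# presence columns are restricted to the category's guild up front (column
# selection commutes with aggregation); the plant-side exclusion operates
# on the aggregated rows, whose label set is permutation-invariant.
.nullSetup <- function(x, otuAnnotations, plantAnnotations, category,
                       nullScope) {
  presence <- (countMatrix(x) > 0) * 1L
  labels <- plantLabels(x)
  ids <- sampleIds(x)
  if (category != "ALL") {
    keepCols <- .guildVector(colnames(presence), otuAnnotations) ==
      .guildFor(category)
    presence <- presence[, keepCols, drop = FALSE]
  }
  keptTypes <- .plantsKeptFor(category)
  if (nullScope == "within-category" && category %in% c("AM_EX", "ECM_EX")) {
    type <- .plantTypeVector(labels, plantAnnotations, warn = FALSE)
    keepSamples <- type %in% keptTypes
    presence <- presence[keepSamples, , drop = FALSE]
    labels <- labels[keepSamples]
    ids <- ids[keepSamples]
  }
  plantSet <- sort(unique(labels))
  rowKeep <- .plantTypeVector(plantSet, plantAnnotations, warn = FALSE) %in%
    keptTypes
  list(presence = presence, labels = labels, ids = ids,
       ord = order(ids), rowKeep = rowKeep)
}

.statFromLabels <- function(setup, labels, fun) {
  agg <- .aggregatePresence(setup$presence, labels)
  agg <- agg[setup$rowKeep, , drop = FALSE]
  agg <- agg[rowSums(agg) > 0, , drop = FALSE]
  agg <- agg[, colSums(agg) > 0, drop = FALSE]
  if (nrow(agg) < 2L || ncol(agg) < 2L) return(NULL)
  tryCatch(fun(agg), error = function(e) NULL)
}

#' Null distribution of a structural index under host-label shuffling
#'
#' For each of `nPerm` randomizations: shuffle the host plant labels,
#' convert the randomized sample-level matrix into a randomized
#' species-level matrix, apply the category's guild/plant selection rules,
#' and compute the index. Randomizations yielding degenerate matrices are
#' skipped and counted in `nFailed`, never imputed; the ensemble is
#' rejected when more than half fail. Each permutation draws its own child
#' seed from its index, so ensembles are reproducible, independent of
#' sample order, and identical whether permutations run serially or in
#' parallel (the first `k` values of an ensemble never depend on `nPerm`).
#'
#' @param x A preprocessed [SampleTable].
#' @param otuAnnotations,plantAnnotations Annotation data.frames (see
#'   [readAnnotations()]).
#' @param category One of `networkCategories()`.
#' @param metric `"h2prime"`, `"wnodf"` or `"cscore"`.
#' @param nPerm Number of randomizations. Conventional choices follow the
#'   cost of the index: 1000 for H2' and weighted NODF, 100 for the
#'   C-score.
#' @param seed Integer master seed.
#' @param nullScope `"full"` (default): labels are shuffled first and the
#'   category's plant-exclusion rules are applied to the randomized table;
#'   `"within-category"`: for `AM_EX`/`ECM_EX`, samples of excluded plants
#'   are removed before shuffling.
#' @return A [NullEnsemble].
#' @export
nullDistribution <- function(x, otuAnnotations, plantAnnotations,
                             category = "ALL",
                             metric = c("h2prime", "wnodf", "cscore"),
                             nPerm = if (metric == "cscore") 100 else 1000,
                             seed,
                             nullScope = c("full", "within-category")) {
  metric <- match.arg(metric)
  stopifnot(is(x, "SampleTable"), nPerm >= 1)
  nullScope <- match.arg(nullScope)
  category <- .matchArg(category, .CATEGORIES, "category")
  fun <- .metricFun(metric)
  setup <- .nullSetup(x, otuAnnotations, plantAnnotations, category, nullScope)
  nPerm <- as.integer(nPerm)
  values <- numeric(0)
  nFailed <- 0L
  for (i in seq_len(nPerm)) {
    shuffled <- withSeed(childSeed(seed, paste0("perm:", i)),
                         sample(setup$labels[setup$ord]))
    labels <- setup$labels
    labels[setup$ord] <- shuffled
    v <- .statFromLabels(setup, labels, fun)
    if (is.null(v)) nFailed <- nFailed + 1L else values <- c(values, v)
  }
  if (nFailed > nPerm / 2)
    stop(sprintf(
      "null ensemble rejected: %d of %d randomizations degenerate for %s/%s",
      nFailed, nPerm, category, metric), call. = FALSE)
  NullEnsemble(metricName = metric, values = values, nRequested = nPerm,
               nFailed = nFailed, seed = as.numeric(seed))
}

#' Standardize an observed index against its null ensemble
#'
#' The relative index value is
#' `z = (I_observed - mean(I_randomized)) / SD(I_randomized)`, with the
#' sample standard deviation (n - 1 denominator). Negative relative
#' nestedness is the "anti-nested" signature. A null ensemble with fewer
#' than two values or zero spread yields an error, never an infinite score.
#'
#' @param observed Observed index value.
#' @param ensemble A [NullEnsemble].
#' @return A [RelativeIndex].
#' @export
relativeIndex <- function(observed, ensemble) {
  stopifnot(is(ensemble, "NullEnsemble"), is.finite(observed))
  v <- ensembleValues(ensemble)
  if (length(v) < 2L)
    stop("relative index undefined: need at least 2 null values",
         call. = FALSE)
  s <- sd(v)
  if (s == 0)
    stop("relative index undefined: null distribution has zero spread",
         call. = FALSE)
  RelativeIndex(observed = observed, nullMean = mean(v), nullSd = s,
                z = (observed - mean(v)) / s)
}

#' Observed index and its relative (z-score) value in one call
#'
#' Computes the observed index of the category's species matrix and its
#' [nullDistribution()] under host-label shuffling, and standardizes the
#' former against the latter.
#'
#' @inheritParams nullDistribution
#' @return A [RelativeIndex].
#' @export
relativeNetworkIndex <- function(x, otuAnnotations, plantAnnotations,
                                 category = "ALL",
                                 metric = c("h2prime", "wnodf", "cscore"),
                                 nPerm = if (metric == "cscore") 100 else 1000,
                                 seed,
                                 nullScope = c("full", "within-category")) {
  metric <- match.arg(metric)
  nullScope <- match.arg(nullScope)
  category <- .matchArg(category, .CATEGORIES, "category")
  setup <- .nullSetup(x, otuAnnotations, plantAnnotations, category, nullScope)
  observed <- .statFromLabels(setup, setup$labels, .metricFun(metric))
  if (is.null(observed))
    stop("observed ", category, " matrix is degenerate; ", metric,
         " undefined", call. = FALSE)
  ens <- nullDistribution(x, otuAnnotations, plantAnnotations, category,
                          metric, nPerm, seed, nullScope)
  relativeIndex(observed, ens)
}
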