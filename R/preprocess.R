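# Sample-level quality pipeline: rare-entry filter -> rarefaction ->
# equal-depth subsampling of samples, in that order.

#' Preprocessing parameters
#'
#' @param entryFractionThreshold Cells representing less than this fraction
#'   of a sample's total reads are set to zero (strict inequality; default
#'   0.001, i.e. 0.1\%). Such rare entries typically derive from soil
#'   contamination or PCR/sequencing errors.
#' @param rarefactionDepth Common read depth each retained sample is rarefied
#'   to (default 1000); samples with fewer reads are dropped.
#' @param samplesPerForest Number of samples drawn without replacement per
#'   forest to equalize sampling effort (default 240).
#' @return A validated parameter list of class `preprocessParams`.
#' @export
preprocessParams <- function(entryFractionThreshold = 0.001,
                             rarefactionDepth = 1000,
                             samplesPerForest = 240) {
  stopifnot(
    entryFractionThreshold >= 0, entryFractionThreshold < 1,
    rarefactionDepth >= 1, samplesPerForest >= 1
  )
  structure(list(
    entryFractionThreshold = entryFractionThreshold,
    rarefactionDepth = as.integer(rarefactionDepth),
    samplesPerForest = as.integer(samplesPerForest)
  ), class = "preprocessParams")
}

#' Zero out rare cell entries of a sample table
#'
#' A cell is set to zero if and only if its reads represent less than
#' `threshold` of the sample's total read count, evaluated on the totals
#' before any filtering; cells exactly at the threshold are kept. Columns
#' that become all-zero are retained (they are only pruned when species
#' matrices are built), so sample-level label shuffling stays well defined.
#'
#' @param x A [SampleTable].
#' @param threshold Per-sample fraction below which a cell is zeroed.
#' @return A filtered [SampleTable].
#' @export
filterRareEntries <- function(x, threshold = 0.001) {
  stopifnot(is(x, "SampleTable"), threshold >= 0, threshold < 1)
  counts <- countMatrix(x)
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning("sample(s) with zero total reads left unchanged: ",
            paste(head(rownames(counts)[tot == 0], 5L), collapse = ", "),
            call. = FALSE)
  if (threshold > 0 && any(tot > 0)) {
    frac <- counts / ifelse(tot == 0, 1, tot)  # zero-total rows unchanged
    counts[frac < threshold] <- 0L
  }
  SampleTable(counts, plantLabels(x), forestId(x))
}

.rarefyRow <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(x)
  reads <- rep.int(seq_along(x), x)
  tabulate(sample(reads, depth), nbins = length(x))
}

#' Rarefy every sample to a common read depth
#'
#' Samples with fewer than `depth` reads are dropped (with an error if none
#' remain); each retained sample's reads are subsampled uniformly without
#' replacement (multivariate hypergeometric) to exactly `depth` reads.
#' Randomness is keyed per sample on `childSeed(seed, sample_id)`, so the
#' result is independent of row order and reproducible from `seed`.
#'
#' @param x A [SampleTable].
#' @param depth Target read depth.
#' @param seed Integer master seed.
#' @return A rarefied [SampleTable].
#' @export
rarefySamples <- function(x, depth = 1000, seed) {
  stopifnot(is(x, "SampleTable"), depth >= 1)
  counts <- countMatrix(x)
  tot <- rowSums(counts)
  keep <- tot >= depth
  if (!any(keep))
    stop("all samples have fewer than ", depth, " reads; empty table",
         call. = FALSE)
  counts <- counts[keep, , drop = FALSE]
  out <- counts
  for (i in seq_len(nrow(counts))) {
    out[i, ] <- withSeed(childSeed(seed, paste0("rarefy:", rownames(counts)[i])),
                         .rarefyRow(counts[i, ], depth))
  }
  SampleTable(out, plantLabels(x)[keep], forestId(x))
}

#' Draw an equal number of samples per forest
#'
#' Selects exactly `n` samples uniformly at random without replacement.
#' Each sample receives a pseudorandom priority keyed on
#' `childSeed(seed, sample_id)` and the `n` smallest priorities are kept
#' (bottom-k sampling), which makes the selected set independent of input
#' row order. Retained samples keep their original order.
#'
#' @param x A [SampleTable].
#' @param n Number of samples to retain.
#' @param seed Integer master seed.
#' @return A [SampleTable] with `n` samples.
#' @export
subsampleSamples <- function(x, n = 240, seed) {
  stopifnot(is(x, "SampleTable"), n >= 1)
  ids <- sampleIds(x)
  if (length(ids) < n)
    stop(sprintf("forest %s has only %d samples; %d requested",
                 forestId(x), length(ids), n), call. = FALSE)
  prio <- vapply(ids, function(id)
    withSeed(childSeed(seed, paste0("subsample:", id)), runif(1L)),
    numeric(1L))
  keep <- sort(order(prio, ids)[seq_len(n)])
  SampleTable(countMatrix(x)[keep, , drop = FALSE], plantLabels(x)[keep],
              forestId(x))
}

#' Run the full per-forest preprocessing pipeline
#'
#' Applies, in order: the rare-entry filter, rarefaction to a common depth,
#' and subsampling to `min(samplesPerForest, number of retained samples)`
#' samples. Applying the pipeline a second time with the same parameters and
#' seed leaves sample totals unchanged.
#'
#' @param x A [SampleTable].
#' @param params A [preprocessParams()] list.
#' @param seed Integer master seed.
#' @return A preprocessed [SampleTable].
#' @export
preprocessSampleTable <- function(x, params = preprocessParams(), seed) {
  stopifnot(inherits(params, "preprocessParams"))
  x <- filterRareEntries(x, params$entryFractionThreshold)
  x <- rarefySamples(x, params$rarefactionDepth, seed)
  n <- min(params$samplesPerForest, length(sampleIds(x)))
  subsampleSamples(x, n, seed)
}

#' Expected OTU accumulation curve
#'
#' For each number of samples k = 1..N, the expected number of fungal OTUs
#' observed in a uniformly drawn size-k subset of samples, computed
#' analytically (the sample-based rarefaction expectation of
#' `vegan::specaccum(method = "exact")`) rather than by random permutation,
#' so the curve is deterministic.
#'
#' @param x A [SampleTable].
#' @return A data.frame with columns `k` (samples) and `richness` (expected
#'   OTU count), non-decreasing in `k`.
#' @export
accumulationCurve <- function(x) {
  stopifnot(is(x, "SampleTable"))
  counts <- countMatrix(x)
  if (nrow(counts) < 1L) stop("empty sample table", call. = FALSE)
  if (nrow(counts) == 1L)
    return(data.frame(k = 1L, richness = sum(counts[1L, ] > 0)))
  sa <- vegan::specaccum(counts, method = "exact")
  data.frame(k = sa$sites, richness = as.numeric(sa$richness))
}
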