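# Structural indices of plant-by-fungus association matrices. Each index
# has a plain-matrix method (used by the null-model loop and by tests) and
# a SpeciesMatrix method.

.assertNonDegenerate <- function(a) {
  if (isDegenerate(a))
    stop("degenerate matrix: structural indices need at least 2 plants and ",
         "2 OTUs", call. = FALSE)
}

.connectance <- function(a) sum(a > 0) / length(a)

#' Connectance
#'
#' The proportion of non-zero entries in a plant-by-fungus community
#' matrix: realized links over all possible plant-OTU pairs.
#'
#' @param x A [SpeciesMatrix] or plants x OTUs matrix (non-degenerate).
#' @return A proportion in `[0, 1]`.
#' @export
setGeneric("connectance", function(x) standardGeneric("connectance"))

#' @rdname connectance
#' @export
setMethod("connectance", "matrix", function(x) {
  .assertNonDegenerate(x)
  .connectance(x)
})

#' @rdname connectance
#' @export
setMethod("connectance", "SpeciesMatrix", function(x)
  connectance(assocMatrix(x)))

# H2': two-dimensional Shannon entropy of the interaction proportions,
# rescaled between the minimum and maximum entropy achievable under the
# observed integer marginal totals. 0 = maximally generalized, 1 =
# maximally specialized.
.h2parts <- function(a) {
  m <- sum(a)
  if (m <= 0) stop("matrix total must be positive", call. = FALSE)
  h2raw <- log(m) - sum(a[a > 0] * log(a[a > 0])) / m
  ex <- h2_extremes_cpp(rowSums(a), colSums(a))
  list(h2_raw = h2raw, h2_min = ex[1L], h2_max = ex[2L])
}

.h2prime <- function(a) {
  p <- .h2parts(a)
  den <- p$h2_max - p$h2_min
  if (den < 1e-9)
    stop("H2' undefined: marginal totals admit a single interaction ",
         "distribution", call. = FALSE)
  min(max((p$h2_max - p$h2_raw) / den, 0), 1)
}

#' Network-level interaction specificity H2'
#'
#' With interaction proportions `p_ij = a_ij / m`, the two-dimensional
#' Shannon entropy is `H2 = -sum p_ij ln p_ij`. H2' rescales it between the
#' extremes achievable given the integer marginal totals:
#' `H2' = (H2max - H2) / (H2max - H2min)`, clipped to `[0, 1]`. `H2max` is
#' found by an even-distribution heuristic (largest-remainder rounding of
#' the marginal expectation followed by entropy-increasing 2x2 swaps) and
#' `H2min` by a greedy concentration heuristic; on small matrices both are
#' validated against exhaustive enumeration in the package tests. Entropies
#' are in natural log; H2' is scale-free so the base cancels.
#'
#' @param x A non-degenerate [SpeciesMatrix] or matrix with positive total.
#' @return A list with elements `h2prime` (the index) and `parts` (a list
#'   with `h2_raw`, `h2_min`, `h2_max`, all in nats).
#' @export
setGeneric("h2Prime", function(x) standardGeneric("h2Prime"))

#' @rdname h2Prime
#' @export
setMethod("h2Prime", "matrix", function(x) {
  .assertNonDegenerate(x)
  parts <- .h2parts(x)
  den <- parts$h2_max - parts$h2_min
  if (den < 1e-9)
    stop("H2' undefined: marginal totals admit a single interaction ",
         "distribution", call. = FALSE)
  list(h2prime = min(max((parts$h2_max - parts$h2_raw) / den, 0), 1),
       parts = parts)
})

#' @rdname h2Prime
#' @export
setMethod("h2Prime", "SpeciesMatrix", function(x) h2Prime(assocMatrix(x)))

.wnodf <- function(a) wnodf_cpp(a * 1.0)

#' Weighted NODF nestedness
#'
#' Nestedness of a weighted matrix on the 0-100 scale. For each unordered
#' pair of rows (and of columns), the member with the strictly larger
#' marginal total is the richer one and the pair scores 100 times the
#' fraction of the poorer member's nonzero cells whose values are smaller
#' than the richer member's corresponding values; pairs with tied totals
#' score 0. The index is the mean over all row pairs and column pairs.
#'
#' @param x A non-degenerate [SpeciesMatrix] or matrix.
#' @return A value in `[0, 100]`.
#' @export
setGeneric("weightedNODF", function(x) standardGeneric("weightedNODF"))

#' @rdname weightedNODF
#' @export
setMethod("weightedNODF", "matrix", function(x) {
  .assertNonDegenerate(x)
  .wnodf(x)
})

#' @rdname weightedNODF
#' @export
setMethod("weightedNODF", "SpeciesMatrix", function(x)
  weightedNODF(assocMatrix(x)))

.cscore <- function(a) {
  B <- (a > 0) * 1
  S <- crossprod(B)            # shared host plants per OTU pair
  r <- diag(S)                 # host range of each OTU
  R <- matrix(r, nrow(S), ncol(S))
  C <- (R - S) * (t(R) - S)    # checkerboard units per pair
  mean(C[upper.tri(C)])
}

#' Checkerboard C-score of the fungal community
#'
#' Host-range differentiation among fungal OTUs. The matrix is binarized;
#' for each unordered OTU pair (i, j) the number of checkerboard units is
#' `(r_i - S_ij)(r_j - S_ij)` where `r` is the number of host plants of an
#' OTU and `S_ij` the number of shared hosts. The C-score is the raw mean
#' over all OTU pairs (no per-pair normalization; only relative, z-scored
#' values are interpreted downstream, where the normalization cancels).
#' High scores indicate host differentiation, low scores host overlap.
#'
#' @param x A non-degenerate [SpeciesMatrix] or matrix with >= 2 OTUs.
#' @return A non-negative number; 0 iff all OTUs share identical host sets.
#' @export
setGeneric("cScore", function(x) standardGeneric("cScore"))

#' @rdname cScore
#' @export
setMethod("cScore", "matrix", function(x) {
  .assertNonDegenerate(x)
  .cscore(x)
})

#' @rdname cScore
#' @export
setMethod("cScore", "SpeciesMatrix", function(x) cScore(assocMatrix(x)))

#' Bundle the structural indices of a network
#'
#' Computes node counts, the fungus/plant ratio, connectance, H2',
#' weighted NODF and the checkerboard C-score for one species matrix. On a
#' degenerate matrix the counts (and connectance) are still reported while
#' the structural indices are returned as `NA` with the failure reasons in
#' attribute `"undefined"`; individual index errors never fail the bundle.
#'
#' @param x A [SpeciesMatrix].
#' @return A one-row data.frame with columns `forest_id`, `category`,
#'   `n_plants`, `n_otus`, `fungus_plant_ratio`, `connectance`, `h2prime`,
#'   `wnodf`, `cscore`.
#' @export
setGeneric("networkSummary", function(x) standardGeneric("networkSummary"))

#' @rdname networkSummary
#' @export
setMethod("networkSummary", "SpeciesMatrix", function(x) {
  a <- assocMatrix(x)
  out <- data.frame(
    forest_id = forestId(x),
    category = networkCategory(x),
    n_plants = nrow(a),
    n_otus = ncol(a),
    fungus_plant_ratio = ncol(a) / nrow(a),
    connectance = .connectance(a),
    h2prime = NA_real_, wnodf = NA_real_, cscore = NA_real_,
    stringsAsFactors = FALSE
  )
  reasons <- character(0)
  for (metric in c("h2prime", "wnodf", "cscore")) {
    v <- tryCatch(
      switch(metric,
             h2prime = h2Prime(a)$h2prime,
             wnodf = weightedNODF(a),
             cscore = cScore(a)),
      error = function(e) {
        reasons[[metric]] <<- conditionMessage(e)
        NA_real_
      })
    out[[metric]] <- v
  }
  if (length(reasons)) attr(out, "undefined") <- reasons
  out
})
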