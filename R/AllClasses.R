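#' SampleTable: per-forest sample-by-OTU read counts with host labels
#'
#' The unit of the sample-level analyses: an integer matrix of sequencing
#' read counts with one row per root sample and one column per fungal OTU,
#' together with the host plant species/taxon label of every sample and the
#' forest the samples came from. This is the object the host-label-shuffle
#' null model permutes.
#'
#' @slot forestId Single character forest identifier.
#' @slot counts Integer matrix, samples x OTUs; row names are sample ids,
#'   column names OTU ids, both unique.
#' @slot plantLabels Character vector of host plant labels, one per sample.
#'
#' @param counts Samples x OTUs matrix of non-negative integer read counts
#'   with unique row (sample id) and column (OTU id) names.
#' @param plantLabels Character vector of plant labels, one per row of
#'   `counts`.
#' @param forestId Single character forest identifier.
#' @return A validated `SampleTable` object.
#' @examples
#' m <- matrix(c(3L, 0L, 0L, 5L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' SampleTable(m, c("plantA", "plantB"), "F1")
#' @aliases SampleTable-class
#' @export SampleTable
#' @exportClass SampleTable
SampleTable <- setClass("SampleTable", slots = c(
  forestId = "character",
  counts = "matrix",
  plantLabels = "character"
))

setValidity("SampleTable", function(object) {
  if (length(object@forestId) != 1L || is.na(object@forestId) ||
      !nzchar(object@forestId))
    return("forestId must be a single non-empty string")
  msg <- .checkCountMatrix(object@counts)
  if (!is.null(msg)) return(msg)
  if (length(object@plantLabels) != nrow(object@counts))
    return("plantLabels must have one entry per sample")
  if (anyNA(object@plantLabels) || any(!nzchar(object@plantLabels)))
    return("plantLabels must be non-missing, non-empty strings")
  TRUE
})

#' @param counts,plantLabels,forestId See slot descriptions.
#' @noRd
setMethod("initialize", "SampleTable", function(.Object, counts, plantLabels,
                                                forestId, ...) {
  if (!missing(counts)) {
    msg <- .checkCountMatrix(counts)
    if (!is.null(msg)) stop(msg, call. = FALSE)
    storage.mode(counts) <- "integer"
    .Object@counts <- counts
  }
  if (!missing(plantLabels)) .Object@plantLabels <- as.character(plantLabels)
  if (!missing(forestId)) .Object@forestId <- as.character(forestId)
  validObject(.Object)
  .Object
})

#' SpeciesMatrix: plant-by-fungus association counts
#'
#' The unit the structural indices are computed on: an integer matrix whose
#' cell (i, j) counts the samples in which plant species/taxon i was
#' associated with fungal OTU j (presence of reads, not read counts). A
#' matrix carries the network category it represents (`ALL` or one of the
#' guild-specific partial networks) and the forest it came from. Rows and
#' columns with no associations are pruned at construction.
#'
#' @slot assoc Integer matrix, plants x OTUs, of association (sample) counts.
#' @slot category One of `networkCategories()`.
#' @slot forestId Single character forest identifier.
#'
#' @param assoc Plants x OTUs matrix of non-negative integers with unique
#'   dimnames.
#' @param category One of `networkCategories()`.
#' @param forestId Single character forest identifier.
#' @param prune Drop all-zero rows and columns (default `TRUE`).
#' @return A validated `SpeciesMatrix`.
#' @aliases SpeciesMatrix-class
#' @export SpeciesMatrix
#' @exportClass SpeciesMatrix
SpeciesMatrix <- setClass("SpeciesMatrix", slots = c(
  assoc = "matrix",
  category = "character",
  forestId = "character"
))

setValidity("SpeciesMatrix", function(object) {
  msg <- .checkCountMatrix(object@assoc, what = "assoc")
  if (!is.null(msg)) return(msg)
  if (length(object@category) != 1L || !object@category %in% .CATEGORIES)
    return(sprintf("category must be one of: %s",
                   paste(.CATEGORIES, collapse = ", ")))
  if (length(object@forestId) != 1L || !nzchar(object@forestId))
    return("forestId must be a single non-empty string")
  if (nrow(object@assoc) == 0L || ncol(object@assoc) == 0L)
    return("assoc must have at least one row and one column")
  if (any(rowSums(object@assoc) == 0) || any(colSums(object@assoc) == 0))
    return("assoc must not contain all-zero rows or columns (prune first)")
  TRUE
})

setMethod("initialize", "SpeciesMatrix", function(.Object, assoc, category,
                                                  forestId, prune = TRUE, ...) {
  if (!missing(assoc)) {
    if (isTRUE(prune) && is.matrix(assoc)) {
      assoc <- assoc[rowSums(assoc) > 0, , drop = FALSE]
      assoc <- assoc[, colSums(assoc) > 0, drop = FALSE]
    }
    storage.mode(assoc) <- "integer"
    .Object@assoc <- assoc
  }
  if (!missing(category)) .Object@category <- as.character(category)
  if (!missing(forestId)) .Object@forestId <- as.character(forestId)
  validObject(.Object)
  .Object
})

#' NullEnsemble: index values under the host-label-shuffle null
#'
#' Holds the values of one structural index computed on randomized
#' species-level matrices, obtained by shuffling host plant labels in a
#' sample-level matrix. Randomizations that produced degenerate matrices
#' (fewer than two plants or two OTUs after category extraction) are counted
#' in `nFailed` rather than imputed.
#'
#' @slot metricName One of `"h2prime"`, `"wnodf"`, `"cscore"`.
#' @slot values Numeric vector of index values, one per successful
#'   randomization.
#' @slot nRequested Number of randomizations requested.
#' @slot nFailed Number of degenerate randomizations.
#' @slot seed Master seed of the ensemble.
#' @aliases NullEnsemble-class
#' @export NullEnsemble
#' @exportClass NullEnsemble
NullEnsemble <- setClass("NullEnsemble", slots = c(
  metricName = "character",
  values = "numeric",
  nRequested = "integer",
  nFailed = "integer",
  seed = "numeric"
))

setValidity("NullEnsemble", function(object) {
  if (length(object@metricName) != 1L)
    return("metricName must be a single string")
  if (length(object@values) + object@nFailed != object@nRequested)
    return("length(values) + nFailed must equal nRequested")
  if (length(object@values) && any(!is.finite(object@values)))
    return("null index values must be finite")
  TRUE
})

#' RelativeIndex: a null-standardized (z-score) network index
#'
#' The relative index value `z = (observed - mean(null)) / sd(null)`, where
#' the null distribution comes from a [NullEnsemble]. Values above roughly 2
#' (below -2) indicate an index larger (smaller) than expected by chance;
#' negative relative nestedness is the "anti-nested" signature.
#'
#' @slot observed Observed index value.
#' @slot nullMean Mean of the null ensemble.
#' @slot nullSd Sample standard deviation (n - 1 denominator) of the null
#'   ensemble; must be positive.
#' @slot z The standardized score.
#' @aliases RelativeIndex-class
#' @export RelativeIndex
#' @exportClass RelativeIndex
RelativeIndex <- setClass("RelativeIndex", slots = c(
  observed = "numeric",
  nullMean = "numeric",
  nullSd = "numeric",
  z = "numeric"
))

setValidity("RelativeIndex", function(object) {
  for (s in c("observed", "nullMean", "nullSd", "z"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("%s must be a single finite number", s))
  if (object@nullSd <= 0) return("nullSd must be positive")
  expect <- (object@observed - object@nullMean) / object@nullSd
  if (abs(object@z - expect) > 1e-8 * max(1, abs(expect)))
    return("z must equal (observed - nullMean) / nullSd")
  TRUE
})

# ---- accessors ----

#' Accessors for mycorrnet data classes
#'
#' @param x A [SampleTable], [SpeciesMatrix], [NullEnsemble] or
#'   [RelativeIndex] object.
#' @return The requested component: ids, labels, matrices, or scalar values.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "SampleTable", function(x) rownames(x@counts))

#' @rdname accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))
#' @rdname accessors
#' @export
setMethod("otuIds", "SampleTable", function(x) colnames(x@counts))
#' @rdname accessors
#' @export
setMethod("otuIds", "SpeciesMatrix", function(x) colnames(x@assoc))

#' @rdname accessors
#' @export
setGeneric("plantLabels", function(x) standardGeneric("plantLabels"))
#' @rdname accessors
#' @export
setMethod("plantLabels", "SampleTable", function(x) x@plantLabels)
#' @rdname accessors
#' @export
setMethod("plantLabels", "SpeciesMatrix", function(x) rownames(x@assoc))

#' @rdname accessors
#' @export
setGeneric("forestId", function(x) standardGeneric("forestId"))
#' @rdname accessors
#' @export
setMethod("forestId", "SampleTable", function(x) x@forestId)
#' @rdname accessors
#' @export
setMethod("forestId", "SpeciesMatrix", function(x) x@forestId)

#' @rdname accessors
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))
#' @rdname accessors
#' @export
setMethod("countMatrix", "SampleTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))
#' @rdname accessors
#' @export
setMethod("assocMatrix", "SpeciesMatrix", function(x) x@assoc)

#' @rdname accessors
#' @export
setGeneric("networkCategory", function(x) standardGeneric("networkCategory"))
#' @rdname accessors
#' @export
setMethod("networkCategory", "SpeciesMatrix", function(x) x@category)

#' @rdname accessors
#' @export
setGeneric("ensembleValues", function(x) standardGeneric("ensembleValues"))
#' @rdname accessors
#' @export
setMethod("ensembleValues", "NullEnsemble", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setMethod("metricName", "NullEnsemble", function(x) x@metricName)

#' @rdname accessors
#' @export
setGeneric("nFailed", function(x) standardGeneric("nFailed"))
#' @rdname accessors
#' @export
setMethod("nFailed", "NullEnsemble", function(x) x@nFailed)

#' @rdname accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))
#' @rdname accessors
#' @export
setMethod("zScore", "RelativeIndex", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("observedValue", function(x) standardGeneric("observedValue"))
#' @rdname accessors
#' @export
setMethod("observedValue", "RelativeIndex", function(x) x@observed)

#' @rdname accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))
#' @rdname accessors
#' @export
setMethod("nullMean", "RelativeIndex", function(x) x@nullMean)

#' @rdname accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))
#' @rdname accessors
#' @export
setMethod("nullSd", "RelativeIndex", function(x) x@nullSd)

#' Is a species matrix too small for structural indices?
#'
#' A plant-by-fungus matrix with fewer than two plants or fewer than two
#' OTUs is flagged degenerate; the structural indices refuse it.
#'
#' @param x A [SpeciesMatrix] or plain matrix.
#' @return `TRUE` if degenerate.
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
#' @rdname isDegenerate
#' @export
setMethod("isDegenerate", "SpeciesMatrix", function(x)
  nrow(x@assoc) < 2L || ncol(x@assoc) < 2L)
#' @rdname isDegenerate
#' @export
setMethod("isDegenerate", "matrix", function(x) nrow(x) < 2L || ncol(x) < 2L)

# ---- show methods ----

setMethod("show", "SampleTable", function(object) {
  cat(sprintf(
    "SampleTable (forest %s): %d samples x %d OTUs, %d plant species/taxa\n",
    object@forestId, nrow(object@counts), ncol(object@counts),
    length(unique(object@plantLabels))
  ))
  tot <- rowSums(object@counts)
  cat(sprintf("  read depth: min %d, median %d, max %d\n",
              min(tot), as.integer(stats::median(tot)), max(tot)))
})

setMethod("show", "SpeciesMatrix", function(object) {
  cat(sprintf(
    "SpeciesMatrix [%s] (forest %s): %d plants x %d OTUs, %d links%s\n",
    object@category, object@forestId, nrow(object@assoc), ncol(object@assoc),
    sum(object@assoc > 0),
    if (isDegenerate(object)) " (degenerate)" else ""
  ))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf(
    "NullEnsemble '%s': %d/%d successful randomizations (seed %s)\n",
    object@metricName, length(object@values), object@nRequested,
    format(object@seed)
  ))
  if (length(object@values) >= 2L)
    cat(sprintf("  null mean %.4g, sd %.4g\n", mean(object@values),
                sd(object@values)))
})

setMethod("show", "RelativeIndex", function(object) {
  cat(sprintf(
    "RelativeIndex: observed %.4g, null %.4g +/- %.4g, z = %.3f\n",
    object@observed, object@nullMean, object@nullSd, object@z
  ))
})
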