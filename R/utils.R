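# Closed vocabularies shared across the package.
.GUILDS <- c("AM", "ECM", "SAPENDO", "PATHO", "UNKNOWN")
.PLANT_TYPES <- c("AM_PLANT", "ECM_PLANT", "NM_PLANT", "DUAL")
.CATEGORIES <- c("ALL", "AM", "AM_EX", "ECM", "ECM_EX", "SAPENDO", "PATHO")

#' Controlled vocabularies
#'
#' The closed vocabularies used throughout the package: fungal functional
#' guilds, plant mycorrhizal types, and network categories. `AM_EX` and
#' `ECM_EX` are the arbuscular-mycorrhizal and ectomycorrhizal partial
#' networks restricted to compatible plants as well as fungi.
#'
#' @return A character vector of vocabulary values.
#' @examples
#' fungalGuilds()
#' networkCategories()
#' @export
fungalGuilds <- function() .GUILDS

#' @rdname fungalGuilds
#' @export
plantMycorrhizalTypes <- function() .PLANT_TYPES

#' @rdname fungalGuilds
#' @export
networkCategories <- function() .CATEGORIES

# Largest signed 32-bit prime modulus; all derived seeds stay below 2^31.
.M31 <- 2147483647

# Deterministic, platform-independent string hash (polynomial rolling hash).
hashString <- function(x) {
  h <- 7
  for (b in utf8ToInt(as.character(x))) h <- (h * 31 + b) %% .M31
  h
}

#' Derive a child seed from a master seed and a string key
#'
#' Stochastic stages key their randomness on stable identifiers (sample ids,
#' permutation indices) so that results are independent of input row order
#' and of the execution order of permutations.
#'
#' @param seed Integer master seed.
#' @param key Character key (e.g. a sample id).
#' @return An integer seed in `[0, 2^31)`.
#' @export
childSeed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (((seed %% .M31) * 48271) %% .M31 + hashString(key)) %% .M31
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Validate a numeric matrix of read counts; returns an error message naming
# the first offending cell, or NULL when valid.
.checkCountMatrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    return(sprintf("%s must be a numeric matrix", what))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    return(sprintf("%s must carry row and column names", what))
  if (anyDuplicated(rownames(counts)))
    return("duplicated sample_id")
  if (anyDuplicated(colnames(counts)))
    return("duplicated otu_id")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(counts))
    return(sprintf(
      "invalid count %s at row '%s', column '%s' (must be a non-negative integer)",
      format(counts[bad[1L]]), rownames(counts)[ij[1L]], colnames(counts)[ij[2L]]
    ))
  }
  NULL
}

.matchArg <- function(arg, choices, what) {
  if (!is.character(arg) || length(arg) != 1L || !arg %in% choices)
    stop(sprintf("%s must be one of: %s", what, paste(choices, collapse = ", ")),
         call. = FALSE)
  arg
}
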