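# Cross-site comparison: assemble the forest x category property table and
# model it (ANOVA with Bonferroni correction; correlation-matrix PCA).

.PT_COLUMNS <- c("forest_id", "category", "n_plants", "n_otus",
                 "fungus_plant_ratio", "connectance",
                 "rel_h2prime", "rel_wnodf", "rel_cscore")

#' Assemble the forest x category property table
#'
#' One row per (forest, category) combination, carrying the size and
#' connectance of the network together with the relative (null-
#' standardized) structural indices. Undefined indices are stored as `NA`;
#' rows are kept even when all their relative indices are missing.
#'
#' @param entries A data.frame with (at least) columns `forest_id`,
#'   `category`, `n_plants`, `n_otus`, `fungus_plant_ratio`, `connectance`,
#'   `rel_h2prime`, `rel_wnodf`, `rel_cscore` — e.g. row-bound results of
#'   [analyzeForest()].
#' @return A data.frame with the canonical column order, stable across
#'   runs.
#' @export
buildPropertyTable <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  missing <- setdiff(.PT_COLUMNS, names(entries))
  if (length(missing))
    stop("entries lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  key <- paste(entries$forest_id, entries$category, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (forest_id, category) row: ",
         sub("\r", " / ", key[duplicated(key)][1L]), call. = FALSE)
  out <- entries[order(entries$forest_id,
                       match(entries$category, .CATEGORIES)),
                 .PT_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Analyze one forest: observed and relative indices for each category
#'
#' For every requested network category, aggregates the sample table to the
#' species level, extracts the category, computes the structural indices
#' ([networkSummary()]) and standardizes H2', weighted NODF and the C-score
#' against their host-label-shuffle null distributions. Categories whose
#' matrices are degenerate (or whose ensembles are rejected) get `NA`
#' relative indices; the row is retained.
#'
#' @param x A preprocessed [SampleTable].
#' @param otuAnnotations,plantAnnotations Annotation data.frames.
#' @param categories Character vector of categories to analyze.
#' @param nPerm Named vector of randomization counts per metric; the
#'   defaults mirror the usual practice of 1000 randomizations for H2' and
#'   nestedness and 100 for the costlier checkerboard score.
#' @param seed Integer master seed; each (category, metric) ensemble draws
#'   a child seed.
#' @param nullScope Passed to [nullDistribution()].
#' @return A data.frame with one row per category: the [networkSummary()]
#'   columns plus `rel_h2prime`, `rel_wnodf`, `rel_cscore`.
#' @export
analyzeForest <- function(x, otuAnnotations, plantAnnotations,
                          categories = networkCategories(),
                          nPerm = c(h2prime = 1000, wnodf = 1000, cscore = 100),
                          seed,
                          nullScope = "full") {
  stopifnot(is(x, "SampleTable"))
  all <- aggregateToSpecies(x)
  rows <- lapply(categories, function(cat) {
    m <- tryCatch(
      extractPartial(all, otuAnnotations, plantAnnotations, cat),
      error = function(e) NULL)
    if (is.null(m)) {
      row <- data.frame(forest_id = forestId(x), category = cat,
                        n_plants = 0L, n_otus = 0L,
                        fungus_plant_ratio = NA_real_,
                        connectance = NA_real_, h2prime = NA_real_,
                        wnodf = NA_real_, cscore = NA_real_,
                        stringsAsFactors = FALSE)
    } else {
      row <- networkSummary(m)
    }
    for (metric in c("h2prime", "wnodf", "cscore")) {
      rel <- NA_real_
      if (!is.na(row[[metric]])) {
        rel <- tryCatch({
          ens <- nullDistribution(
            x, otuAnnotations, plantAnnotations, cat, metric,
            nPerm = nPerm[[metric]],
            seed = childSeed(seed, paste("null", cat, metric, sep = ":")),
            nullScope = nullScope)
          zScore(relativeIndex(row[[metric]], ens))
        }, error = function(e) NA_real_)
      }
      row[[paste0("rel_", metric)]] <- rel
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ANOVA of a relative network index across forests and categories
#'
#' Fits the linear model
#' `response ~ n_plants + n_otus + connectance + locality + category`
#' (locality = forest site as a factor) and reports per-term F tests.
#' Sequential (type-I) sums of squares in the order above are the default;
#' `ss = "marginal"` reports marginal F tests instead (each term dropped
#' from the full model). P values receive a Bonferroni correction across
#' the terms of this model (alpha is conventionally 0.05).
#'
#' @param pt A property table (see [buildPropertyTable()]).
#' @param response One of `"rel_h2prime"`, `"rel_wnodf"`, `"rel_cscore"`.
#' @param ss `"sequential"` (default) or `"marginal"`.
#' @return A data.frame with columns `term`, `df`, `F`, `p`,
#'   `p_bonferroni`.
#' @export
anovaNetworkProperties <- function(pt, response = c("rel_h2prime",
                                                    "rel_wnodf",
                                                    "rel_cscore"),
                                   ss = c("sequential", "marginal")) {
  response <- match.arg(response)
  ss <- match.arg(ss)
  need <- c(response, "n_plants", "n_otus", "connectance", "forest_id",
            "category")
  missing <- setdiff(need, names(pt))
  if (length(missing))
    stop("property table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- pt[, need]
  names(d)[1L] <- ".response"
  d <- d[complete.cases(d), , drop = FALSE]
  d$locality <- factor(d$forest_id)
  d$category <- factor(d$category)
  nTerms <- 5L
  if (nrow(d) < nTerms + 2L)
    stop("too few complete rows for the ANOVA model", call. = FALSE)
  lone <- c(names(which(table(d$locality) < 2L)),
            names(which(table(d$category) < 2L)))
  fit <- lm(.response ~ n_plants + n_otus + connectance + locality + category,
            data = d)
  if (anyNA(coef(fit))) {
    alias <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design (level(s) ",
         paste(unique(c(lone, alias)), collapse = ", "),
         " unestimable after removing missing rows)", call. = FALSE)
  }
  if (ss == "sequential") {
    a <- anova(fit)
    keep <- rownames(a) != "Residuals"
    out <- data.frame(term = rownames(a)[keep], df = a$Df[keep],
                      F = a$`F value`[keep], p = a$`Pr(>F)`[keep],
                      stringsAsFactors = FALSE)
  } else {
    a <- drop1(fit, . ~ ., test = "F")
    keep <- !is.na(a$Df)
    out <- data.frame(term = rownames(a)[keep], df = a$Df[keep],
                      F = a$`F value`[keep], p = a$`Pr(>F)`[keep],
                      stringsAsFactors = FALSE)
  }
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Correlation-matrix PCA of network properties
#'
#' Principal component analysis of the seven network descriptors (relative
#' H2', relative weighted NODF, relative C-score, number of plant
#' species/taxa, number of fungal OTUs, fungus/plant ratio, connectance),
#' standardized to zero mean and unit variance (i.e. PCA of the correlation
#' matrix). Rows with any missing descriptor are dropped. The loading sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param pt A property table (see [buildPropertyTable()]).
#' @return A list of class `"pcaNetworkProperties"` with elements
#'   `loadings` (variable x component), `scores` (row x component) and
#'   `explained_variance` (proportions summing to 1).
#' @export
pcaNetworkProperties <- function(pt) {
  vars <- c("rel_h2prime", "rel_wnodf", "rel_cscore", "n_plants", "n_otus",
            "fungus_plant_ratio", "connectance")
  missing <- setdiff(vars, names(pt))
  if (length(missing))
    stop("property table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(pt[, vars])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L)
    stop("need at least 3 complete rows for PCA", call. = FALSE)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("constant variable(s): ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  structure(list(
    loadings = pr$rotation,
    scores = pr$x,
    explained_variance = pr$sdev^2 / sum(pr$sdev^2)
  ), class = "pcaNetworkProperties")
}

#' @export
print.pcaNetworkProperties <- function(x, ...) {
  cat("Correlation-matrix PCA of network properties\n")
  ev <- round(100 * x$explained_variance, 1)
  cat("  variance explained (%):", paste(ev, collapse = ", "), "\n")
  cat("  loadings (first 3 components):\n")
  print(round(x$loadings[, seq_len(min(3L, ncol(x$loadings))), drop = FALSE],
              3))
  invisible(x)
}
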