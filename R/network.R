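# From sample-level counts to plant-by-fungus association matrices and the
# seven network categories (ALL, AM, AM_EX, ECM, ECM_EX, SAPENDO, PATHO).

# Fast path used by the null-model loop: aggregate a 0/1 presence matrix by
# plant label. Rows of the result are sorted unique labels.
.aggregatePresence <- function(presence, labels) {
  rowsum(presence, labels)
}

#' Aggregate a sample table into a species-level association matrix
#'
#' Builds the plant species/taxa x fungal OTU matrix in which cell (p, o)
#' counts the samples labeled with plant p in which OTU o had a nonzero read
#' count (presence, not read abundance). Plants and OTUs with no
#' associations are pruned. The result is the `ALL`-category network.
#'
#' @param x A preprocessed [SampleTable].
#' @return A [SpeciesMatrix] with category `"ALL"`.
#' @export
aggregateToSpecies <- function(x) {
  stopifnot(is(x, "SampleTable"))
  presence <- (countMatrix(x) > 0) * 1L
  assoc <- .aggregatePresence(presence, plantLabels(x))
  SpeciesMatrix(assoc, "ALL", forestId(x))
}

# Compatibility of plant mycorrhizal types with the AM_EX / ECM_EX plant
# restrictions. DUAL plants (documented hosts of both symbiosis types) are
# retained in both exclusive partial networks.
.plantsKeptFor <- function(category) {
  switch(category,
    AM_EX = c("AM_PLANT", "DUAL"),
    ECM_EX = c("ECM_PLANT", "DUAL"),
    .PLANT_TYPES
  )
}

.guildFor <- function(category) {
  switch(category,
    AM = , AM_EX = "AM",
    ECM = , ECM_EX = "ECM",
    SAPENDO = "SAPENDO",
    PATHO = "PATHO",
    NULL
  )
}

# Look up guilds for a set of OTU ids (missing -> UNKNOWN) and mycorrhizal
# types for plant labels (missing -> NM_PLANT, with a warning: conservative
# exclusion from AM_EX / ECM_EX).
.guildVector <- function(otuIds, otuAnnotations) {
  g <- setNames(otuAnnotations$guild, otuAnnotations$otu_id)[otuIds]
  g[is.na(g)] <- "UNKNOWN"
  unname(g)
}

.plantTypeVector <- function(labels, plantAnnotations, warn = TRUE) {
  t <- setNames(plantAnnotations$mycorrhizal_type,
                plantAnnotations$plant_label)[labels]
  if (anyNA(t) && warn)
    warning("unannotated plant(s) treated as NM_PLANT: ",
            paste(head(labels[is.na(t)], 5L), collapse = ", "),
            call. = FALSE)
  t[is.na(t)] <- "NM_PLANT"
  unname(t)
}

#' Extract a guild-specific partial network
#'
#' Restricts an `ALL` species matrix to one of the network categories:
#' `AM`, `ECM`, `SAPENDO` and `PATHO` keep the fungal OTUs of the matching
#' guild and all plants; `AM_EX` additionally drops plants that are not
#' arbuscular-mycorrhizal hosts (keeping `AM_PLANT` and `DUAL`); `ECM_EX`
#' keeps ectomycorrhizal fungi and only `ECM_PLANT` and `DUAL` plants;
#' `ALL` is the identity. Rows and columns left without associations are
#' pruned. OTUs without an annotation default to guild `UNKNOWN`; plants
#' without an annotation default to `NM_PLANT` with a warning.
#'
#' @param x A [SpeciesMatrix] of category `"ALL"`.
#' @param otuAnnotations Data.frame with columns `otu_id`, `guild` (see
#'   [readAnnotations()]).
#' @param plantAnnotations Data.frame with columns `plant_label`,
#'   `mycorrhizal_type`.
#' @param category One of `networkCategories()`.
#' @return A [SpeciesMatrix] of the requested category. The result may be
#'   degenerate (fewer than 2 plants or OTUs); structural indices refuse
#'   such matrices (see [isDegenerate()]).
#' @export
extractPartial <- function(x, otuAnnotations, plantAnnotations, category) {
  stopifnot(is(x, "SpeciesMatrix"))
  category <- .matchArg(category, .CATEGORIES, "category")
  if (networkCategory(x) != "ALL")
    stop("partial networks are extracted from the ALL matrix", call. = FALSE)
  if (category == "ALL")
    return(SpeciesMatrix(assocMatrix(x), "ALL", forestId(x)))
  assoc <- assocMatrix(x)
  guild <- .guildFor(category)
  colKeep <- .guildVector(colnames(assoc), otuAnnotations) == guild
  rowKeep <- .plantTypeVector(rownames(assoc), plantAnnotations) %in%
    .plantsKeptFor(category)
  sub <- assoc[rowKeep, colKeep, drop = FALSE]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  sub <- sub[, colSums(sub) > 0, drop = FALSE]
  if (nrow(sub) == 0L || ncol(sub) == 0L)
    stop(sprintf("category %s has no associations in forest %s", category,
                 forestId(x)), call. = FALSE)
  SpeciesMatrix(sub, category, forestId(x), prune = FALSE)
}

#' Betweenness centrality of network nodes
#'
#' Shortest-path betweenness on the unweighted bipartite graph whose
#' vertices are the plants and fungal OTUs of a species matrix and whose
#' edges are its nonzero cells. Used for node sizing in network figures;
#' disconnected graphs are allowed (betweenness is then computed within
#' components).
#'
#' @param x A non-degenerate [SpeciesMatrix].
#' @return A data.frame with columns `node`, `side` (`"plant"` or
#'   `"fungus"`) and `betweenness`, ranked by decreasing betweenness within
#'   each side.
#' @export
betweennessScores <- function(x) {
  stopifnot(is(x, "SpeciesMatrix"))
  if (isDegenerate(x)) stop("degenerate species matrix", call. = FALSE)
  inc <- assocMatrix(x) > 0
  g <- igraph::graph_from_biadjacency_matrix(inc)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  side <- ifelse(igraph::V(g)$type, "fungus", "plant")
  out <- data.frame(node = igraph::V(g)$name, side = side,
                    betweenness = unname(btw), stringsAsFactors = FALSE)
  out <- out[order(out$side, -out$betweenness, out$node), ]
  rownames(out) <- NULL
  out
}
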