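# Fixtures built in code and independent brute-force oracles used to check
# the package's implementations.

makeTable <- function(counts, labels, forest = "F1") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("otu%02d", seq_len(ncol(counts)))
  SampleTable(counts, labels, forest)
}

randomTable <- function(nSamples, nOtus, nPlants, seed, lambda = 3,
                        forest = "F1") {
  set.seed(seed)
  counts <- matrix(rpois(nSamples * nOtus, lambda), nSamples, nOtus,
                   dimnames = list(sprintf("s%03d", seq_len(nSamples)),
                                   sprintf("otu%03d", seq_len(nOtus))))
  storage.mode(counts) <- "integer"
  makeTable(counts, sample(sprintf("plant%02d", seq_len(nPlants)),
                           nSamples, replace = TRUE), forest)
}

randomAssoc <- function(nr, nc, seed, lambda = 2) {
  set.seed(seed)
  a <- matrix(rpois(nr * nc, lambda), nr, nc,
              dimnames = list(sprintf("p%02d", seq_len(nr)),
                              sprintf("o%02d", seq_len(nc))))
  # guarantee no all-zero rows/columns
  for (i in which(rowSums(a) == 0)) a[i, sample.int(nc, 1)] <- 1
  for (j in which(colSums(a) == 0)) a[sample.int(nr, 1), j] <- 1
  a
}

# ---- brute-force metric oracles (independent of the package internals) ----

oracleConnectance <- function(a) {
  cnt <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (a[i, j] > 0) cnt <- cnt + 1
  cnt / (nrow(a) * ncol(a))
}

oracleWnodf <- function(a) {
  rt <- rowSums(a); ct <- colSums(a)
  scores <- c()
  pairScore <- function(u, v) {  # u richer slice, v poorer slice
    nz <- sum(v > 0)
    if (nz == 0) return(0)
    100 * sum(v > 0 & v < u) / nz
  }
  for (i in seq_len(nrow(a) - 1)) for (k in (i + 1):nrow(a)) {
    scores <- c(scores, if (rt[i] == rt[k]) 0 else
      if (rt[i] > rt[k]) pairScore(a[i, ], a[k, ]) else pairScore(a[k, ], a[i, ]))
  }
  for (j in seq_len(ncol(a) - 1)) for (l in (j + 1):ncol(a)) {
    scores <- c(scores, if (ct[j] == ct[l]) 0 else
      if (ct[j] > ct[l]) pairScore(a[, j], a[, l]) else pairScore(a[, l], a[, j]))
  }
  mean(scores)
}

oracleCscore <- function(a) {
  b <- a > 0
  n <- ncol(b)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ri <- sum(b[, i]); rj <- sum(b[, j]); s <- sum(b[, i] & b[, j])
    vals <- c(vals, (ri - s) * (rj - s))
  }
  mean(vals)
}

# Exhaustive enumeration of non-negative integer matrices with fixed
# marginals; exact entropy extremes and exact H2'.
enumerateMatrices <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  out <- list()
  rec <- function(mat, i, rrem, crem) {
    if (i > nr) {
      if (all(crem == 0)) out[[length(out) + 1L]] <<- mat
      return(invisible())
    }
    fillRow <- function(row, j, left, crem) {
      if (j == nc) {
        if (left <= crem[nc]) {
          row[nc] <- left
          mat[i, ] <- row
          crem2 <- crem; crem2[nc] <- crem2[nc] - left
          rec(mat, i + 1L, rrem, crem2)
        }
        return(invisible())
      }
      for (v in 0:min(left, crem[j])) {
        row[j] <- v
        crem2 <- crem; crem2[j] <- crem2[j] - v
        fillRow(row, j + 1L, left - v, crem2)
      }
    }
    fillRow(numeric(nc), 1L, rs[i], crem)
    invisible()
  }
  rec(matrix(0, nr, nc), 1L, rs, cs)
  out
}

entropyOf <- function(a) {
  m <- sum(a); p <- a[a > 0] / m
  -sum(p * log(p))
}

exactH2prime <- function(a) {
  mats <- enumerateMatrices(rowSums(a), colSums(a))
  hs <- vapply(mats, entropyOf, numeric(1))
  (max(hs) - entropyOf(a)) / (max(hs) - min(hs))
}

# Expected accumulation curve by exhaustive subset enumeration.
oracleAccum <- function(presence) {
  n <- nrow(presence)
  vapply(seq_len(n), function(k) {
    subsets <- utils::combn(n, k)
    mean(apply(subsets, 2, function(idx)
      sum(colSums(presence[idx, , drop = FALSE]) > 0)))
  }, numeric(1))
}

# All-pairs shortest-path betweenness by explicit path counting (each
# unordered pair counted once), independent of igraph.
oracleBetweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sig[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- dist[s, v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[s, w] == dist[s, v] + 1)
          sig[s, w] <- sig[s, w] + sig[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t])
        btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
  }
  btw
}

# Small annotation fixtures.
makeOtuAnn <- function(otuIds, guilds) {
  data.frame(otu_id = otuIds, taxonomy = NA_character_, guild = guilds,
             stringsAsFactors = FALSE)
}
makePlantAnn <- function(labels, types) {
  data.frame(plant_label = labels, mycorrhizal_type = types,
             stringsAsFactors = FALSE)
}
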