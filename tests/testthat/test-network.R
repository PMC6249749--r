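test_that("species aggregation counts samples with presence, not reads", {
  counts <- rbind(
    s1 = c(5L, 0L, 1L),
    s2 = c(999L, 0L, 0L),
    s3 = c(0L, 0L, 2L),
    s4 = c(0L, 3L, 0L)
  )
  colnames(counts) <- c("o1", "o2", "o3")
  st <- makeTable(counts, c("pA", "pA", "pA", "pB"))
  sm <- aggregateToSpecies(st)
  a <- assocMatrix(sm)
  expect_identical(a["pA", "o1"], 2L)  # read counts 5 and 999 each add 1
  expect_identical(a["pA", "o3"], 2L)
  expect_identical(a["pB", "o2"], 1L)
  expect_false("o2" %in% rownames(a))  # pruning of empty rows/cols
  expect_identical(networkCategory(sm), "ALL")
})

test_that("aggregation matches a naive double loop and conserves presences", {
  for (seed in 1:3) {
    st <- randomTable(20, 15, 5, seed = seed, lambda = 0.5)
    a <- assocMatrix(aggregateToSpecies(st))
    counts <- countMatrix(st)
    labels <- plantLabels(st)
    for (p in rownames(a)) for (o in colnames(a)) {
      expect_identical(a[p, o],
                       sum(labels == p & counts[, o] > 0))
    }
    expect_identical(sum(a), sum(counts > 0))  # conservation
  }
})

test_that("partial networks follow the guild and plant selection rules", {
  counts <- rbind(
    s1 = c(4L, 2L, 0L, 0L, 1L),
    s2 = c(0L, 3L, 5L, 0L, 0L),
    s3 = c(0L, 0L, 2L, 7L, 1L),
    s4 = c(1L, 0L, 0L, 2L, 0L)
  )
  colnames(counts) <- paste0("o", 1:5)
  st <- makeTable(counts, c("pAM", "pAM", "pECM", "pDUAL"))
  otus <- makeOtuAnn(paste0("o", 1:5),
                     c("AM", "AM", "ECM", "ECM", "SAPENDO"))
  plants <- makePlantAnn(c("pAM", "pECM", "pDUAL"),
                         c("AM_PLANT", "ECM_PLANT", "DUAL"))
  all <- aggregateToSpecies(st)

  am <- extractPartial(all, otus, plants, "AM")
  expect_setequal(otuIds(am), c("o1", "o2"))
  expect_identical(networkCategory(am), "AM")

  # AM_EX drops the ECM plant; DUAL plants stay in both exclusive networks
  amex <- extractPartial(all, otus, plants, "AM_EX")
  expect_setequal(plantLabels(amex), c("pAM", "pDUAL"))
  ecmex <- extractPartial(all, otus, plants, "ECM_EX")
  expect_true("pDUAL" %in% plantLabels(ecmex))
  expect_false("pAM" %in% plantLabels(ecmex))

  # an ECM OTU associated only with an AM plant is pruned from ECM_EX
  # (o3 associates with pAM via s2 and pECM via s3; o4 with pECM/pDUAL)
  counts2 <- counts
  counts2["s3", "o3"] <- 0L
  st2 <- makeTable(counts2, c("pAM", "pAM", "pECM", "pDUAL"))
  ecmex2 <- extractPartial(aggregateToSpecies(st2), otus, plants, "ECM_EX")
  expect_false("o3" %in% otuIds(ecmex2))
})

test_that("guild categories partition the ALL columns on random fixtures", {
  set.seed(42)
  for (rep in 1:3) {
    st <- randomTable(30, 25, 6, seed = 100 + rep, lambda = 0.7)
    guilds <- sample(fungalGuilds(), 25, replace = TRUE)
    otus <- makeOtuAnn(otuIds(st), guilds)
    plants <- makePlantAnn(sprintf("plant%02d", 1:6),
                           sample(plantMycorrhizalTypes(), 6, replace = TRUE))
    all <- aggregateToSpecies(st)
    parts <- character(0)
    for (cat in c("AM", "ECM", "SAPENDO", "PATHO")) {
      m <- tryCatch(extractPartial(all, otus, plants, cat),
                    error = function(e) NULL)
      if (!is.null(m)) {
        parts <- c(parts, otuIds(m))
        # always a value-preserving submatrix of ALL
        expect_identical(assocMatrix(m),
                         assocMatrix(all)[plantLabels(m), otuIds(m),
                                          drop = FALSE])
      }
    }
    unknown <- otuIds(all)[mycorrnet:::.guildVector(otuIds(all), otus) ==
                             "UNKNOWN"]
    expect_setequal(c(parts, unknown), otuIds(all))
  }
})

test_that("pruning is a fixpoint and degeneracy is flagged", {
  a <- randomAssoc(5, 7, seed = 1)
  sm <- SpeciesMatrix(a, "ALL", "F1")
  re <- SpeciesMatrix(assocMatrix(sm), "ALL", "F1")
  expect_identical(assocMatrix(re), assocMatrix(sm))

  degenerate <- SpeciesMatrix(matrix(1:5, 1, 5,
                                     dimnames = list("p1", paste0("o", 1:5))),
                              "ALL", "F1")
  expect_true(isDegenerate(degenerate))
  expect_false(isDegenerate(sm))
})

test_that("unannotated plants are excluded conservatively with a warning", {
  counts <- rbind(s1 = c(2L, 1L), s2 = c(0L, 3L))
  colnames(counts) <- c("o1", "o2")
  st <- makeTable(counts, c("pKnown", "pMystery"))
  otus <- makeOtuAnn(c("o1", "o2"), c("AM", "AM"))
  plants <- makePlantAnn("pKnown", "AM_PLANT")
  all <- aggregateToSpecies(st)
  expect_warning(m <- extractPartial(all, otus, plants, "AM_EX"),
                 "pMystery")
  expect_identical(plantLabels(m), "pKnown")
})

test_that("betweenness matches exhaustive shortest-path counting", {
  # star: the hub plant mediates all fungus-fungus paths
  star <- matrix(1L, 1, 4, dimnames = list("p1", paste0("o", 1:4)))
  # a 1 x k matrix is degenerate for indices but fine for centrality via
  # a padded 2-plant version
  a <- rbind(star, p2 = c(1L, 0L, 0L, 0L))
  sm <- SpeciesMatrix(a, "ALL", "F1")
  b <- betweennessScores(sm)
  expect_gt(b$betweenness[b$node == "p1"],
            max(b$betweenness[b$side == "fungus"]))

  # path p1 - o1 - p2: the bridging OTU scores, the ends do not
  pa <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("p1", "p2"), "o1"))
  pa <- cbind(pa, o2 = c(1L, 0L))
  bp <- betweennessScores(SpeciesMatrix(pa, "ALL", "F1"))
  expect_gt(bp$betweenness[bp$node == "o1"], 0)
  expect_equal(bp$betweenness[bp$node == "p2"], 0)

  # random bipartite graphs against the brute-force oracle
  for (seed in 1:3) {
    set.seed(seed)
    inc <- matrix(rbinom(64, 1, 0.3), 8, 8,
                  dimnames = list(paste0("p", 1:8), paste0("o", 1:8)))
    inc[rowSums(inc) == 0, 1] <- 1L
    inc[1, colSums(inc) == 0] <- 1L
    storage.mode(inc) <- "integer"
    sm <- SpeciesMatrix(inc, "ALL", "F1", prune = FALSE)
    got <- betweennessScores(sm)
    adj <- rbind(cbind(matrix(0, 8, 8), inc),
                 cbind(t(inc), matrix(0, 8, 8)))
    want <- oracleBetweenness(adj)
    names(want) <- c(paste0("p", 1:8), paste0("o", 1:8))
    expect_equal(got$betweenness, unname(want[got$node]), tolerance = 1e-9)
  }
})
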