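test_that("connectance is the fraction of realized links", {
  a <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("p1", "p2"),
                                                   c("o1", "o2")))
  expect_equal(connectance(a), 0.5)
  expect_equal(connectance(matrix(3, 4, 5)), 1.0)
  for (seed in 1:5) {
    r <- randomAssoc(10, 10, seed = seed)
    expect_equal(connectance(r), oracleConnectance(r))
  }
  expect_error(connectance(matrix(1:5, 1, 5)), "degenerate")
})

test_that("H2' hits its analytic endpoints", {
  diagm <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(h2Prime(diagm)$h2prime, 1)      # perfect specialization
  unif <- matrix(5, 2, 2)
  expect_equal(h2Prime(unif)$h2prime, 0)       # perfect generalization
  parts <- h2Prime(diagm)$parts
  expect_lte(parts$h2_min, parts$h2_raw + 1e-9)
})

test_that("heuristic H2' tracks the exhaustive marginal-constrained oracle", {
  # the 3x3 case with marginals (6,3,1) / (5,4,1)
  a <- matrix(c(4, 2, 0,
                1, 2, 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(rowSums(a), c(6, 3, 1), ignore_attr = TRUE)
  expect_equal(colSums(a), c(5, 4, 1), ignore_attr = TRUE)
  expect_lt(abs(h2Prime(a)$h2prime - exactH2prime(a)), 0.02)

  set.seed(7)
  for (rep in 1:8) {
    m <- matrix(rpois(9, 1), 3, 3)
    if (sum(m) < 2 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ex <- tryCatch(exactH2prime(m), error = function(e) NULL)
    h <- tryCatch(h2Prime(m)$h2prime, error = function(e) NULL)
    if (is.null(ex) || is.null(h) || !is.finite(ex)) next
    expect_lt(abs(h - ex), 0.02)
  }
})

test_that("H2' is invariant under permutation and (near) scaling", {
  a <- randomAssoc(5, 7, seed = 3)
  h <- h2Prime(a)$h2prime
  perm <- a[sample(nrow(a)), sample(ncol(a))]
  expect_equal(h2Prime(perm)$h2prime, h, tolerance = 1e-6)
  # integer rescaling preserves the interaction distribution; the
  # marginal-constrained integer extremes shift slightly with the total,
  # so equality is approximate (absolute scale)
  expect_lt(abs(h2Prime(a * 3L)$h2prime - h), 0.05)
})

test_that("H2' refuses matrices whose marginals admit a single distribution", {
  one <- matrix(c(7, 0, 0, 0), 2, 2)  # only one matrix has these marginals
  expect_error(h2Prime(one), "undefined")
})

test_that("weighted NODF matches hand enumeration and the tie rule", {
  tied <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(weightedNODF(tied), 0)   # all marginal totals tied

  nested <- matrix(c(4, 2, 1,
                     3, 1, 0,
                     2, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(weightedNODF(nested), 100)  # all six pair scores are 100
})

test_that("weighted NODF agrees with brute force and vegan on random matrices", {
  for (seed in 1:10) {
    a <- randomAssoc(6, 6, seed = 20 + seed)
    expect_equal(weightedNODF(a), oracleWnodf(a), tolerance = 1e-12)
  }
  # vegan gates pairs on binary fill rather than marginal totals; the two
  # definitions coincide when both orderings are strict and agree, so the
  # cross-check draws matrices until that holds
  consistent <- function(a) {
    ok <- function(tot, fill) {
      !anyDuplicated(tot) && !anyDuplicated(fill) &&
        identical(order(tot), order(fill))
    }
    ok(rowSums(a), rowSums(a > 0)) && ok(colSums(a), colSums(a > 0))
  }
  found <- 0
  n <- 5
  for (seed in 1:100) {
    set.seed(seed)
    a <- matrix(0, n, n)
    for (i in 1:n) for (j in seq_len(n - i + 1)) a[i, j] <- rpois(1, 3) + 1
    dimnames(a) <- list(paste0("p", 1:n), paste0("o", 1:n))
    if (!consistent(a)) next
    found <- found + 1
    v <- vegan::nestednodf(a, order = TRUE, weighted = TRUE)
    expect_equal(weightedNODF(a), unname(v$statistic["NODF"]),
                 tolerance = 1e-9)
    if (found >= 5) break
  }
  expect_gte(found, 3)
})

test_that("perfect nesting and block checkerboards sit at the NODF extremes", {
  # staircase with multiplicative weights: every poorer row/column is a
  # strict subset with strictly smaller cell values
  n <- 6
  b <- matrix(0, n, n)
  for (i in 1:n) for (j in seq_len(n - i + 1)) b[i, j] <- (n - i + 1) * (n - j + 1)
  expect_equal(weightedNODF(b), 100)

  blocks <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                  c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(weightedNODF(blocks), 0)  # cross-block pairs share nothing
})

test_that("checkerboard score measures host-range differentiation", {
  seg <- matrix(c(1, 0, 0, 1), 2, 2)   # plants x OTUs, no shared hosts
  expect_equal(cScore(seg), 1)
  full <- matrix(1, 2, 2)              # identical host sets
  expect_equal(cScore(full), 0)

  for (seed in 1:5) {
    set.seed(seed)
    b <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12)
    b[rowSums(b) == 0, 1] <- 1
    b[1, colSums(b) == 0] <- 1
    dimnames(b) <- list(paste0("p", 1:5), paste0("o", 1:12))
    expect_equal(cScore(b), oracleCscore(b))
  }

  # zero iff all OTUs share identical host sets
  same <- cbind(o1 = c(1, 1, 0), o2 = c(1, 1, 0), o3 = c(1, 1, 0))
  rownames(same) <- paste0("p", 1:3)
  expect_equal(cScore(same[1:2, ]), 0)
})

test_that("wnodf and cscore are invariant under row/column permutation", {
  a <- randomAssoc(6, 8, seed = 55)
  set.seed(1)
  perm <- a[sample(nrow(a)), sample(ncol(a))]
  expect_equal(weightedNODF(perm), weightedNODF(a), tolerance = 1e-12)
  expect_equal(cScore(a[sample(nrow(a)), ]), cScore(a), tolerance = 1e-12)
})

test_that("networkSummary bundles indices and degrades gracefully", {
  a <- matrix(c(3, 1, 0, 2, 2, 5), 2, 3,
              dimnames = list(c("p1", "p2"), c("o1", "o2", "o3")))
  sm <- SpeciesMatrix(a, "ALL", "F1")
  s <- networkSummary(sm)
  expect_identical(s$n_plants, 2L)
  expect_identical(s$n_otus, 3L)
  expect_equal(s$fungus_plant_ratio, 1.5)
  expect_equal(s$connectance, connectance(sm))
  expect_equal(s$h2prime, h2Prime(sm)$h2prime)
  expect_equal(s$wnodf, weightedNODF(sm))
  expect_equal(s$cscore, cScore(sm))

  degenerate <- SpeciesMatrix(matrix(1:5, 1, 5,
                                     dimnames = list("p1", paste0("o", 1:5))),
                              "ALL", "F1")
  sd <- networkSummary(degenerate)
  expect_identical(sd$n_plants, 1L)
  expect_identical(sd$n_otus, 5L)
  expect_true(is.finite(sd$connectance))
  expect_true(all(is.na(c(sd$h2prime, sd$wnodf, sd$cscore))))
  expect_true(!is.null(attr(sd, "undefined")))
})
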