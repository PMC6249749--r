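# A synthetic 8-forest x 7-category property table with noise responses.
syntheticPropertyTable <- function(seed = 1) {
  set.seed(seed)
  grid <- expand.grid(forest_id = sprintf("F%d", 1:8),
                      category = networkCategories(),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  data.frame(
    grid,
    n_plants = sample(17:55, n, replace = TRUE),
    n_otus = sample(300:1500, n, replace = TRUE),
    fungus_plant_ratio = runif(n, 5, 60),
    connectance = runif(n, 0.02, 0.5),
    rel_h2prime = rnorm(n, 20, 8),
    rel_wnodf = rnorm(n, -5, 4),
    rel_cscore = rnorm(n, 5, 3),
    stringsAsFactors = FALSE
  )
}

test_that("the property table has one stable row per forest and category", {
  pt <- buildPropertyTable(syntheticPropertyTable())
  expect_identical(nrow(pt), 56L)   # 8 forests x 7 categories
  expect_identical(names(pt)[1:2], c("forest_id", "category"))
  expect_identical(pt, buildPropertyTable(syntheticPropertyTable()))

  dup <- rbind(syntheticPropertyTable(), syntheticPropertyTable()[1, ])
  expect_error(buildPropertyTable(dup), "duplicated")

  # missing relative indices are carried, not dropped
  d <- syntheticPropertyTable()
  d$rel_h2prime[3] <- NA
  pt2 <- buildPropertyTable(d)
  expect_identical(nrow(pt2), 56L)
  expect_true(anyNA(pt2$rel_h2prime))
})

test_that("ANOVA df structure is fixed by the design, not the response", {
  pt <- buildPropertyTable(syntheticPropertyTable(2))
  for (resp in c("rel_h2prime", "rel_wnodf", "rel_cscore")) {
    a <- anovaNetworkProperties(pt, resp)
    df <- setNames(a$df, a$term)
    expect_identical(df[["locality"]], 7L)   # 8 forests
    expect_identical(df[["category"]], 6L)   # 7 categories
    expect_identical(df[["n_plants"]], 1L)
    expect_identical(df[["n_otus"]], 1L)
    expect_identical(df[["connectance"]], 1L)
    expect_equal(a$p_bonferroni, pmin(1, a$p * 5))
  }
})

test_that("sequential sums of squares reproduce an independent projection oracle", {
  pt <- buildPropertyTable(syntheticPropertyTable(3))
  a <- anovaNetworkProperties(pt, "rel_wnodf")

  # rebuild the sequential decomposition by successive QR projections
  d <- pt
  d$locality <- factor(d$forest_id)
  d$category <- factor(d$category)
  y <- d$rel_wnodf
  blocks <- list(
    n_plants = model.matrix(~n_plants, d),
    n_otus = model.matrix(~n_otus, d)[, -1, drop = FALSE],
    connectance = model.matrix(~connectance, d)[, -1, drop = FALSE],
    locality = model.matrix(~locality, d)[, -1, drop = FALSE],
    category = model.matrix(~category, d)[, -1, drop = FALSE]
  )
  X <- NULL
  rssPrev <- sum((y - mean(y))^2)
  ss <- df <- numeric(0)
  for (nm in names(blocks)) {
    X <- cbind(X, blocks[[nm]])
    fit <- qr(X)
    res <- qr.resid(fit, y)
    ss[nm] <- rssPrev - sum(res^2)
    rssPrev <- sum(res^2)
    df[nm] <- ncol(blocks[[nm]]) - (nm == "n_plants")  # intercept in block 1
  }
  dfRes <- nrow(d) - sum(df) - 1
  msRes <- rssPrev / dfRes
  Fvals <- (ss / df) / msRes
  expect_equal(a$F, unname(Fvals), tolerance = 1e-9)

  # sequential term SS plus residual SS equals the total SS
  expect_equal(sum(ss) + rssPrev, sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("p values are uniform when the response is pure noise", {
  pvals <- matrix(NA_real_, 1000, 5)
  base <- syntheticPropertyTable(4)
  for (i in seq_len(1000)) {
    d <- base
    set.seed(10000 + i)
    d$rel_h2prime <- rnorm(nrow(d))
    a <- anovaNetworkProperties(buildPropertyTable(d), "rel_h2prime")
    pvals[i, ] <- a$p
  }
  for (j in 1:5) {
    ks <- suppressWarnings(ks.test(pvals[, j], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("marginal SS is available and rank deficiency is reported", {
  pt <- buildPropertyTable(syntheticPropertyTable(5))
  m <- anovaNetworkProperties(pt, "rel_cscore", ss = "marginal")
  expect_setequal(m$term, c("n_plants", "n_otus", "connectance", "locality",
                            "category"))

  # leave a factor level with a single usable row spread over a collinear
  # design: all rows of one forest missing except one makes the model
  # estimable, but dropping a whole covariate's variation does not
  broken <- pt
  broken$connectance <- 0.3   # constant column -> aliased coefficient
  expect_error(anovaNetworkProperties(buildPropertyTable(broken),
                                      "rel_cscore"),
               "rank-deficient")
})

test_that("PCA of the seven descriptors matches the eigen decomposition", {
  pt <- buildPropertyTable(syntheticPropertyTable(6))
  res <- pcaNetworkProperties(pt)
  vars <- c("rel_h2prime", "rel_wnodf", "rel_cscore", "n_plants", "n_otus",
            "fungus_plant_ratio", "connectance")
  X <- scale(as.matrix(pt[, vars]))
  eig <- eigen(cor(as.matrix(pt[, vars])))
  expect_equal(res$explained_variance, eig$values / sum(eig$values),
               tolerance = 1e-9)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-9)
  expect_equal(abs(unname(res$loadings)), abs(eig$vectors), tolerance = 1e-9)

  # scores are centered and reconstruct the standardized data
  expect_equal(colMeans(res$scores), rep(0, 7), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(res$scores %*% t(res$loadings), X, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a single latent factor loads everything on PC1", {
  set.seed(9)
  latent <- rnorm(20)
  d <- data.frame(
    forest_id = sprintf("F%d", rep(1:5, 4)),
    category = rep(networkCategories()[1:4], each = 5),
    n_plants = 2 * latent + 1, n_otus = -latent,
    fungus_plant_ratio = 3 * latent, connectance = latent / 2,
    rel_h2prime = latent, rel_wnodf = -2 * latent, rel_cscore = 5 * latent,
    stringsAsFactors = FALSE
  )
  res <- pcaNetworkProperties(buildPropertyTable(d))
  expect_equal(res$explained_variance[1], 1, tolerance = 1e-9)
})

test_that("PCA sampling behaviour: independent variables give flat eigenvalues", {
  set.seed(10)
  n <- 10000
  d <- data.frame(
    forest_id = sprintf("F%06d", seq_len(n)), category = "ALL",
    n_plants = rnorm(n), n_otus = rnorm(n), fungus_plant_ratio = rnorm(n),
    connectance = rnorm(n), rel_h2prime = rnorm(n), rel_wnodf = rnorm(n),
    rel_cscore = rnorm(n), stringsAsFactors = FALSE
  )
  res <- pcaNetworkProperties(buildPropertyTable(d))
  expect_true(all(abs(res$explained_variance * 7 - 1) < 0.1))

  d$connectance <- 1
  expect_error(pcaNetworkProperties(buildPropertyTable(d)), "connectance")
})
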