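test_that("PCA matches a dense covariance eigen-decomposition oracle", {
  set.seed(30)
  arr <- array(rnorm(6 * 2 * 12), c(6, 2, 12))
  al <- gpa(arr)
  sp <- fitShapePCA(al)
  X <- t(apply(alignedCoords(al), 3, flat))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / 12, symmetric = TRUE)
  m <- length(sp@eigenvalues)
  expect_lt(max(abs(sp@eigenvalues - ev$values[1:m])), 1e-8)
  for (j in 1:m) {
    d <- min(max(abs(sp@axes[, j] - ev$vectors[, j])),
             max(abs(sp@axes[, j] + ev$vectors[, j])))
    expect_lt(d, 1e-8)
  }
  ## trace identity: total variance = mean squared deviation from consensus
  expect_equal(sum(sp@eigenvalues), mean(rowSums(Xc^2)), tolerance = 1e-10)
  ## scores are centred and reproduce the centred data with all axes
  expect_lt(max(abs(colMeans(shapeScores(sp)))), 1e-8)
  expect_lt(max(abs(shapeScores(sp) %*% t(sp@axes) - Xc)), 1e-8)
  ## percentages sum to 100 and are non-increasing
  expect_equal(sum(pctVariance(sp)), 100, tolerance = 1e-6)
  expect_false(is.unsorted(rev(pctVariance(sp))))
})

test_that("rank-1 variation loads entirely on PC1", {
  set.seed(31)
  mean_shape <- matrix(rnorm(12), 6, 2)
  v <- matrix(rnorm(12), 6, 2); v <- v / sqrt(sum(v^2))
  ## build pre-aligned rank-1 data directly (no GPA, which would distort)
  arr <- array(0, c(6, 2, 8))
  t_i <- seq(-0.1, 0.1, length.out = 8)
  for (i in 1:8) arr[, , i] <- mean_shape + t_i[i] * v
  al <- new("AlignedShapes", aligned = arr,
            mean_shape = apply(arr, c(1, 2), mean),
            centroid_sizes = rep(1, 8),
            distances = abs(t_i - mean(t_i)),
            iterations = 1L, converged = TRUE, subset = 1:6,
            ids = as.character(1:8), info = data.frame(row = 1:8))
  sp <- fitShapePCA(al)
  expect_equal(pctVariance(sp)[1], 100, tolerance = 1e-8)
  expect_equal(unname(varianceTable(sp, 1)$pct_variance), 100,
               tolerance = 1e-8)
})

test_that("projection is self-consistent and respects orthonormality", {
  set.seed(32)
  x <- simulateDataset(smallSpec(specimens = 4L))
  al <- gpa(subsetConfigs(x, view = "anterior"), subset = 4:19)
  sp <- fitShapePCA(al)
  ## projecting the training configurations reproduces stored scores
  expect_lt(max(abs(projectShapes(sp, alignedCoords(al)) -
                    shapeScores(sp))), 1e-8)
  ## projecting the mean gives zero
  expect_lt(max(abs(projectShapes(sp, meanShape(sp)))), 1e-10)
  ## mean + 2 * axis1 projects to (2, 0, ..., 0)
  cfg <- shapeAlongAxis(sp, 1, 2)
  prj <- projectShapes(sp, cfg)
  expect_equal(prj[1, 1], 2, tolerance = 1e-8)
  expect_lt(max(abs(prj[1, -1])), 1e-8)
  ## landmark-count mismatch errors
  expect_error(projectShapes(sp, matrix(0, 5, 2)), "mismatch")
})

test_that("shapeAlongAxis round-trips at observed score extremes", {
  set.seed(33)
  x <- simulateDataset(smallSpec(specimens = 4L))
  al <- gpa(subsetConfigs(x, view = "sinistral"), subset = 3:10)
  sp <- fitShapePCA(al)
  expect_equal(shapeAlongAxis(sp, 1, 0), meanShape(sp))
  for (s in range(shapeScores(sp)[, 1])) {
    prj <- projectShapes(sp, shapeAlongAxis(sp, 1, s))
    expect_equal(prj[1, 1], s, tolerance = 1e-8)
  }
  expect_error(shapeAlongAxis(sp, ncol(sp@axes) + 1, 1), "out of range")
})

test_that("combineViews joins on vertebra, drops unpaired, keeps variance", {
  set.seed(34)
  x <- simulateDataset(smallSpec(specimens = 5L))
  spaces <- lapply(c(anterior = "anterior", sinistral = "sinistral"),
                   function(v) fitShapePCA(gpa(subsetConfigs(x, view = v),
                     subset = analysisSubset(v, "precaudal"))))
  comb <- combineViews(spaces)
  expect_equal(ncol(shapeScores(comb)),
               sum(vapply(spaces, function(s) ncol(shapeScores(s)), 0L)))
  expect_equal(nrow(shapeScores(comb)), length(unique(pairKeys(x))))
  expect_equal(unique(comb@blocks), c("anterior", "sinistral"))

  ## a vertebra missing one view is dropped and logged
  drop_id <- rownames(spaces$anterior@scores)[1]
  spaces2 <- spaces
  spaces2$anterior@scores <- spaces2$anterior@scores[-1, , drop = FALSE]
  expect_message(comb2 <- combineViews(spaces2), "dropped 1")
  expect_equal(comb2@dropped, drop_id)
  expect_false(drop_id %in% rownames(shapeScores(comb2)))

  ## a second PCA on the combined table preserves total variance
  Z <- shapeScores(comb)
  Zc <- sweep(Z, 2, colMeans(Z))
  ev <- eigen(crossprod(Zc) / nrow(Z), symmetric = TRUE, only.values = TRUE)
  expect_equal(sum(ev$values), mean(rowSums(Zc^2)), tolerance = 1e-8)

  ## swapping view order permutes columns only
  comb_rev <- combineViews(rev(spaces))
  expect_equal(shapeScores(comb_rev),
               shapeScores(comb)[, c(which(comb@blocks == "sinistral"),
                                     which(comb@blocks == "anterior"))])
})

test_that("combined-view reconstruction round-trips through both blocks", {
  set.seed(35)
  x <- simulateDataset(smallSpec(specimens = 5L))
  spaces <- lapply(c(anterior = "anterior", sinistral = "sinistral"),
                   function(v) fitShapePCA(gpa(subsetConfigs(x, view = v),
                     subset = analysisSubset(v, "precaudal"))))
  comb <- combineViews(spaces)
  fit2 <- flatmorph:::.fitSecondPCA(shapeScores(comb), cum_var = 1)
  s <- 0.05
  shapes <- combinedShapeAlongAxis(spaces, comb, fit2, 1, s)
  reproj <- unlist(lapply(names(spaces), function(v)
    projectShapes(spaces[[v]], shapes[[v]])))
  z <- flatmorph:::.applySecondPCA(fit2, matrix(reproj, 1))
  expect_equal(z[1, 1], s, tolerance = 1e-6)
  expect_lt(max(abs(z[1, -1])), 1e-6)
})
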