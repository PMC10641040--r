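test_that("preshape centres, scales, and rejects degenerate input", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1))
  ps <- preshape(sq)
  expect_equal(ps$size, sqrt(8))            # hand evaluation of sqrt(sum d^2)
  expect_equal(colMeans(ps$points), c(0, 0))
  expect_equal(sqrt(sum(ps$points^2)), 1)

  ## unit-size zero-centroid input passes through unchanged
  expect_equal(preshape(ps$points)$points, ps$points)
  expect_equal(preshape(ps$points)$size, 1)

  ## translation invariance
  expect_equal(preshape(sweep(sq, 2, c(5, 7), "+"))$points, ps$points)

  expect_error(preshape(sq[1:2, ]), "insufficient")
  expect_error(preshape(matrix(1, 4, 2)), "degenerate")
})

test_that("opaAlign recovers rotations and excludes reflection", {
  set.seed(10)
  X <- preshape(matrix(rnorm(12), 6, 2))$points
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fit <- opaAlign(target = X %*% t(R), source = X)
  expect_lt(fit$residual, 1e-10)
  expect_equal(fit$angle, th, tolerance = 1e-10)

  ## asymmetric shape vs its mirror cannot align to zero without reflection
  mir <- X %*% diag(c(-1, 1))
  fit2 <- opaAlign(X, preshape(mir)$points)
  expect_gt(fit2$residual, 0.1)
  fit3 <- opaAlign(X, preshape(mir)$points, allow_reflection = TRUE)
  expect_lt(fit3$residual, 1e-10)
  expect_true(fit3$reflected)

  expect_error(opaAlign(X, X[1:4, ]), "dimension")
})

test_that("opaAlign matches a fine grid search over rotation angle", {
  set.seed(2)
  for (rep in 1:3) {
    X <- preshape(matrix(rnorm(16), 8, 2))$points
    Y <- preshape(matrix(rnorm(16), 8, 2))$points
    fit <- opaAlign(Y, X)
    grid <- seq(-pi, pi, by = 0.001 * pi / 180)
    res <- vapply(grid, function(th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sqrt(sum((X %*% t(R) - Y)^2))
    }, 0)
    expect_lt(abs(fit$residual - min(res)), 1e-6)
  }
})

test_that("GPA removes nuisance and is order/nuisance invariant", {
  set.seed(3)
  base <- matrix(rnorm(20), 10, 2)
  arr <- array(0, c(10, 2, 10))
  for (i in 1:10) {
    th <- runif(1, -pi, pi); s <- runif(1, 0.5, 2); tr <- runif(2, -5, 5)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    arr[, , i] <- sweep(s * base %*% t(R), 2, tr, "+")
  }
  al <- gpa(arr)
  expect_true(al@converged)
  expect_lt(max(procrustesDistances(al)), 1e-8)
  spread <- apply(alignedCoords(al), c(1, 2), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-8)

  ## aligned configurations have zero centroid and unit size; their mean is
  ## the stored consensus
  for (i in 1:10) {
    cfg <- alignedCoords(al)[, , i]
    expect_lt(max(abs(colMeans(cfg))), 1e-8)
    expect_equal(sqrt(sum(sweep(cfg, 2, colMeans(cfg))^2)), 1,
                 tolerance = 1e-8)
  }
  expect_equal(apply(alignedCoords(al), c(1, 2), mean), meanShape(al))
})

test_that("GPA of two distinct shapes puts them equidistant from the mean", {
  set.seed(4)
  arr <- array(rnorm(12 * 2 * 2), c(12, 2, 2))
  al <- gpa(arr)
  d <- procrustesDistances(al)
  expect_equal(d[1], d[2], tolerance = 1e-8)
})

test_that("GPA mean is invariant to input permutation", {
  set.seed(5)
  arr <- array(rnorm(8 * 2 * 15, sd = 0.1) +
                 rep(as.vector(matrix(rnorm(16), 8, 2)), 15), c(8, 2, 15))
  al1 <- gpa(arr)
  perm <- sample(15)
  al2 <- gpa(arr[, , perm])
  expect_lt(max(abs(meanShape(al1) - meanShape(al2))), 1e-10)
  expect_equal(procrustesDistances(al1), procrustesDistances(al2)[order(perm)],
               tolerance = 1e-10)
})

test_that("the consensus locally minimises summed squared distances", {
  set.seed(6)
  x <- simulateDataset(smallSpec(specimens = 4L))
  al <- gpa(subsetConfigs(x, view = "anterior"), subset = 4:19)
  m <- meanShape(al)
  ssq <- function(target) {
    tn <- preshape(target)$points
    sum(vapply(seq_len(dim(al@aligned)[3]), function(i)
      opaAlign(tn, alignedCoords(al)[, , i])$residual^2, 0))
  }
  base <- ssq(m)
  for (r in 1:10) {
    pert <- m + matrix(rnorm(length(m), sd = 1e-3), nrow(m), 2)
    expect_gte(ssq(pert), base - 1e-12)
  }
})

test_that("IQR outlier rule is one-sided, strict, and flags gross outliers", {
  expect_false(any(flagOutliers(rep(0.3, 8))))
  ## element exactly at Q3 + 1.5 IQR is not flagged (strict inequality)
  d <- c(1, 2, 3, 4, 7)   # Q3 = 4, IQR = 2, bound = 7
  expect_false(flagOutliers(d)[5])
  expect_true(flagOutliers(c(1, 2, 3, 4, 7.2))[5])
  expect_error(flagOutliers(c(1, 2, 3)), "at least 4")

  ## a configuration with one landmark displaced by 10x the shape diameter
  set.seed(7)
  base <- matrix(rnorm(16), 8, 2)
  arr <- array(rep(base, 12) + rnorm(8 * 2 * 12, sd = 0.01), c(8, 2, 12))
  arr[1, 1, 12] <- arr[1, 1, 12] + 10 * diff(range(base))
  fl <- flagOutliers(gpa(arr))
  expect_true(fl[12])
  expect_false(any(fl[1:11]))
})
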