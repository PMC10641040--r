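test_that("a well-separated training set is recalled perfectly", {
  x <- simulateDataset(smallSpec(separation = 10, specimens = 5L, seed = 50))
  model <- trainClassifier(x, "species")
  pred <- predictClassifier(model, x)
  truth <- specimenInfo(x)$species[match(pred$id, pairKeys(x))]
  expect_equal(mean(pred$label == truth), 1)
})

test_that("single-vertebra classes are removed before training", {
  x <- simulateDataset(smallSpec(taxa = c(FAA = 3L), specimens = c(4L, 4L, 1L),
                                 n_per_type = 1L, seed = 51))
  expect_message(model <- trainClassifier(x, "species"), "single-vertebra")
  expect_false("T03" %in% model@lda@classes)
  expect_true(all(c("T01", "T02") %in% model@lda@classes))
})

test_that("the across-type model uses the shared landmark subsets", {
  x <- simulateDataset(smallSpec(types = c("cervical", "precaudal", "caudal"),
                                 specimens = 3L, n_per_type = 1L, seed = 52))
  model <- trainClassifier(x, "vertebra_type")
  expect_equal(model@subsets$anterior, c(4:8, 13:19))
  expect_equal(model@subsets$sinistral, 3:10)
})

test_that("test standardisation is frozen and rigid-invariant", {
  set.seed(53)
  x <- simulateDataset(smallSpec(specimens = 6L, seed = 53))
  ids <- unique(pairKeys(x))
  train <- x[pairKeys(x) %in% ids[1:16]]
  test <- x[pairKeys(x) %in% ids[17:24]]
  model <- trainClassifier(train, "species")

  ## a training vertebra fed back as test matches its training scores
  z_train <- standardizeAndScore(model, train)
  comb_scores <- local({
    spaces <- lapply(model@views, function(v) {
      lv <- subsetConfigs(train, view = v)
      al <- gpa(lv, subset = model@subsets[[v]])
      fitShapePCA(al)
    })
    names(spaces) <- model@views
    combineViews(spaces)
  })
  z_ref <- sweep(shapeScores(comb_scores), 2, model@centre2) %*% model@rot2
  expect_lt(max(abs(z_train[rownames(z_ref), ] - z_ref)), 1e-6)

  ## rigidly transforming test configurations leaves scores unchanged
  z1 <- standardizeAndScore(model, test)
  z2 <- standardizeAndScore(model, transformSet(test))
  expect_lt(max(abs(z1 - z2)), 1e-8)

  ## missing required landmarks are reported by name
  broken <- test
  broken@present[[1]][model@subsets$anterior[1]] <- FALSE
  expect_error(standardizeAndScore(model, broken), "lacks required")
})

test_that("training statistics never leak from test items", {
  x <- simulateDataset(smallSpec(specimens = 6L, seed = 54))
  ids <- unique(pairKeys(x))
  train <- x[pairKeys(x) %in% ids[1:16]]
  m1 <- trainClassifier(train, "species")
  m2 <- trainClassifier(train, "species")   # refit: deterministic
  expect_equal(m1@lda@means, m2@lda@means)
  expect_equal(m1@centre2, m2@centre2)
  ## predictions for one test item do not depend on other test items
  test <- x[pairKeys(x) %in% ids[17:24]]
  p_all <- predictClassifier(m1, test)
  one <- test[pairKeys(test) == ids[17]]
  p_one <- predictClassifier(m1, one)
  expect_equal(p_all$posterior[p_all$id == ids[17]], p_one$posterior,
               tolerance = 1e-12)
  expect_equal(p_all$label[p_all$id == ids[17]], p_one$label)
})

test_that("bootstrap evaluation is reproducible and hits the separable limit", {
  x <- simulateDataset(smallSpec(separation = 12, specimens = 10L, seed = 55))
  r1 <- bootstrapAccuracy(x, "species", reps = 10, seed = 99)
  r2 <- bootstrapAccuracy(x, "species", reps = 10, seed = 99)
  expect_identical(r1@accuracies, r2@accuracies)
  expect_equal(r1@mean, 1)
  expect_equal(r1@sd, 0)
  ids <- unique(pairKeys(x))
  cls <- specimenInfo(x)$species[match(ids, pairKeys(x))]
  n_test_per_rep <- length(ids) - sum(ceiling(0.7 * table(cls)))
  expect_equal(sum(r1@confusion), 10 * n_test_per_rep)
  ## classes below 4 members cannot be stratified
  key_cls <- specimenInfo(x)$species[match(ids, pairKeys(x))]
  keep <- c(ids[key_cls == "T01"], ids[key_cls == "T02"][1:3])
  small <- x[pairKeys(x) %in% keep]
  expect_error(bootstrapAccuracy(small, "species", reps = 2, seed = 1),
               "too small")
})

test_that("hierarchical chaining multiplies stage accuracies", {
  ## the worked example: type then family for precaudal vertebrae
  expect_equal(round(100 * hierarchicalAccuracy(c(0.8953, 0.9569)), 2),
               85.67)
  expect_equal(hierarchicalAccuracy(c(1, 0.73)), 0.73)
  p <- c(0.9, 0.8, 0.95)
  expect_lte(hierarchicalAccuracy(p), min(p))
  expect_error(hierarchicalAccuracy(c(0.5, 1.2)), "\\[0, 1\\]")
})
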