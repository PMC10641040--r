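test_that("the generator is a deterministic function of the spec", {
  sp <- smallSpec(seed = 60)
  x1 <- simulateDataset(sp)
  x2 <- simulateDataset(sp)
  expect_identical(x1@coords, x2@coords)
  expect_identical(specimenInfo(x1), specimenInfo(x2))
  ## bit-identical TPS output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeTPS(subsetConfigs(x1, view = "anterior"), f1)
  writeTPS(subsetConfigs(x2, view = "anterior"), f2)
  expect_identical(readLines(f1), readLines(f2))
  ## templates too
  expect_identical(makeTemplates(sp), makeTemplates(sp))
})

test_that("zero separation collapses all taxa onto one template", {
  tm <- makeTemplates(smallSpec(separation = 0, seed = 61))
  tt <- tm$anterior$precaudal
  for (i in 2:length(tt)) expect_equal(tt[[i]], tt[[1]])
})

test_that("between-taxon template distance is calibrated to separation", {
  for (seed in c(62, 63)) {
    sp <- syntheticSpec(taxa_per_family = c(A = 2L, B = 2L, C = 2L,
                                            D = 2L, E = 2L),
                        specimens_per_taxon = 1L, separation = 5,
                        within_sd = 0.02, seed = seed)
    tm <- makeTemplates(sp)
    ds <- c()
    for (view in c("anterior", "sinistral"))
      for (ty in c("cervical", "precaudal", "caudal", "atlas")) {
        tt <- tm[[view]][[ty]]
        for (i in 1:9) for (j in (i + 1):10)
          ds <- c(ds, sqrt(sum((tt[[i]] - tt[[j]])^2)))
      }
    expect_lt(abs(mean(ds) - 5 * 0.02) / (5 * 0.02), 0.2)
  }
})

test_that("with noise and nuisance off, configurations equal their template", {
  sp <- smallSpec(within_sd = 0, specimens = 2L, seed = 64,
                  rotation_range = c(0, 0), translation_range = c(0, 0),
                  scale_range = c(1, 1))
  x <- simulateDataset(sp)
  tm <- makeTemplates(sp)
  i <- which(specimenInfo(x)$view == "anterior")[1]
  taxon <- specimenInfo(x)$species[i]
  expect_equal(x@coords[[i]], tm$anterior$precaudal[[taxon]],
               tolerance = 1e-12)
})

test_that("GPA on one taxon recovers its template shape", {
  sp <- smallSpec(taxa = c(FAA = 1L), specimens = 20L, within_sd = 0.02,
                  seed = 65)
  x <- simulateDataset(sp)
  al <- gpa(subsetConfigs(x, view = "anterior"))
  tm <- makeTemplates(sp)$anterior$precaudal[["T01"]]
  fit <- opaAlign(meanShape(al) / sqrt(sum(meanShape(al)^2)),
                  preshape(tm)$points)
  n <- dim(alignedCoords(al))[3]
  expect_lt(max(abs(fit$aligned - meanShape(al) /
                      sqrt(sum(meanShape(al)^2)))),
            3 * 0.02 / sqrt(n))
})

test_that("mirror forms are x-negated copies detectable by alignment", {
  sp <- smallSpec(taxa = c(FAA = 1L), specimens = 4L, within_sd = 0,
                  mirror_fraction = 0.5, seed = 66)
  x <- simulateDataset(sp)
  info <- specimenInfo(x)
  expect_setequal(unique(info$form), c("mirror", "normal"))
  i_m <- which(info$form == "mirror" & info$view == "anterior")[1]
  i_n <- which(info$form == "normal" & info$view == "anterior")[1]
  pm <- preshape(x@coords[[i_m]])$points
  pn <- preshape(x@coords[[i_n]])$points
  ## no rotation aligns a mirror onto a normal form...
  expect_gt(opaAlign(pn, pm)$residual, 0.1)
  ## ...but allowing reflection aligns them exactly (within_sd = 0)
  expect_lt(opaAlign(pn, pm, allow_reflection = TRUE)$residual, 1e-8)
})

test_that("structural cervical landmarks are emitted as missing", {
  x <- simulateDataset(smallSpec(types = "cervical", specimens = 2L,
                                 seed = 67))
  ant <- which(specimenInfo(x)$view == "anterior")
  absent <- landmarkScheme("anterior", "cervical")$cervical_absent
  for (i in ant) {
    expect_false(any(x@present[[i]][absent]))
    expect_true(all(x@present[[i]][-absent]))
  }
})

test_that("degradation drops landmarks as specified", {
  x <- simulateDataset(smallSpec(specimens = 10L, seed = 68))
  ## p_loss = 0: only provenance changes
  d0 <- degradeDataset(x, p_loss = 0, seed = 1)
  expect_identical(d0@coords, x@coords)
  expect_identical(d0@present, x@present)
  expect_true(all(specimenInfo(d0)$provenance == "archaeological"))
  ## p_loss = 1: everything gone, identification impossible
  d1 <- degradeDataset(x, p_loss = 1, seed = 1)
  expect_true(all(!unlist(d1@present)))
  expect_error(identifySample(d1[pairKeys(d1) == pairKeys(d1)[1]], x),
               "insufficient landmarks")
  ## tip-biased loss hits tip landmarks at a higher realised rate
  db <- degradeDataset(x, "tip_biased", p_loss = 0.3, seed = 2)
  tips <- landmarkScheme("anterior", "precaudal")$tips
  ant <- which(specimenInfo(x)$view == "anterior")
  tip_lost <- unlist(lapply(ant, function(i) !db@present[[i]][tips]))
  non_lost <- unlist(lapply(ant, function(i) !db@present[[i]][-tips]))
  p_tip <- mean(tip_lost); p_non <- mean(non_lost)
  se <- sqrt(p_tip * (1 - p_tip) / length(tip_lost) +
             p_non * (1 - p_non) / length(non_lost))
  expect_gt(p_tip - p_non, 3 * se)
})

test_that("generated datasets survive a TPS round trip without loss", {
  x <- simulateDataset(smallSpec(types = c("precaudal", "cervical"),
                                 specimens = 2L, seed = 69))
  for (view in c("anterior", "sinistral")) {
    f <- withr::local_tempfile(fileext = ".tps")
    xv <- subsetConfigs(x, view = view)
    writeTPS(xv, f)
    y <- readTPS(f)
    expect_identical(y@present, xv@present)
    expect_identical(specimenInfo(y)$species, specimenInfo(xv)$species)
    expect_identical(specimenInfo(y)$vertebra, specimenInfo(xv)$vertebra)
    for (i in seq_along(y@coords)) {
      p <- xv@present[[i]]
      expect_lt(max(abs(y@coords[[i]][p, ] - xv@coords[[i]][p, ])), 1e-4)
    }
  }
})
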