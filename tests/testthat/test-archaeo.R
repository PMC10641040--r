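test_that("usableLandmarks intersects presence with the analysis subset", {
  x <- simulateDataset(smallSpec(specimens = 2L, seed = 70))
  i <- which(specimenInfo(x)$view == "anterior")[1]
  ## fully present anterior precaudal at species level: 4..19
  expect_equal(usableLandmarks(x, i, "species"), 4:19)
  ## arch tips are excluded even when present
  expect_true(all(x@present[[i]][1:3]))
  ## missing landmarks leave the mask
  x@present[[i]][c(6, 14)] <- FALSE
  expect_equal(usableLandmarks(x, i, "species"), setdiff(4:19, c(6, 14)))
  ## everything missing: empty set
  x@present[[i]][] <- FALSE
  expect_length(usableLandmarks(x, i, "species"), 0)
})

test_that("a complete well-separated sample is identified along the chain", {
  sp <- smallSpec(types = c("cervical", "precaudal", "caudal"),
                  specimens = 4L, n_per_type = 1L, separation = 10,
                  type_effect = 10, seed = 71)
  x <- simulateDataset(sp)
  ref <- x
  key <- unique(pairKeys(x))[5]
  smp <- x[pairKeys(x) == key]
  truth <- specimenInfo(smp)
  res <- identifySample(smp, ref, mode = "full_chain")
  expect_equal(res@decisions$level,
               c("vertebra_type", "family", "species"))
  expect_equal(res@decisions$label[1], truth$vertebra[1])
  expect_equal(res@decisions$label[2], truth$family[1])
  expect_equal(res@decisions$label[3], truth$species[1])
  expect_true(all(res@decisions$posterior > 0.95))
  expect_equal(res@chained_posterior, prod(res@decisions$posterior))

  ## given_type agrees with full_chain when the type was predicted right
  res2 <- identifySample(smp, ref, mode = "given_type")
  expect_equal(res2@decisions$label, res@decisions$label[2:3])

  ## identification is deterministic
  res3 <- identifySample(smp, ref, mode = "full_chain")
  expect_identical(res3@decisions, res@decisions)
})

test_that("landmarks absent from the sample are removed from references", {
  x <- simulateDataset(smallSpec(specimens = 4L, separation = 10,
                                 seed = 72))
  key <- unique(pairKeys(x))[1]
  smp <- x[pairKeys(x) == key]
  i <- which(specimenInfo(smp)$view == "anterior")
  smp@present[[i]][7] <- FALSE
  smp@coords[[i]][7, ] <- NA
  res <- identifySample(smp, x[pairKeys(x) != key], mode = "given_type")
  expect_false(7 %in% res@landmarks_used$anterior)
  expect_true(all(res@landmarks_used$anterior %in%
                    which(smp@present[[i]])))
})

test_that("samples below the landmark minimum are unidentifiable", {
  x <- simulateDataset(smallSpec(specimens = 4L, seed = 73))
  key <- unique(pairKeys(x))[1]
  smp <- x[pairKeys(x) == key]
  for (i in 1:2) {             # keep only 2 landmarks in each view
    smp@present[[i]][] <- FALSE
    smp@present[[i]][5:6] <- TRUE
  }
  expect_error(identifySample(smp, x[pairKeys(x) != key]),
               "insufficient landmarks")
  ## a batch keeps running and flags the failure
  batch <- c(smp, x[pairKeys(x) == unique(pairKeys(x))[2]])
  res <- identifyBatch(batch, x[!(pairKeys(x) %in% pairKeys(batch))])
  expect_equal(nrow(res), 2)
  expect_match(res$flags[1], "unidentifiable")
  expect_false(is.na(res$species[2]))
})

test_that("a view with too few landmarks is dropped, not fatal", {
  x <- simulateDataset(smallSpec(specimens = 4L, separation = 10,
                                 seed = 74))
  key <- unique(pairKeys(x))[3]
  smp <- x[pairKeys(x) == key]
  i <- which(specimenInfo(smp)$view == "anterior")
  smp@present[[i]][] <- FALSE           # anterior view unusable
  res <- identifySample(smp, x[pairKeys(x) != key], mode = "given_type")
  expect_equal(res@views_used, "sinistral")
  expect_true(any(grepl("view_dropped:anterior", res@flags)))
  expect_true(any(grepl("single_view_only", res@flags)))
})

test_that("the chain truncates when a family has too few species", {
  ## reference with one family containing a single species
  sp <- smallSpec(taxa = c(FAA = 1L, FAB = 2L), specimens = 4L,
                  separation = 10, seed = 75)
  x <- simulateDataset(sp)
  ## sample from the single-species family FAA
  faa_keys <- unique(pairKeys(x)[specimenInfo(x)$family == "FAA"])
  smp <- x[pairKeys(x) == faa_keys[1]]
  res <- identifySample(smp, x[pairKeys(x) != faa_keys[1]],
                        mode = "given_type")
  expect_equal(res@decisions$level, "family")
  expect_true(any(grepl("chain_truncated_at_species", res@flags)))
})
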