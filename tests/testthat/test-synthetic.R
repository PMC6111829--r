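test_that("surface clouds are deterministic, on-surface and head-sized", {
  a <- makeSurfaceCloud("head_ellipsoid", 1000, seed = 5)
  b <- makeSurfaceCloud("head_ellipsoid", 1000, seed = 5)
  expect_identical(coords(a), coords(b))
  c_ <- makeSurfaceCloud("head_ellipsoid", 1000, seed = 6)
  expect_false(identical(coords(a), coords(c_)))
  # every sampled point satisfies the implicit surface equation
  expect_lt(max(abs(iicp:::.surfaceResidual(coords(a), "head_ellipsoid"))),
            1e-9)
  rng <- apply(coords(a), 2, function(v) diff(range(v)))
  expect_true(all(rng > c(170, 130, 150)) && all(rng < c(260, 210, 240)))
  # five uniquely-labelled markers at the bump apexes
  expect_equal(nrow(markers(a)), 5L)
  expect_false(anyDuplicated(markers(a)$label) > 0)
})

test_that("registration cases honour their construction contract", {
  case <- makeRegistrationCase("head_ellipsoid", nReference = 500,
                               nFloating = 150, rotationDeg = c(20, 10, 15),
                               translationMm = c(30, 20, 10),
                               noiseSigmaMm = 0, outlierFraction = 0,
                               overlapFraction = 1, seed = 8)
  # noise-free full-overlap floating points map exactly onto reference points
  back <- coords(applyTransform(case@groundTruth, case@floating))
  nn <- bruteForceNN(back, coords(case@reference))
  expect_lt(max(nn$distance), 1e-9)
  # ground-truth residual via the weighted objective
  cs <- nearestCorrespondences(back, coords(case@reference))
  w <- assignWeights(cs@distance, sortedMedian(cs@distance))
  expect_lt(weightedRMS(cs@distance, w), 1e-9)
  # markers correspond one-to-one by label across frames
  expect_setequal(markers(case@floating)$label,
                  markers(case@reference)$label)
})

test_that("identity-displacement noise-free cases are subsets of the reference", {
  case <- makeRegistrationCase("head_ellipsoid", nReference = 400,
                               nFloating = 100, rotationDeg = c(0, 0, 0),
                               translationMm = c(0, 0, 0),
                               noiseSigmaMm = 0, outlierFraction = 0,
                               overlapFraction = 1, seed = 2)
  nn <- bruteForceNN(coords(case@floating), coords(case@reference))
  expect_lt(max(nn$distance), 1e-12)
})

test_that("half-space cropping keeps floating points in the cut region", {
  case <- makeRegistrationCase("head_ellipsoid", nReference = 1000,
                               nFloating = 200, rotationDeg = c(10, 0, 0),
                               translationMm = c(10, 0, 0),
                               noiseSigmaMm = 0, outlierFraction = 0,
                               overlapFraction = 0.5, seed = 13)
  back <- coords(applyTransform(case@groundTruth, case@floating))
  # every mapped floating point is one of the kept reference points, and
  # those span at most the cropped half of the reference cloud
  nn <- bruteForceNN(back, coords(case@reference))
  expect_lt(max(nn$distance), 1e-9)
  expect_lte(length(unique(nn$index)), 500)
})

test_that("additive noise matches its nominal sigma", {
  sig <- 1.0
  case <- makeRegistrationCase("head_ellipsoid", nReference = 15000,
                               nFloating = 10000, rotationDeg = c(0, 0, 0),
                               translationMm = c(0, 0, 0),
                               noiseSigmaMm = sig, outlierFraction = 0,
                               overlapFraction = 1, seed = 17)
  # with identity ground truth the displacement from the generating point
  # (recorded by index in the generator echo) is pure noise
  gen <- coords(case@reference)[case@generatorParams$sampleIndices, ]
  resid <- coords(case@floating) - gen
  sds <- apply(resid, 2, sd)
  expect_true(all(abs(sds - sig) / sig < 0.1))
})

test_that("generator rejects out-of-domain parameters", {
  expect_error(makeRegistrationCase(overlapFraction = 1.5, seed = 1),
               "overlapFraction")
  expect_error(makeRegistrationCase(outlierFraction = 0.7, seed = 1),
               "outlierFraction")
  expect_error(makeRegistrationCase(nReference = 200, nFloating = 190,
                                    overlapFraction = 0.5, seed = 1),
               "not enough points")
})

test_that("case directories round-trip through the standard file layout", {
  case <- makeRegistrationCase("bumpy_sphere", nReference = 200,
                               nFloating = 60, rotationDeg = c(10, 5, 0),
                               translationMm = c(5, 5, 5),
                               noiseSigmaMm = 0.5, outlierFraction = 0,
                               overlapFraction = 0.9, seed = 3)
  dir <- file.path(tempdir(), "case-rt")
  writeRegistrationCase(case, dir)
  expect_true(all(file.exists(file.path(dir,
    c("reference.ply", "floating.ply", "ground_truth.json", "markers.csv",
      "params.json")))))
  back <- readRegistrationCase(dir)
  expect_identical(unname(coords(back@reference)),
                   unname(coords(case@reference)))
  expect_identical(unname(coords(back@floating)),
                   unname(coords(case@floating)))
  expect_lt(max(abs(asMatrix(back@groundTruth) -
                    asMatrix(case@groundTruth))), 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("the local-minimum fixture is certified at generation", {
  fix <- localMinimumFixture(seed = 1)
  expect_gt(fix@generatorParams$icpRotationErrorDeg, 10)
  # re-running classic ICP reproduces the certified failure
  res <- registerICP(fix@floating, fix@reference,
                     registrationConfig(
                       seed = fix@generatorParams$acceptedSeed))
  expect_gt(rotationAngle(resultTransform(res), fix@groundTruth), 10)
  # deterministic regeneration
  fix2 <- localMinimumFixture(seed = 1)
  expect_identical(coords(fix2@floating), coords(fix@floating))
})
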