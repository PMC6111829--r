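test_that("noise-free rigid estimation recovers known transforms", {
  ref <- coords(smallCloud(20, seed = 2))
  # identity
  est0 <- estimateRigidTransform(ref, ref)
  expect_lt(max(abs(rotation(est0) - diag(3))), 1e-9)
  expect_lt(max(abs(translation(est0))), 1e-9)
  # 30 degrees about Z plus a translation
  tf <- fromParameters(c(0, 0, 30 * pi / 180, 10, 0, 0))
  flo <- applyTransform(invertTransform(tf), ref)
  est <- estimateRigidTransform(flo, ref)
  expect_lt(max(abs(rotation(est) - rotation(tf))), 1e-9)
  expect_lt(max(abs(translation(est) - translation(tf))), 1e-9)
})

test_that("weighted estimate is locally optimal against random search", {
  set.seed(4)
  ref <- matrix(rnorm(60, sd = 30), 20, 3)
  tf <- randomRigidTransform()
  flo <- applyTransform(invertTransform(tf), PointCloud(ref))
  flo <- coords(flo) + matrix(rnorm(60, sd = 0.5), 20, 3)
  w <- runif(20, 0.1, 1)
  est <- estimateRigidTransform(flo, ref, w)
  obj <- function(tr) {
    moved <- applyTransform(tr, flo)
    sum(w * rowSums((moved - ref)^2))
  }
  o0 <- obj(est)
  p0 <- toParameters(est)
  for (i in 1:1000) {
    p <- p0 + rnorm(6, sd = c(rep(0.02, 3), rep(0.2, 3)))
    expect_gte(obj(fromParameters(p)), o0 - 1e-9)
  }
})

test_that("estimation is invariant to uniform weight rescaling and never reflects", {
  set.seed(6)
  ref <- matrix(rnorm(45, sd = 20), 15, 3)
  flo <- matrix(rnorm(45, sd = 20), 15, 3)
  w <- runif(15, 0.2, 2)
  e1 <- estimateRigidTransform(flo, ref, w)
  e2 <- estimateRigidTransform(flo, ref, w * 137.5)
  expect_equal(rotation(e1), rotation(e2), tolerance = 1e-12)
  expect_equal(det(rotation(e1)), 1, tolerance = 1e-9)
  # mirrored target would need a reflection; the estimator must not return one
  e3 <- estimateRigidTransform(flo, ref * cbind(-1, 1, 1)[rep(1, 15), ])
  expect_equal(det(rotation(e3)), 1, tolerance = 1e-9)
})

test_that("collinear geometry raises a degenerate-geometry error", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(estimateRigidTransform(line, line), "degenerate geometry")
  expect_error(estimateRigidTransform(line[1:2, ], line[1:2, ]),
               "at least 3")
})

test_that("applyTransform is an isometry and moves markers along", {
  pc <- PointCloud(coords(smallCloud(15, 3)),
                   markers = data.frame(label = "m", x = 1, y = 2, z = 3))
  expect_equal(coords(applyTransform(rigidTransform(), pc)), coords(pc))
  moved <- applyTransform(rigidTransform(diag(3), c(1, 2, 3)),
                          PointCloud(rbind(c(0, 0, 0))))
  expect_equal(unname(coords(moved)), rbind(c(1, 2, 3)))
  set.seed(8)
  tf <- randomRigidTransform()
  out <- applyTransform(tf, pc)
  d0 <- dist(coords(pc))
  expect_equal(as.vector(dist(coords(out))), as.vector(d0),
               tolerance = 1e-9)
  expect_equal(unname(as.matrix(markers(out)[, c("x", "y", "z")])),
               unname(applyTransform(tf, rbind(c(1, 2, 3)))))
})

test_that("composition and inversion satisfy the group laws", {
  set.seed(10)
  tf <- randomRigidTransform()
  id <- rigidTransform()
  expect_equal(asMatrix(composeTransforms(tf, id)), asMatrix(tf))
  expect_lt(max(abs(asMatrix(composeTransforms(tf, invertTransform(tf))) -
                    diag(4))), 1e-9)
  t2 <- randomRigidTransform()
  expect_equal(asMatrix(composeTransforms(t2, tf)),
               asMatrix(t2) %*% asMatrix(tf), tolerance = 1e-12)
  p <- rnorm(3)
  expect_equal(as.vector(applyTransform(composeTransforms(t2, tf),
                                        rbind(p))),
               as.vector(applyTransform(t2, applyTransform(tf, rbind(p)))),
               tolerance = 1e-9)
})

test_that("parameter view round-trips away from gimbal lock", {
  expect_equal(unname(toParameters(rigidTransform())), rep(0, 6))
  p <- c(50, 50, 50) * pi / 180
  tf <- fromParameters(c(p, 1, 2, 3))
  expect_equal(unname(toParameters(tf)), c(p, 1, 2, 3), tolerance = 1e-9)
  set.seed(12)
  for (i in 1:50) {
    pr <- c(runif(3, -pi + 0.01, pi - 0.01), runif(3, -100, 100))
    pr[2] <- runif(1, -pi / 2 + 0.05, pi / 2 - 0.05)  # stay off the lock
    expect_equal(unname(toParameters(fromParameters(pr))), pr,
                 tolerance = 1e-9)
  }
  # pure translation of norm 200 mm along the diagonal
  tf200 <- fromParameters(c(0, 0, 0, rep(200 / sqrt(3), 3)))
  expect_equal(rotation(tf200), diag(3))
  expect_equal(sqrt(sum(translation(tf200)^2)), 200, tolerance = 1e-12)
  # gimbal lock raises
  expect_error(toParameters(fromParameters(c(0, pi / 2, 0, 0, 0, 0))),
               "gimbal")
})

test_that("transform difference matches a small-angle rotation-vector oracle", {
  expect_equal(transformDifference(rigidTransform(), rigidTransform()),
               rep(0, 6))
  t10 <- fromParameters(c(10 * pi / 180, 0, 0, 0, 0, 0))
  expect_equal(transformDifference(rigidTransform(), t10),
               c(10 * pi / 180, 0, 0, 0, 0, 0), tolerance = 1e-12)
  # for small rotations the parameter difference approximates the
  # rotation-vector (matrix-log) difference componentwise
  set.seed(14)
  for (i in 1:20) {
    v1 <- rnorm(3, sd = 3e-4)
    v2 <- rnorm(3, sd = 3e-4)
    t1 <- fromParameters(c(v1, rnorm(3)))
    t2 <- fromParameters(c(v2, rnorm(3)))
    g <- transformDifference(t1, t2)
    R <- rotation(t1) %*% t(rotation(t2))
    logvec <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
    expect_lt(max(abs(g[1:3] - abs(logvec))), 1e-6)
  }
  # angle wrap: 179 vs -179 degrees differ by 2, not 358
  ta <- fromParameters(c(179 * pi / 180, 0, 0, 0, 0, 0))
  tb <- fromParameters(c(-179 * pi / 180, 0, 0, 0, 0, 0))
  expect_equal(transformDifference(ta, tb)[1], 2 * pi / 180,
               tolerance = 1e-9)
})
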