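# Shared helpers: independent oracles and small generated fixtures.

# Brute-force exhaustive nearest neighbour (the oracle the KD-tree is
# checked against); O(N_F * N_R), ties broken by smallest reference index
# via which.min.
bruteForceNN <- function(floating, reference) {
  idx <- integer(nrow(floating))
  dist <- numeric(nrow(floating))
  for (i in seq_len(nrow(floating))) {
    d2 <- colSums((t(reference) - floating[i, ])^2)
    idx[i] <- which.min(d2)
    dist[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dist)
}

# A random proper rotation via QR of a Gaussian matrix.
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

randomRigidTransform <- function(maxTrans = 50) {
  rigidTransform(randomRotation(), runif(3, -maxTrans, maxTrans))
}

# A small non-degenerate test cloud.
smallCloud <- function(n = 25, seed = 1) {
  set.seed(seed)
  PointCloud(matrix(rnorm(3 * n, sd = 20), n, 3))
}
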