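# Shared fixtures. The heptamer is the workhorse molecule; topologies are
# memoised because construction is pure.

.fixture_env <- new.env(parent = emptyenv())

heptamer_topology <- function() {
  if (is.null(.fixture_env$hepta))
    .fixture_env$hepta <- parse_sequence(
      "Boc-Ala-Val~[4Tz]Phe-Leu~[4Tz]Phe-Leu~[4Tz]Val-OAll")
  .fixture_env$hepta
}

gly_topology <- function() {
  if (is.null(.fixture_env$gly))
    .fixture_env$gly <- parse_sequence("Boc-Gly-Gly~[4Tz]Gly-OAll")
  .fixture_env$gly
}

random_torsions <- function(topology) {
  n <- nrow(topology$residues)
  torsion_state(topology$residues$position_index,
                runif(n, -179.9, 180), runif(n, -179.9, 180))
}

# independent dihedral oracle (praxeolitic projection formula)
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(cross3(b1, v) * w), sum(v * w)) * 180 / pi
}

# independent superposition-RMSD oracle: Horn's closed-form quaternion method
# (max eigenvalue of the 4x4 key matrix; proper rotations only)
oracle_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  S <- t(P) %*% Q
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  sqrt(max(0, sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P))
}

# independent radius-of-gyration oracle: literal formula, explicit loop
oracle_rog <- function(x, w = rep(1, nrow(x))) {
  ctr <- c(0, 0, 0)
  for (i in seq_len(nrow(x))) ctr <- ctr + w[i] * x[i, ]
  ctr <- ctr / sum(w)
  s <- 0
  for (i in seq_len(nrow(x))) s <- s + w[i] * sum((x[i, ] - ctr)^2)
  sqrt(s / sum(w))
}

# independent average-linkage clusterer (greedy merge of the closest cluster
# pair by mean cross-distance), used as the dual route against stats::hclust
oracle_average_linkage <- function(D, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  labels
}

# random rigid motion
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1-2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
    2*(q[2]*q[3]+q[1]*q[4]), 1-2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
    2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1-2*(q[2]^2+q[3]^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 5))
}
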