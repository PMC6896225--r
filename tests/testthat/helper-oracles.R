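# Independent oracles used by the test suite. Each deliberately avoids the
# code path it checks.

# Brute-force minimal-RMSD search over rotations: coarse 10-degree Euler
# grid (zyz), then hierarchical halving refinement of the best candidate
# basins down to <1e-3 rad. Translation is handled by centroid alignment,
# optimal for any fixed rotation. Returns RMSD in Angstrom.
oracleGridRmsd <- function(mobile, reference, nSeeds = 8) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  score <- function(a, b, g) {
    R <- Rz(a) %*% Ry(b) %*% Rz(g)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  step0 <- 10 * pi / 180
  grid <- expand.grid(a = seq(-pi, pi - step0, by = step0),
                      b = seq(0, pi, by = step0),
                      g = seq(-pi, pi - step0, by = step0))
  vals <- mapply(score, grid$a, grid$b, grid$g)
  seeds <- grid[order(vals)[seq_len(nSeeds)], ]
  bestV <- Inf
  for (s in seq_len(nSeeds)) {
    best <- unlist(seeds[s, ])
    v0 <- score(best[1], best[2], best[3])
    step <- step0
    while (step > 5e-4) {
      step <- step / 2
      cand <- expand.grid(a = best[1] + (-2:2) * step,
                          b = best[2] + (-2:2) * step,
                          g = best[3] + (-2:2) * step)
      for (i in seq_len(nrow(cand))) {
        v <- score(cand[i, 1], cand[i, 2], cand[i, 3])
        if (v < v0) {
          v0 <- v
          best <- unlist(cand[i, ])
        }
      }
    }
    bestV <- min(bestV, v0)
  }
  10 * bestV
}

# Winding-number (angle-summation) point-in-polygon oracle, independent of
# the crossing-number implementation. Points on the boundary are treated
# as inside (angle sum becomes +/- pi at an edge; we accept |sum| > pi/2).
oracleWindingInside <- function(pts, poly) {
  vapply(seq_len(nrow(pts)), function(i) {
    dx <- poly[, 1] - pts[i, 1]
    dy <- poly[, 2] - pts[i, 2]
    if (any(dx^2 + dy^2 < 1e-18)) return(TRUE)  # on a vertex
    th <- atan2(dy, dx)
    dth <- diff(c(th, th[1]))
    dth <- (dth + pi) %% (2 * pi) - pi
    abs(sum(dth)) > pi / 2
  }, logical(1))
}

# Central-difference gradient of the total potential; checks the analytic
# forces of the compiled core.
oracleNumericForces <- function(system, reference, kBias, params,
                                h = 1e-6) {
  n <- nrow(coords(system))
  g <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    s2 <- system
    x <- coords(system)
    x[i, d] <- x[i, d] + h
    coords(s2) <- x
    up <- computePotential(s2, reference, kBias, params)
    x[i, d] <- x[i, d] - 2 * h
    coords(s2) <- x
    um <- computePotential(s2, reference, kBias, params)
    g[i, d] <- -(up - um) / (2 * h)
  }
  g
}

# Plain double-loop Pearson correlation (direct summation).
oracleDirectPearson <- function(a, b) {
  am <- mean(a)
  bm <- mean(b)
  num <- 0
  da <- 0
  db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - am) * (b[i] - bm)
    da <- da + (a[i] - am)^2
    db <- db + (b[i] - bm)^2
  }
  num / sqrt(da * db)
}
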