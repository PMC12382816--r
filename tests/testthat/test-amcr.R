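# AMCR regularizer: pair rules, density weighting, repulsion, loss.

test_that("label_dist is the Manhattan distance on standardized labels", {
  expect_equal(label_dist(c(0, 0), c(0, 0)), 0)
  expect_equal(label_dist(c(0, 0), c(1, 2)), 3)
  expect_equal(label_dist(c(0.5, -0.5), c(-0.5, 0.5)), 2)
  expect_equal(label_dist(c(1, 2), c(0, 0)), label_dist(c(0, 0), c(1, 2)))
})

test_that("a lone two-view pair yields mutual positives and no anchors", {
  z <- unit_rows(matrix(rnorm(4), 2, 2))
  y <- matrix(c(0.3, 0.3, -0.2, -0.2), 2, 2)
  b <- embedding_batch(z, y_hat = y, y = y)
  a <- assign_pairs(b, omega = 1)
  expect_equal(a$Kplus[[1]], 2L)
  expect_equal(a$Kplus[[2]], 1L)
  expect_equal(lengths(a$Kminus), c(0L, 0L))
  expect_false(any(a$is_anchor))
})

test_that("pair rules follow the label/prediction decision table", {
  # two source images (4 views); image B's labels are far from image A's
  z <- unit_rows(matrix(rnorm(8), 4, 2))
  y <- rbind(c(0, 0), c(0, 0), c(2, 1), c(2, 1))
  # predictions erroneously similar across the pair -> negatives
  yh <- rbind(c(0, 0), c(0, 0), c(0.4, 0.3), c(0.4, 0.3))
  b <- embedding_batch(z, yh, y)
  a <- assign_pairs(b, omega = 1)
  expect_true(3L %in% a$Kminus[[1]])
  expect_true(1L %in% a$Kminus[[3]])
  expect_true(all(a$is_anchor))
  # dissimilar predictions -> no pair at all
  yh2 <- rbind(c(0, 0), c(0, 0), c(1.5, 1.0), c(1.5, 1.0))
  a2 <- assign_pairs(embedding_batch(z, yh2, y), omega = 1)
  expect_equal(lengths(a2$Kminus), rep(0L, 4))
  expect_equal(a2$Kplus[[1]], 2L)   # sibling only
  # structural guards
  expect_error(embedding_batch(z[1:3, ], yh[1:3, ], y[1:3, ]), "even")
  expect_error(embedding_batch(z * 2, yh, y), "unit")
})

test_that("density weights invert the label histogram", {
  # uniform occupancy: one label per cell -> all weights 1
  centers <- seq(-0.9, 0.9, length.out = 10)
  grid <- as.matrix(expand.grid(centers, centers))
  d_uni <- fit_density(grid, bins = 10)
  expect_equal(d_uni$d, rep(1, nrow(grid)), tolerance = 1e-12)
  expect_equal(d_uni$eta, d_uni$d * 1.0)
  # 90/10 clusters: raw inverse densities are ~9x apart
  y2 <- rbind(matrix(rep(c(0, 0), 90), ncol = 2, byrow = TRUE),
              matrix(rep(c(5, 5), 10), ncol = 2, byrow = TRUE))
  dm <- fit_density(y2, bins = 4)
  d_major <- dm$d[1]; d_minor <- dm$d[100]
  expect_equal(d_minor / d_major, 0.9 / 0.1, tolerance = 0.05)
  expect_equal(mean(dm$d), 1, tolerance = 1e-12)
  # eta scales with eta0
  dm2 <- fit_density(y2, bins = 4, eta0 = 2)
  expect_equal(dm2$eta, 2 * dm2$d)
  expect_warning(fit_density(matrix(1, 5, 2)), "identical")
})

test_that("repulsion weights grow with label dissimilarity and eta", {
  z <- unit_rows(matrix(rnorm(8), 4, 2))
  y <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))     # dist 2 = 2*omega
  yh <- matrix(0, 4, 2)
  b <- embedding_batch(z, yh, y)
  a <- assign_pairs(b, omega = 1)
  S1 <- repulsion_weights(a, rep(1, 4), y, omega = 1)
  expect_equal(S1$S[S1$j == 1 & S1$q == 3], 2)   # eta * dist / omega
  expect_true(all(S1$S > 1))                     # S > eta for negatives
  S2 <- repulsion_weights(a, rep(2, 4), y, omega = 1)
  expect_equal(S2$S, 2 * S1$S)                   # proportional to eta
  # monotone in distance at fixed eta
  y3 <- rbind(c(0, 0), c(0, 0), c(3, 1), c(3, 1))
  a3 <- assign_pairs(embedding_batch(z, yh, y3), omega = 1)
  S3 <- repulsion_weights(a3, rep(1, 4), y3, omega = 1)
  expect_gt(S3$S[1], S1$S[1])
  # capped at s_max
  S4 <- repulsion_weights(a3, rep(10, 4), y3, omega = 1, s_max = 10)
  expect_true(all(S4$S <= 10))
})

test_that("hand-built single-anchor loss matches -log(e/(e+2))", {
  z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, -1))
  y <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  # only view 3 collapses onto the anchor's prediction
  yh <- rbind(c(0, 0), c(3, 3), c(0.1, 0), c(9, 9))
  b <- embedding_batch(z, yh, y)
  a <- assign_pairs(b, omega = 1)
  expect_equal(a$Kminus[[1]], 3L)
  S <- matrix(0, 4, 4); S[1, 3] <- 2
  out <- amcr_loss(b, a, S, tau = 1)
  expect_equal(out$per_sample[1], -log(exp(1) / (exp(1) + 2)),
               tolerance = 1e-6)
  expect_equal(out$per_sample[2], 0)   # non-anchor contributes exactly zero
})

test_that("zero-anchor batches give exactly zero loss", {
  b <- random_batch(6, seed = 3, collapse_frac = 0, label_spread = 0.01)
  a <- assign_pairs(b, omega = 5)      # everything label-similar
  expect_false(any(a$is_anchor))
  S <- repulsion_weights(a, rep(1, 12), b$y, omega = 5)
  out <- amcr_loss(b, a, S, tau = 0.2)
  expect_identical(out$total, 0)
  expect_identical(out$per_sample, rep(0, 12))
})

test_that("high-temperature limit reaches its closed form", {
  b <- random_batch(5, seed = 11, collapse_frac = 0.8)
  a <- assign_pairs(b, omega = 1)
  stopifnot(any(a$is_anchor))
  S <- repulsion_weights(a, rep(1.3, 10), b$y, omega = 1)
  out <- amcr_loss(b, a, S, tau = 1e6)
  Sm <- morphoreg:::repulsion_dense(S, 10)
  j <- which(a$is_anchor)[1]
  npos <- length(a$Kplus[[j]])
  ssum <- sum(Sm[j, a$Kminus[[j]]])
  expect_equal(out$per_sample[j], log(npos + ssum) - log(npos),
               tolerance = 1e-4)
})

test_that("vectorized loss matches the double-loop reference", {
  set.seed(123)
  for (seed in 1:30) {
    np <- sample(2:16, 1)
    b <- random_batch(np, seed = seed, collapse_frac = runif(1, 0.2, 0.9))
    omega <- runif(1, 0.5, 1.5)
    tau <- runif(1, 0.1, 1)
    eta <- runif(2 * np, 0.5, 2)
    a <- assign_pairs(b, omega)
    S <- repulsion_weights(a, eta, b$y, omega)
    got <- amcr_loss(b, a, S, tau)
    ref <- amcr_reference(b$z, b$y, b$y_hat, omega, tau, eta)
    expect_equal(got$total, ref$total, tolerance = 1e-6)
    expect_equal(got$per_sample, ref$per_sample, tolerance = 1e-6)
  }
})

test_that("total loss is invariant under batch permutation", {
  set.seed(7)
  b <- random_batch(8, seed = 21, collapse_frac = 0.6)
  a <- assign_pairs(b, 1)
  eta <- runif(16, 0.5, 2)
  S <- repulsion_weights(a, eta, b$y, 1)
  t0 <- amcr_loss(b, a, S, 0.2)$total
  # permute sibling pairs as units
  perm_pairs <- sample(8)
  idx <- as.vector(rbind(2 * perm_pairs - 1, 2 * perm_pairs))
  b2 <- embedding_batch(b$z[idx, ], b$y_hat[idx, ], b$y[idx, ])
  a2 <- assign_pairs(b2, 1)
  S2 <- repulsion_weights(a2, eta[idx], b2$y, 1)
  expect_equal(amcr_loss(b2, a2, S2, 0.2)$total, t0, tolerance = 1e-9)
})

test_that("loss gradient attracts positives and repels negatives", {
  # analytic gradient vs numerical differentiation
  b <- random_batch(4, seed = 31, collapse_frac = 0.7)
  a <- assign_pairs(b, 1)
  S <- repulsion_weights(a, rep(1, 8), b$y, 1)
  g <- morphoreg:::amcr_loss_grad(b, a, S, 0.5)
  f <- function(zflat) {
    z <- matrix(zflat, 8, 8)
    bb <- b; bb$z <- z
    amcr_loss(bb, a, S, 0.5)$total
  }
  eps <- 1e-6
  for (k in c(1, 10, 33, 64)) {
    zp <- c(b$z); zp[k] <- zp[k] + eps
    zm <- c(b$z); zm[k] <- zm[k] - eps
    expect_equal(g[k], (f(zp) - f(zm)) / (2 * eps), tolerance = 1e-4)
  }
  # a descent step increases anchor-positive similarity and decreases
  # anchor-negative similarity in a hand-built one-anchor configuration
  z <- unit_rows(rbind(c(1, 0.2), c(1, 0.15), c(0.4, 1), c(-0.5, -1)))
  y <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  yh <- rbind(c(0, 0), c(3, 3), c(0.1, 0), c(9, 9))
  bb <- embedding_batch(z, yh, y)
  aa <- assign_pairs(bb, 1)
  SS <- repulsion_weights(aa, rep(1, 4), y, 1)
  gg <- morphoreg:::amcr_loss_grad(bb, aa, SS, 0.5)
  z2 <- unit_rows(z - 0.05 * gg)
  expect_gt(sum(z2[1, ] * z2[2, ]), sum(z[1, ] * z[2, ]))
  expect_lt(sum(z2[1, ] * z2[3, ]), sum(z[1, ] * z[3, ]))
})

test_that("larger repulsion weights strictly increase the anchor loss", {
  z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, -1))
  y <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  yh <- rbind(c(0, 0), c(3, 3), c(0.1, 0), c(9, 9))
  b <- embedding_batch(z, yh, y)
  a <- assign_pairs(b, 1)
  vals <- vapply(c(0.5, 1, 2, 4), function(s) {
    S <- matrix(0, 4, 4); S[1, 3] <- s
    amcr_loss(b, a, S, 1)$per_sample[1]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("regression and hybrid losses follow their definitions", {
  expect_equal(l1_regression_loss(matrix(0, 3, 2), matrix(0, 3, 2)), 0)
  expect_equal(l1_regression_loss(matrix(c(0.5, 0.2), 1, 2),
                                  matrix(0, 1, 2)), 0.7)
  yh <- matrix(rnorm(10), 5, 2); y <- matrix(rnorm(10), 5, 2)
  expect_equal(l1_regression_loss(y + 2 * (yh - y), y),
               2 * l1_regression_loss(yh, y))
  expect_equal(hybrid_loss(0.7, 0.5514, beta = 1), 1.2514)
  expect_equal(hybrid_loss(0.7, 0.5514, beta = 0), 0.7)
  expect_equal(hybrid_loss(0, 0.5, 2) / hybrid_loss(0, 0.5, 1), 2)
})

test_that("collapse rate matches brute-force pair enumeration", {
  # perfect predictor: no collapse
  b <- random_batch(6, seed = 41, collapse_frac = 0)
  bp <- embedding_batch(b$z, b$y, b$y)
  expect_equal(collapse_rate(bp, omega = 0.5), 0)
  # constant predictor over mutually dissimilar labels: total collapse
  z <- unit_rows(matrix(rnorm(12), 6, 2))
  y <- rbind(c(0, 0), c(0, 0), c(4, 4), c(4, 4), c(-4, 4), c(-4, 4))
  bc <- embedding_batch(z, matrix(0, 6, 2), y)
  expect_equal(collapse_rate(bc, omega = 1), 1)
  # mixed batch vs O(n^2) enumeration
  bm <- random_batch(8, seed = 43, collapse_frac = 0.5)
  manhattan <- function(a, b) sum(abs(a - b))
  num <- 0; den <- 0
  for (j in 1:16) for (q in 1:16) {
    if (q == j) next
    if (manhattan(bm$y[j, ], bm$y[q, ]) > 0.8) {
      den <- den + 1
      if (manhattan(bm$y_hat[j, ], bm$y_hat[q, ]) <= 0.8) num <- num + 1
    }
  }
  expect_equal(collapse_rate(bm, 0.8), num / den)
  # undefined when no dissimilar pairs exist
  ball <- random_batch(3, seed = 44, collapse_frac = 0, label_spread = 0.01)
  expect_true(is.na(collapse_rate(ball, omega = 10)))
})
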