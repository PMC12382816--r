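# Shared fixtures and independent reference implementations.

# unit-norm random embeddings
unit_rows <- function(m) m / sqrt(rowSums(m^2))

# random embedding batch with sibling label structure; predictions are the
# labels plus noise, with an optional fraction of rows collapsed to zero to
# force negative pairs
random_batch <- function(n_pairs, d = 8, seed = 1, collapse_frac = 0.5,
                         label_spread = 1.5) {
  withr::with_seed(seed, {
    n <- 2L * n_pairs
    z <- unit_rows(matrix(rnorm(n * d), n, d))
    y0 <- matrix(rnorm(n_pairs * 2, sd = label_spread), n_pairs, 2)
    y <- y0[rep(seq_len(n_pairs), each = 2L), , drop = FALSE]
    yh <- y + matrix(rnorm(n * 2, sd = 0.3), n, 2)
    ncol_collapse <- floor(collapse_frac * n)
    if (ncol_collapse > 0) {
      rows <- sample(n, ncol_collapse)
      yh[rows, ] <- matrix(rnorm(2 * ncol_collapse, sd = 0.05),
                           ncol_collapse, 2)
    }
    embedding_batch(z, yh, y)
  })
}

# Independent double-loop reference for the AMCR regularizer: applies the
# pair rules, the density-scaled repulsion weights and the anchor loss
# definition literally, one pair at a time. Takes eta as a per-sample
# vector so the density model itself can be checked separately.
amcr_reference <- function(z, y, y_hat, omega, tau, eta, s_max = 10) {
  n <- nrow(z)
  manhattan <- function(a, b) sum(abs(a - b))
  total <- 0
  per <- numeric(n)
  for (j in seq_len(n)) {
    kp <- integer(0); kq <- integer(0)
    for (q in seq_len(n)) {
      if (q == j) next
      dy <- manhattan(y[j, ], y[q, ])
      dp <- manhattan(y_hat[j, ], y_hat[q, ])
      if (dy <= omega) kp <- c(kp, q)
      else if (dp <= omega) kq <- c(kq, q)
    }
    if (length(kq) == 0L) next
    num <- 0
    for (i in kp) num <- num + exp(sum(z[j, ] * z[i, ]) / tau)
    den <- num
    for (q in kq) {
      S <- min(eta[j] * manhattan(y[j, ], y[q, ]) / omega, s_max)
      den <- den + S * exp(sum(z[j, ] * z[q, ]) / tau)
    }
    per[j] <- -log((num / length(kp)) / den)
  }
  list(total = sum(per) / n, per_sample = per)
}

# session-cached small synthetic dataset (generated once, reused by tests)
.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function(n = 48, seed = 401) {
  key <- paste0("ds_", n, "_", seed)
  hit <- .fixture_env[[key]]
  if (!is.null(hit)) return(hit)
  dir <- file.path(tempdir(), paste0("morphoreg-fix-", n, "-", seed))
  cfg <- synth_config(n_samples = n, seed = seed)
  man <- generate_dataset(cfg, dir)
  out <- list(config = cfg, manifest = man,
              images = morphoreg:::load_images(man))
  .fixture_env[[key]] <- out
  out
}

# small custom networks for dependency-graph tests
chain_net <- function(seed = 1) {
  withr::with_seed(seed, {
    bd <- morphoreg:::mr_builder()
    morphoreg:::bd_conv(bd, "c1", 3L, 8L, 3L, stride = 2L)
    morphoreg:::bd_bn(bd, "c1_bn", 8L)
    morphoreg:::bd_act(bd, "c1_act", "relu")
    morphoreg:::bd_conv(bd, "c2", 8L, 4L, 3L, stride = 2L)
    bd$layers[["gap"]] <- morphoreg:::new_layer("gap", "gap", "c2")
    hd <- morphoreg:::init_linear(4L, 2L)
    bd$layers[["head"]] <- morphoreg:::new_layer(
      "head", "linear", "gap", in_features = 4L, out_features = 2L,
      W = hd$W, b = hd$b)
    morphoreg:::new_network(bd$layers, embedding = "gap", output = "head",
                            arch = architecture_spec("tiny-cnn",
                                                     input_size = 16L))
  })
}

# give batch-norm layers nonzero shifts and off-unit running statistics so
# that a zeroed convolution channel is NOT automatically dead: closure tests
# would otherwise be vacuous on freshly initialized networks
randomize_bn <- function(net, seed = 99) {
  withr::with_seed(seed, {
    for (id in names(net$layers)) {
      ly <- net$layers[[id]]
      if (ly$op != "bn") next
      C <- ly$channels
      # positive shift and negative running mean guarantee that a zeroed
      # convolution channel maps to a strictly positive constant, which
      # survives ReLU -- keeping the minimality check non-vacuous
      ly$beta <- runif(C, 0.05, 0.4)
      ly$gamma <- runif(C, 0.6, 1.4)
      ly$running_mean <- runif(C, -0.3, -0.05)
      ly$running_var <- runif(C, 0.5, 1.5)
      net$layers[[id]] <- ly
    }
  })
  net
}
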