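# Adaptive multi-scale contrastive regression (AMCR).
#
# A contrastive regularizer for imbalanced multi-target regression. On a
# batch of 2N augmented views with unit embeddings z, standardized true
# labels y and predictions y_hat:
#
#   * two samples are label-similar when the Manhattan distance of their
#     standardized labels is <= omega;
#   * positives of j are all label-similar samples (the sibling view always
#     qualifies); negatives are samples whose labels are dissimilar but
#     whose *predictions* are erroneously similar ("prediction collapse");
#   * a sample with at least one negative is an anchor and contributes
#       L_j = -log[ (1/N+_j) sum_{i in K+} e^{z_j.z_i/tau}
#                   / ( sum_{p in K+} e^{z_j.z_p/tau}
#                       + sum_{q in K-} S_jq e^{z_j.z_q/tau} ) ],
#     non-anchors contribute 0, and the total is the mean over all 2N;
#   * the repulsion weight S_jq = eta_j * Dist(y_j, y_q) / omega grows with
#     label dissimilarity and with eta_j = eta0 * d_j, where d_j is the
#     inverse label-density weight of sample j (minority samples push
#     harder). S is capped at s_max for numerical safety.

#' AMCR configuration
#'
#' @param omega similarity threshold in standardized Manhattan label units
#' @param tau temperature of the contrastive softmax
#' @param beta weight of the AMCR term in the hybrid objective
#' @param eta0 base repulsion strength
#' @param density_bins histogram bins per label dimension for the density
#'   weights
#' @param s_max cap on repulsion weights
#' @return list of class `mr_amcr_config`
#' @export
amcr_config <- function(omega = 1.0, tau = 0.2, beta = 1.0, eta0 = 1.0,
                        density_bins = 10L, s_max = 10) {
  if (omega <= 0) stop("omega must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  if (eta0 <= 0) stop("eta0 must be > 0")
  structure(list(omega = omega, tau = tau, beta = beta, eta0 = eta0,
                 density_bins = as.integer(density_bins), s_max = s_max),
            class = "mr_amcr_config")
}

#' Manhattan distance between standardized label vectors
#'
#' `Dist(y_i, y_j) = |l_i - l_j| + |w_i - w_j|`, the label-space metric of
#' the pair-selection rules.
#'
#' @param y_i,y_j numeric length-2 vectors (standardized length, weight)
#' @return nonnegative scalar
#' @examples
#' label_dist(c(0, 0), c(1, 2)) # 3
#' @export
label_dist <- function(y_i, y_j) {
  sum(abs(as.numeric(y_i) - as.numeric(y_j)))
}

# all-pairs Manhattan distance matrix for an n x 2 label matrix
label_dist_matrix <- function(y) {
  abs(outer(y[, 1], y[, 1], `-`)) + abs(outer(y[, 2], y[, 2], `-`))
}

#' Assemble an embedding batch
#'
#' @param z 2N x D embedding matrix, rows unit-length (tolerance 1e-6)
#' @param y_hat 2N x 2 standardized predictions
#' @param y 2N x 2 standardized true labels
#' @param sibling integer vector: `sibling[j]` is the index of the other
#'   view of the same source image; defaults to consecutive pairing
#'   (1,2), (3,4), ...
#' @return list of class `mr_embedding_batch`
#' @export
embedding_batch <- function(z, y_hat, y, sibling = NULL) {
  z <- as.matrix(z); y_hat <- as.matrix(y_hat); y <- as.matrix(y)
  n <- nrow(z)
  if (n %% 2 != 0L) stop("batch size must be even (2N augmented views)")
  if (nrow(y_hat) != n || nrow(y) != n) stop("z, y_hat, y sizes disagree")
  if (is.null(sibling)) {
    sibling <- as.integer(seq_len(n) + rep(c(1L, -1L), n / 2))
  }
  if (any(sibling[sibling] != seq_len(n)) || any(sibling == seq_len(n))) {
    stop("sibling map must be a perfect matching without fixed points")
  }
  if (any(abs(y - y[sibling, , drop = FALSE]) > 1e-9)) {
    stop("sibling views must share identical labels")
  }
  nrm <- sqrt(rowSums(z^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("embeddings must be unit-normalized (|z| = 1 within 1e-6)")
  }
  structure(list(z = z, y_hat = y_hat, y = y, sibling = as.integer(sibling)),
            class = "mr_embedding_batch")
}

#' Select positive and negative pairs
#'
#' Applies the decision rules: `q` is a positive of `j` when their true
#' labels are similar (`Dist(y_j, y_q) <= omega`); a negative when the true
#' labels are dissimilar but the predictions are erroneously similar
#' (`Dist(y_hat_j, y_hat_q) <= omega`); otherwise unpaired. A sample is an
#' anchor iff it has at least one negative.
#'
#' @param batch an [embedding_batch()]
#' @param omega similarity threshold
#' @return tibble with list-columns `Kplus`, `Kminus` and logical
#'   `is_anchor`, one row per view
#' @export
assign_pairs <- function(batch, omega) {
  if (!inherits(batch, "mr_embedding_batch")) stop("batch must be an embedding_batch()")
  n <- nrow(batch$z)
  Dy <- label_dist_matrix(batch$y)
  Dp <- label_dist_matrix(batch$y_hat)
  diag(Dy) <- NA; diag(Dp) <- NA
  kplus <- vector("list", n)
  kminus <- vector("list", n)
  for (j in seq_len(n)) {
    sim <- which(Dy[j, ] <= omega)
    kplus[[j]] <- sim
    kminus[[j]] <- which(Dy[j, ] > omega & Dp[j, ] <= omega)
  }
  tibble::tibble(j = seq_len(n), Kplus = kplus, Kminus = kminus,
                 is_anchor = lengths(kminus) > 0L)
}

#' Fit the label-density model
#'
#' A 2-D histogram over standardized training labels; the inverse-density
#' weight of a sample is `d = 1 / (p_hat + eps_floor)` rescaled so that the
#' training-set mean of `d` is 1, and the per-sample repulsion strength is
#' `eta = eta0 * d`.
#'
#' @param train_labels matrix or data frame of standardized labels
#'   (columns: length, weight)
#' @param bins histogram bins per dimension
#' @param eta0 base repulsion strength
#' @return list of class `mr_density` with the histogram, the training
#'   weights `d` and `eta`
#' @export
fit_density <- function(train_labels, bins = 10L, eta0 = 1.0) {
  y <- as.matrix(as.data.frame(train_labels))[, 1:2, drop = FALSE]
  n <- nrow(y)
  if (n < 1) stop("need at least one training label")
  rngs <- apply(y, 2, range)
  degenerate <- all(rngs[1, ] == rngs[2, ])
  if (degenerate) {
    warning("all labels identical; density weights degenerate to 1")
    model <- structure(list(degenerate = TRUE, eta0 = eta0,
                            d = rep(1, n), eta = rep(eta0, n)),
                       class = "mr_density")
    return(model)
  }
  pad <- pmax((rngs[2, ] - rngs[1, ]) * 1e-6, 1e-12)
  breaks_l <- seq(rngs[1, 1] - pad[1], rngs[2, 1] + pad[1], length.out = bins + 1)
  breaks_w <- seq(rngs[1, 2] - pad[2], rngs[2, 2] + pad[2], length.out = bins + 1)
  bl <- findInterval(y[, 1], breaks_l, all.inside = TRUE)
  bw <- findInterval(y[, 2], breaks_w, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (i in seq_len(n)) counts[bl[i], bw[i]] <- counts[bl[i], bw[i]] + 1L
  p_hat <- counts / n
  eps_floor <- 1 / (10 * n)
  d_raw <- 1 / (p_hat[cbind(bl, bw)] + eps_floor)
  scale <- mean(d_raw)
  d <- d_raw / scale
  structure(list(degenerate = FALSE, breaks_l = breaks_l, breaks_w = breaks_w,
                 p_hat = p_hat, eps_floor = eps_floor, norm = scale,
                 eta0 = eta0, d = d, eta = eta0 * d),
            class = "mr_density")
}

#' Inverse-density weights for new labels under a fitted model
#'
#' @param model an [fit_density()] model
#' @param labels matrix or data frame of standardized labels
#' @return numeric vector of weights `d` (training-set normalization)
#' @export
density_weight <- function(model, labels) {
  y <- as.matrix(as.data.frame(labels))[, 1:2, drop = FALSE]
  if (model$degenerate) return(rep(1, nrow(y)))
  bl <- findInterval(y[, 1], model$breaks_l, all.inside = TRUE)
  bw <- findInterval(y[, 2], model$breaks_w, all.inside = TRUE)
  (1 / (model$p_hat[cbind(bl, bw)] + model$eps_floor)) / model$norm
}

#' Repulsion weights for negative pairs
#'
#' `S_jq = eta_j * Dist(y_j, y_q) / omega`, defined only for negative pairs,
#' strictly increasing in label dissimilarity at fixed `eta_j` (every
#' negative has `Dist > omega`, so `S > eta_j`), proportional to `eta_j`,
#' and capped at `s_max`.
#'
#' @param assignment result of [assign_pairs()]
#' @param density an [fit_density()] model (used to look up `eta_j` for the
#'   batch labels), or a numeric vector `eta` of per-sample strengths
#' @param y 2N x 2 standardized true labels of the batch
#' @param omega similarity threshold used in the assignment
#' @param s_max cap on the weights
#' @return tibble `(j, q, S)` over negative pairs, of class
#'   `mr_repulsion`
#' @export
repulsion_weights <- function(assignment, density, y, omega, s_max = 10) {
  y <- as.matrix(y)
  eta <- if (is.numeric(density)) {
    density
  } else {
    density$eta0 * density_weight(density, y)
  }
  if (length(eta) == 1L) eta <- rep(eta, nrow(y))
  Dy <- label_dist_matrix(y)
  nneg <- lengths(assignment$Kminus)
  js <- rep.int(assignment$j, nneg)
  qs <- as.integer(unlist(assignment$Kminus, use.names = FALSE))
  s_vals <- if (length(js)) pmin(eta[js] * Dy[cbind(js, qs)] / omega, s_max)
            else numeric(0)
  rows <- tibble::tibble(j = js, q = qs, S = s_vals)
  structure(rows, class = c("mr_repulsion", class(rows)))
}

# dense 2N x 2N repulsion matrix (zeros outside negative pairs)
repulsion_dense <- function(S_tbl, n) {
  S <- matrix(0, n, n)
  if (nrow(S_tbl) > 0) S[cbind(S_tbl$j, S_tbl$q)] <- S_tbl$S
  S
}

#' AMCR contrastive loss
#'
#' Anchor losses as defined above, averaged over all 2N views; non-anchors
#' contribute exactly zero.
#'
#' @param batch an [embedding_batch()]
#' @param assignment result of [assign_pairs()] on the same batch
#' @param S repulsion weights from [repulsion_weights()] (or a dense matrix)
#' @param tau temperature
#' @return list with `total` (scalar) and `per_sample` (length-2N vector)
#' @export
amcr_loss <- function(batch, assignment, S, tau) {
  if (!inherits(batch, "mr_embedding_batch")) stop("batch must be an embedding_batch()")
  if (tau <= 0) stop("tau must be > 0")
  z <- batch$z
  if (any(!is.finite(z))) stop("embeddings contain NaN/Inf")
  n <- nrow(z)
  Sm <- if (is.matrix(S)) S else repulsion_dense(S, n)
  E <- exp(tcrossprod(z) / tau)
  per <- numeric(n)
  for (j in seq_len(n)) {
    if (!assignment$is_anchor[j]) next
    kp <- assignment$Kplus[[j]]
    kq <- assignment$Kminus[[j]]
    A <- sum(E[j, kp])
    D <- A + sum(Sm[j, kq] * E[j, kq])
    per[j] <- -log((A / length(kp)) / D)
  }
  list(total = sum(per) / n, per_sample = per)
}

# gradient of the total AMCR loss w.r.t. the (unit) embeddings
amcr_loss_grad <- function(batch, assignment, S, tau) {
  z <- batch$z
  n <- nrow(z)
  Sm <- if (is.matrix(S)) S else repulsion_dense(S, n)
  E <- exp(tcrossprod(z) / tau)
  Cf <- matrix(0, n, n)   # dL/dsim coefficients
  for (j in seq_len(n)) {
    if (!assignment$is_anchor[j]) next
    kp <- assignment$Kplus[[j]]
    kq <- assignment$Kminus[[j]]
    A <- sum(E[j, kp])
    D <- A + sum(Sm[j, kq] * E[j, kq])
    Cf[j, kp] <- -E[j, kp] / A + E[j, kp] / D
    Cf[j, kq] <- Sm[j, kq] * E[j, kq] / D
  }
  ((Cf + t(Cf)) %*% z) / (tau * n)
}

#' L1 multi-target regression loss
#'
#' Mean over samples of the summed absolute errors across the two targets.
#'
#' @param y_hat,y N x 2 matrices (standardized predictions and labels)
#' @return nonnegative scalar
#' @export
l1_regression_loss <- function(y_hat, y) {
  y_hat <- as.matrix(y_hat); y <- as.matrix(y)
  stopifnot(all(dim(y_hat) == dim(y)))
  mean(rowSums(abs(y_hat - y)))
}

#' Hybrid objective
#'
#' `L_sum = L_R + beta * L_AMCR`.
#'
#' @param l1 regression term
#' @param amcr contrastive term
#' @param beta balance hyperparameter
#' @return scalar
#' @export
hybrid_loss <- function(l1, amcr, beta) {
  l1 + beta * amcr
}

#' Prediction-collapse rate diagnostic
#'
#' Among ordered pairs with dissimilar true labels (`Dist(y) > omega`), the
#' fraction whose predictions are erroneously similar
#' (`Dist(y_hat) <= omega`). `NA` when no dissimilar-label pair exists.
#'
#' @param batch an [embedding_batch()] (embeddings unused)
#' @param omega similarity threshold
#' @return scalar in \[0, 1\], or `NA`
#' @export
collapse_rate <- function(batch, omega) {
  Dy <- label_dist_matrix(batch$y)
  Dp <- label_dist_matrix(batch$y_hat)
  diag(Dy) <- NA; diag(Dp) <- NA
  dis <- which(Dy > omega)
  if (length(dis) == 0L) return(NA_real_)
  mean(Dp[dis] <= omega)
}
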