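# Two-view augmentation pipeline, evaluation transform, and label
# standardization.
#
# Training images yield an asymmetric pair of views: view 1 applies resize ->
# horizontal flip (p = 0.5) -> rotation U(-20, 20) deg -> color jitter
# (brightness, contrast, saturation, hue) = (0.3, 0.3, 0.3, 0.1) -> random
# grayscale (p = 0.1) -> normalize; view 2 uses rotation U(-15, 15) deg,
# jitter (0.2, 0.2, 0.2, 0.0) and no grayscale. Validation/test images are
# only resized and normalized. Images are HxWx3 arrays in [0, 1] before
# normalization; normalization uses the ImageNet mean [0.485, 0.456, 0.406]
# and SD [0.229, 0.224, 0.225].

MR_IMG_MEAN <- c(0.485, 0.456, 0.406)
MR_IMG_SD <- c(0.229, 0.224, 0.225)

check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("input must be an HxWx3 image array")
  }
  image[, , 1:3, drop = FALSE]
}

# bilinear resize to size x size (half-pixel-center convention)
resize_bilinear <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  map_axis <- function(n_src, n_dst) {
    s <- (seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5
    s <- pmin(pmax(s, 0), n_src - 1)
    i0 <- floor(s)
    list(i0 = as.integer(i0) + 1L,
         i1 = pmin(as.integer(i0) + 2L, n_src),
         w = s - i0)
  }
  rr <- map_axis(d[1], size)
  cc <- map_axis(d[2], size)
  Wr <- matrix(rr$w, size, size)
  Wc <- matrix(cc$w, size, size, byrow = TRUE)
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    p <- img[, , ch]
    out[, , ch] <-
      (1 - Wr) * (1 - Wc) * p[rr$i0, cc$i0] +
      (1 - Wr) * Wc * p[rr$i0, cc$i1] +
      Wr * (1 - Wc) * p[rr$i1, cc$i0] +
      Wr * Wc * p[rr$i1, cc$i1]
  }
  out
}

# bilinear rotation about the image center; out-of-frame samples take `fill`
rotate_bilinear <- function(img, angle_deg, fill) {
  if (angle_deg == 0) return(img)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  wx <- sx - x0; wy <- sy - y0
  # linear indices + validity of the four neighbours, shared across channels
  nb <- function(yi, xi) {
    ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
    ix <- yi + (xi - 1) * H
    ix[!ok] <- 1L
    list(ix = ix, bad = !ok)
  }
  n00 <- nb(y0, x0); n01 <- nb(y0, x0 + 1)
  n10 <- nb(y0 + 1, x0); n11 <- nb(y0 + 1, x0 + 1)
  w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx
  w10 <- wy * (1 - wx); w11 <- wy * wx
  out <- array(0, d)
  for (ch in 1:3) {
    p <- img[, , ch]
    fv <- fill[ch]
    v00 <- p[n00$ix]; v00[n00$bad] <- fv
    v01 <- p[n01$ix]; v01[n01$bad] <- fv
    v10 <- p[n10$ix]; v10[n10$bad] <- fv
    v11 <- p[n11$ix]; v11[n11$bad] <- fv
    out[, , ch] <- w00 * v00 + w01 * v01 + w10 * v10 + w11 * v11
  }
  out
}

luma <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# RGB <-> HSV, vectorized over matrices of any shape (values in [0,1],
# hue in turns)
rgb_to_hsv_mats <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  dlt <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- dlt > 0
  rmax <- nz & mx == r
  gmax <- nz & !rmax & mx == g
  bmax <- nz & !rmax & !gmax
  h[rmax] <- (((g - b) / dlt)[rmax] / 6) %% 1
  h[gmax] <- (((b - r) / dlt)[gmax] + 2) / 6
  h[bmax] <- (((r - g) / dlt)[bmax] + 4) / 6
  s <- ifelse(mx > 0, dlt / mx, 0)
  list(h = h, s = s, v = mx)
}

rgb_to_hsv_img <- function(img) {
  rgb_to_hsv_mats(img[, , 1], img[, , 2], img[, , 3])
}

hsv_to_rgb_mats <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  pick <- function(a0, a1, a2, a3, a4, a5) {
    out <- a0
    out[i == 1] <- a1[i == 1]; out[i == 2] <- a2[i == 2]
    out[i == 3] <- a3[i == 3]; out[i == 4] <- a4[i == 4]
    out[i == 5] <- a5[i == 5]
    out
  }
  list(r = pick(v, q, p, p, t, v),
       g = pick(t, v, v, q, p, p),
       b = pick(p, p, t, v, v, q))
}

hsv_to_rgb_img <- function(h, s, v) {
  m <- hsv_to_rgb_mats(h, s, v)
  arr <- array(0, c(nrow(h), ncol(h), 3))
  arr[, , 1] <- m$r; arr[, , 2] <- m$g; arr[, , 3] <- m$b
  arr
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# torchvision-style photometric jitter; factors drawn before application,
# applied in the fixed order brightness -> contrast -> saturation -> hue.
# The luma plane is computed once and tracked through the affine brightness
# and contrast steps (clamping makes the tracked luma approximate at the
# extremes, which only modulates the saturation mix).
color_jitter <- function(img, brightness, contrast, saturation, hue) {
  gr <- luma(img)
  if (brightness > 0) {
    f <- stats::runif(1, max(0, 1 - brightness), 1 + brightness)
    img <- clamp01(img * f)
    gr <- clamp01(gr * f)
  }
  if (contrast > 0) {
    f <- stats::runif(1, max(0, 1 - contrast), 1 + contrast)
    m <- mean(gr)
    img <- clamp01(f * img + (1 - f) * m)
    gr <- clamp01(f * gr + (1 - f) * m)
  }
  if (saturation > 0) {
    f <- stats::runif(1, max(0, 1 - saturation), 1 + saturation)
    for (ch in 1:3) img[, , ch] <- f * img[, , ch] + (1 - f) * gr
    img <- clamp01(img)
  }
  if (hue > 0) {
    dh <- stats::runif(1, -hue, hue)
    hsv <- rgb_to_hsv_img(img)
    img <- hsv_to_rgb_img(hsv$h + dh, hsv$s, hsv$v)
  }
  img
}

to_grayscale <- function(img) {
  g <- luma(img)
  array(rep(g, 3), dim(img))
}

normalize_image <- function(img) {
  for (ch in 1:3) {
    img[, , ch] <- (img[, , ch] - MR_IMG_MEAN[ch]) / MR_IMG_SD[ch]
  }
  img
}

#' Augmentation configuration (two asymmetric training views)
#'
#' @param size output square size in pixels
#' @param view1,view2 lists with `flip_p`, `rot_deg`, `jitter` (brightness,
#'   contrast, saturation, hue) and `gray_p`
#' @return list of class `mr_augment_config`
#' @export
augment_config <- function(size = 64L,
                           view1 = list(flip_p = 0.5, rot_deg = 20,
                                        jitter = c(0.3, 0.3, 0.3, 0.1),
                                        gray_p = 0.1),
                           view2 = list(flip_p = 0.5, rot_deg = 15,
                                        jitter = c(0.2, 0.2, 0.2, 0.0),
                                        gray_p = 0)) {
  structure(list(size = as.integer(size), view1 = view1, view2 = view2),
            class = "mr_augment_config")
}

# median color of the image border (the background, for synthetic scenes);
# used as rotation fill so corners do not leak the rotation angle
border_median <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ridx <- c(1L, H); cidx <- c(1L, W)
  vapply(1:3, function(ch) {
    stats::median(c(img[ridx, , ch], img[, cidx, ch]))
  }, numeric(1))
}

# Draw all stochastic factors of one view in a fixed order (flip, angle,
# brightness, contrast, saturation, hue, grayscale). Keeping the draw
# separate from the application lets the batched pipeline consume the RNG in
# exactly the same sequence as the per-image one.
draw_view_params <- function(vw) {
  p <- list(flip = stats::runif(1) < vw$flip_p,
            ang = stats::runif(1, -vw$rot_deg, vw$rot_deg))
  p$fb <- if (vw$jitter[1] > 0)
    stats::runif(1, max(0, 1 - vw$jitter[1]), 1 + vw$jitter[1]) else NA_real_
  p$fc <- if (vw$jitter[2] > 0)
    stats::runif(1, max(0, 1 - vw$jitter[2]), 1 + vw$jitter[2]) else NA_real_
  p$fs <- if (vw$jitter[3] > 0)
    stats::runif(1, max(0, 1 - vw$jitter[3]), 1 + vw$jitter[3]) else NA_real_
  p$dh <- if (vw$jitter[4] > 0)
    stats::runif(1, -vw$jitter[4], vw$jitter[4]) else 0
  p$gray <- vw$gray_p > 0 && stats::runif(1) < vw$gray_p
  p
}

jitter_with_params <- function(img, p) {
  gr <- luma(img)
  if (!is.na(p$fb)) {
    img <- clamp01(img * p$fb)
    gr <- clamp01(gr * p$fb)
  }
  if (!is.na(p$fc)) {
    m <- mean(gr)
    img <- clamp01(p$fc * img + (1 - p$fc) * m)
    gr <- clamp01(p$fc * gr + (1 - p$fc) * m)
  }
  if (!is.na(p$fs)) {
    for (ch in 1:3) img[, , ch] <- p$fs * img[, , ch] + (1 - p$fs) * gr
    img <- clamp01(img)
  }
  if (p$dh != 0) {
    hsv <- rgb_to_hsv_img(img)
    img <- hsv_to_rgb_img(hsv$h + p$dh, hsv$s, hsv$v)
  }
  img
}

apply_view_params <- function(img, size, p) {
  img <- resize_bilinear(img, size)
  if (p$flip) img <- img[, rev(seq_len(ncol(img))), , drop = FALSE]
  img <- rotate_bilinear(img, p$ang, border_median(img))
  img <- jitter_with_params(img, p)
  if (p$gray) img <- to_grayscale(img)
  normalize_image(img)
}

apply_view <- function(img, size, vw) {
  apply_view_params(img, size, draw_view_params(vw))
}

#' Generate the asymmetric two-view augmentation pair
#'
#' Both views share the source image's label; view 1 is perturbed more
#' strongly than view 2 (which never grayscales). Deterministic given
#' `seed`.
#'
#' @param image HxWx3 array in \[0, 1\]
#' @param seed integer seed
#' @param config an [augment_config()]
#' @return list of class `mr_view_pair` with normalized arrays `view1`,
#'   `view2`
#' @export
two_view <- function(image, seed, config = augment_config()) {
  image <- check_image(image)
  withr::with_seed(as.integer(seed), {
    v1 <- apply_view(image, config$size, config$view1)
    v2 <- apply_view(image, config$size, config$view2)
    structure(list(view1 = v1, view2 = v2), class = "mr_view_pair")
  })
}

#' Deterministic evaluation transform
#'
#' Resize to `size` and normalize; no stochastic operation.
#'
#' @param image HxWx3 array in \[0, 1\]
#' @param size output square size
#' @return normalized array of dim `c(size, size, 3)`
#' @export
eval_transform <- function(image, size = 64L) {
  normalize_image(resize_bilinear(check_image(image), size))
}

#' Fit the label standardizer on training labels
#'
#' Per-dimension mean and SD of the *training* split only; applying the
#' resulting parameters to validation/test labels is the supported (and
#' leakage-safe) pattern, fitting on them is not.
#'
#' @param train_labels data frame with `length_cm`, `weight_g`
#' @param fitted_on split identifier; must be `"train"`
#' @return list of class `mr_standardizer`
#' @export
fit_label_standardizer <- function(train_labels, fitted_on = "train") {
  if (!identical(fitted_on, "train")) {
    stop("label standardizer must be fitted on the training split only")
  }
  l <- train_labels[["length_cm"]]; w <- train_labels[["weight_g"]]
  if (length(l) < 2 || length(unique(l)) < 2 || length(unique(w)) < 2) {
    stop("need >= 2 distinct labels per dimension to fit a standardizer")
  }
  p <- list(mean_l = mean(l), sd_l = stats::sd(l),
            mean_w = mean(w), sd_w = stats::sd(w), fitted_on = fitted_on)
  if (p$sd_l <= 0 || p$sd_w <= 0) stop("degenerate labels: zero variance")
  structure(p, class = "mr_standardizer")
}

#' Standardize labels to z-scores (and invert)
#'
#' @param labels data frame with `length_cm`, `weight_g` (or, for the
#'   inverse, `length_z`, `weight_z`)
#' @param params an `mr_standardizer` fitted by [fit_label_standardizer()]
#' @return tibble with `length_z`, `weight_z` (or physical units for the
#'   inverse)
#' @export
standardize_labels <- function(labels, params) {
  if (!inherits(params, "mr_standardizer")) stop("params not fitted")
  tibble::tibble(
    length_z = (labels[["length_cm"]] - params$mean_l) / params$sd_l,
    weight_z = (labels[["weight_g"]] - params$mean_w) / params$sd_w
  )
}

#' @rdname standardize_labels
#' @export
unstandardize_labels <- function(labels, params) {
  if (!inherits(params, "mr_standardizer")) stop("params not fitted")
  tibble::tibble(
    length_cm = labels[["length_z"]] * params$sd_l + params$mean_l,
    weight_g = labels[["weight_z"]] * params$sd_w + params$mean_w
  )
}

# ---- batched augmentation (training fast path) ----------------------------
#
# Applies a list of pre-drawn view parameters to a list of equally-sized
# source images in a handful of large vectorized passes. Elementwise
# arithmetic mirrors apply_view_params() operation for operation, so the
# result is bit-identical to mapping the per-image pipeline.

# stack: (S^2 x N) matrix per channel; returns (S, S, 3, N) array
batch_apply_views <- function(images, pars, size) {
  N <- length(pars)
  S <- size
  SP <- S * S
  resized <- lapply(images, resize_bilinear, size = S)
  M <- matrix(unlist(resized, use.names = FALSE), SP * 3L, N)
  chs <- lapply(1:3, function(ch) M[(ch - 1L) * SP + seq_len(SP), ,
                                    drop = FALSE])
  # border median per image; the index multiset mirrors border_median()
  # exactly (corners counted twice) and is invariant under the flip below
  bidx <- c(as.vector(rbind(1L + (0:(S - 1L)) * S, S + (0:(S - 1L)) * S)),
            seq_len(S), (S - 1L) * S + seq_len(S))
  fills <- matrix(0, 3, N)
  for (ch in 1:3) {
    sub <- chs[[ch]][bidx, , drop = FALSE]
    fills[ch, ] <- vapply(seq_len(N), function(n) stats::median(sub[, n]),
                          numeric(1))
  }
  # horizontal flip as a row permutation of the flat planes
  flip_cols <- which(vapply(pars, `[[`, TRUE, "flip"))
  if (length(flip_cols)) {
    perm <- as.vector(matrix(seq_len(SP), S, S)[, rev(seq_len(S))])
    for (ch in 1:3) chs[[ch]][, flip_cols] <- chs[[ch]][perm, flip_cols]
  }
  # rotation: per-image inverse map, gathered per channel in one pass
  th <- vapply(pars, `[[`, 0, "ang") * pi / 180
  cy <- (S + 1) / 2
  gy <- rep(seq_len(S), times = S) - cy
  gx <- rep(seq_len(S), each = S) - cy
  SX <- outer(gx, cos(th)) + outer(gy, sin(th)) + cy
  SY <- outer(gx, -sin(th)) + outer(gy, cos(th)) + cy
  x0 <- floor(SX); y0 <- floor(SY)
  wx <- SX - x0; wy <- SY - y0
  col_off <- rep((seq_len(N) - 1L) * SP, each = SP)
  nb <- function(yi, xi) {
    ok <- yi >= 1 & yi <= S & xi >= 1 & xi <= S
    ix <- yi + (xi - 1) * S
    badidx <- which(!ok)
    ix[badidx] <- 1L
    list(ix = as.integer(ix) + col_off, badidx = badidx,
         badcol = (badidx - 1L) %/% SP + 1L)
  }
  n00 <- nb(y0, x0); n01 <- nb(y0, x0 + 1)
  n10 <- nb(y0 + 1, x0); n11 <- nb(y0 + 1, x0 + 1)
  w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx
  w10 <- wy * (1 - wx); w11 <- wy * wx
  for (ch in 1:3) {
    p <- chs[[ch]]
    fr <- fills[ch, ]
    v00 <- p[n00$ix]; v00[n00$badidx] <- fr[n00$badcol]
    v01 <- p[n01$ix]; v01[n01$badidx] <- fr[n01$badcol]
    v10 <- p[n10$ix]; v10[n10$badidx] <- fr[n10$badcol]
    v11 <- p[n11$ix]; v11[n11$badidx] <- fr[n11$badcol]
    out <- w00 * v00 + w01 * v01 + w10 * v10 + w11 * v11
    dim(out) <- c(SP, N)
    chs[[ch]] <- out
  }
  # photometric jitter with per-image factors broadcast down columns;
  # clamping is the identity for factors <= 1, so it is applied only to the
  # columns that can actually violate [0, 1] (bit-equal to clamping all)
  bcast <- function(v) rep(v, each = SP)
  clamp_cols <- function(m, cols) {
    if (length(cols)) m[, cols] <- clamp01(m[, cols, drop = FALSE])
    m
  }
  gr <- 0.299 * chs[[1]] + 0.587 * chs[[2]] + 0.114 * chs[[3]]
  fb <- vapply(pars, `[[`, 0, "fb")
  if (any(!is.na(fb))) {
    fbv <- ifelse(is.na(fb), 1, fb)
    f <- bcast(fbv)
    viol <- which(fbv > 1)
    for (ch in 1:3) chs[[ch]] <- clamp_cols(chs[[ch]] * f, viol)
    gr <- clamp_cols(gr * f, viol)
  }
  fc <- vapply(pars, `[[`, 0, "fc")
  if (any(!is.na(fc))) {
    fcv <- ifelse(is.na(fc), 1, fc)
    m <- bcast(fcv * 0 + colMeans(gr))
    f <- bcast(fcv)
    viol <- which(fcv > 1)
    for (ch in 1:3) chs[[ch]] <- clamp_cols(f * chs[[ch]] + (1 - f) * m, viol)
    gr <- clamp_cols(f * gr + (1 - f) * m, viol)
  }
  fs <- vapply(pars, `[[`, 0, "fs")
  if (any(!is.na(fs))) {
    fsv <- ifelse(is.na(fs), 1, fs)
    f <- bcast(fsv)
    viol <- which(fsv > 1)
    for (ch in 1:3) chs[[ch]] <- clamp_cols(f * chs[[ch]] + (1 - f) * gr, viol)
  }
  dh <- vapply(pars, `[[`, 0, "dh")
  hue_cols <- which(dh != 0)
  if (length(hue_cols)) {
    hc <- hue_cols
    hsv <- rgb_to_hsv_mats(chs[[1]][, hc, drop = FALSE],
                           chs[[2]][, hc, drop = FALSE],
                           chs[[3]][, hc, drop = FALSE])
    sh <- matrix(rep(dh[hc], each = SP), SP, length(hc))
    rgb <- hsv_to_rgb_mats(hsv$h + sh, hsv$s, hsv$v)
    chs[[1]][, hc] <- rgb$r; chs[[2]][, hc] <- rgb$g; chs[[3]][, hc] <- rgb$b
  }
  gray_cols <- which(vapply(pars, `[[`, TRUE, "gray"))
  if (length(gray_cols)) {
    g2 <- 0.299 * chs[[1]][, gray_cols, drop = FALSE] +
      0.587 * chs[[2]][, gray_cols, drop = FALSE] +
      0.114 * chs[[3]][, gray_cols, drop = FALSE]
    for (ch in 1:3) chs[[ch]][, gray_cols] <- g2
  }
  out <- array(0, c(SP, 3, N))
  for (ch in 1:3) {
    out[, ch, ] <- (chs[[ch]] - MR_IMG_MEAN[ch]) / MR_IMG_SD[ch]
  }
  dim(out) <- c(S, S, 3, N)
  out
}

# draw the two-view parameter pairs for a set of images (one seed each) and
# build the interleaved (view1, view2, view1, ...) augmented batch
batch_two_view <- function(images, seeds, config) {
  pars <- vector("list", 2L * length(images))
  for (k in seq_along(images)) {
    withr::with_seed(as.integer(seeds[k]), {
      pars[[2L * k - 1L]] <- draw_view_params(config$view1)
      pars[[2L * k]] <- draw_view_params(config$view2)
    })
  }
  src <- rep(images, each = 2L)
  batch_apply_views(src, pars, config$size)
}

# single-view batch (baseline training path, view 1 recipe)
batch_one_view <- function(images, seeds, config) {
  pars <- vector("list", length(images))
  for (k in seq_along(images)) {
    pars[[k]] <- withr::with_seed(as.integer(seeds[k]),
                                  draw_view_params(config$view1))
  }
  batch_apply_views(images, pars, config$size)
}
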