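# Training, evaluation and reporting.
#
# The training loop follows the reference recipe: AdamW with decoupled
# weight decay, initial learning rate 1e-3, cosine annealing over the run,
# batch size 16, loss either plain MSE (the ablation baseline), L1, or the
# hybrid L1 + beta * AMCR objective. With the hybrid loss each image
# contributes an asymmetric two-view pair per step; embeddings are
# L2-normalized before the contrastive term, and the regression term is the
# average of both views' L1. Metrics are computed in physical units (cm for
# length, kg for weight) after inverting the label standardizer.

#' Training configuration
#'
#' @param lr initial learning rate (AdamW)
#' @param weight_decay decoupled weight decay
#' @param batch_size images per step (each yields two views under the
#'   hybrid loss)
#' @param epochs training epochs
#' @param scheduler `"cosine"` (annealed to 0 over `epochs`) or `"constant"`
#' @param loss `"l1+amcr"`, `"l1"` or `"mse"`
#' @param seed integer seed governing shuffling, augmentation and
#'   initialization-independent randomness
#' @param augment apply the stochastic view pipeline (`FALSE` feeds the
#'   deterministic evaluation transform instead, useful for capacity checks)
#' @return list of class `mr_train_config`
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-2, batch_size = 16L,
                         epochs = 200L, scheduler = c("cosine", "constant"),
                         loss = c("l1+amcr", "l1", "mse"), seed = 1L,
                         augment = TRUE) {
  scheduler <- match.arg(scheduler)
  loss <- match.arg(loss)
  if (lr <= 0) stop("lr must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), scheduler = scheduler,
                 loss = loss, seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "mr_train_config")
}

#' Length-stratified train/validation/test split
#'
#' Bins total length into `n_bins` equal-width bins over the observed range
#' and allocates each bin's items to the splits in the given proportions
#' (largest-remainder rounding, seeded shuffling within bins). Bins with
#' fewer items than splits are merged into their left neighbour with a
#' warning.
#'
#' @param labels data frame with a `length_cm` column
#' @param ratios proportions for (train, val, test); must sum to 1
#' @param n_bins number of length bins
#' @param seed integer seed
#' @return tibble with `idx` and `split` (factor train/val/test)
#' @export
stratified_split <- function(labels, ratios = c(0.8, 0.1, 0.1), n_bins = 6L,
                             seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  l <- labels[["length_cm"]]
  n <- length(l)
  if (n < n_bins) stop("fewer items than bins")
  rng <- range(l)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(l, breaks, all.inside = TRUE)
  # merge sparse bins leftwards so every kept bin can host all three splits
  tab <- tabulate(bin, n_bins)
  if (any(tab > 0 & tab < 3)) {
    warning("sparse length bins merged with neighbours")
    while (TRUE) {
      tab <- tabulate(bin, n_bins)
      small <- which(tab > 0 & tab < 3)
      if (length(small) == 0L) break
      b <- small[1]
      tgt <- if (b > 1) b - 1L else b + 1L
      bin[bin == b] <- tgt
    }
  }
  split <- character(n)
  withr::with_seed(as.integer(seed), {
    totals <- c(0, 0, 0)
    seen <- 0
    for (b in unique(bin)) {
      idx <- sample(which(bin == b))
      m <- length(idx)
      seen <- seen + m
      quota <- m * ratios
      base <- floor(quota)
      rem <- quota - base
      # leftover slots go to the largest remainders, ties broken by the
      # split furthest below its global share (keeps small datasets from
      # starving the test split)
      deficit <- ratios * seen - (totals + base)
      extra <- order(-rem, -deficit)[seq_len(m - sum(base))]
      counts <- base
      counts[extra] <- counts[extra] + 1
      totals <- totals + counts
      split[idx] <- rep(c("train", "val", "test"), times = counts)
    }
  })
  tibble::tibble(idx = seq_len(n),
                 split = factor(split, levels = c("train", "val", "test")))
}

#' Regression metrics in physical units
#'
#' RMSE, MAE, MAPE (percent) and R^2 per target. Weight is reported in kg.
#' Samples with a zero true value are excluded from MAPE with a warning;
#' R^2 is `NA` when the truth has zero variance.
#'
#' @param y_true,y_pred data frames with `length_cm` and `weight_g`
#' @return tibble of class `mr_metrics`: one row per target
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (nrow(y_true) < 2) stop("need at least 2 samples")
  one <- function(t, p, target, unit) {
    err <- t - p
    rmse <- sqrt(mean(err^2))
    mae <- mean(abs(err))
    nz <- t != 0
    if (!all(nz)) warning("zero true values excluded from MAPE")
    mape <- 100 * mean(abs(err[nz] / t[nz]))
    sst <- sum((t - mean(t))^2)
    r2 <- if (sst > 0) 1 - sum(err^2) / sst else {
      warning("zero-variance truth: R^2 undefined")
      NA_real_
    }
    tibble::tibble(target = target, unit = unit, rmse = rmse, mae = mae,
                   mape_percent = mape, r2 = r2, n = length(t))
  }
  out <- dplyr::bind_rows(
    one(y_true[["length_cm"]], y_pred[["length_cm"]], "length", "cm"),
    one(y_true[["weight_g"]] / 1000, y_pred[["weight_g"]] / 1000,
        "weight", "kg")
  )
  structure(out, class = c("mr_metrics", class(out)))
}

# ---- AdamW with cosine annealing ------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

cosine_lr <- function(lr0, epoch, epochs, scheduler) {
  if (scheduler == "constant") return(lr0)
  0.5 * lr0 * (1 + cos(pi * (epoch - 1) / max(epochs, 1)))
}

aug_seed <- function(seed, epoch, i) {
  as.integer((as.numeric(seed) * 1000003 + epoch * 7919 + i) %% 2147483647)
}

# stack a list of HxWx3 arrays into an (H,W,3,N) batch
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(d[1], d[2], d[3], length(imgs)))
}

# ---- the training loop ----------------------------------------------------

#' Train a regression network
#'
#' Runs the optimization recipe described above on a generated dataset. The
#' label standardizer and the label-density model are fitted on the training
#' split only. Per epoch the history records the total loss, its L1 and
#' AMCR components, the validation L1 (standardized and physical) and the
#' prediction-collapse rate; the best-validation-L1 parameters are retained.
#'
#' @param net an `mr_network` from [build_model()]
#' @param manifest dataset manifest (see [generate_dataset()]); images are
#'   read from `manifest$path`
#' @param split result of [stratified_split()] on the manifest labels
#' @param config an [train_config()]
#' @param amcr an [amcr_config()] (used when `config$loss == "l1+amcr"`)
#' @param images optional pre-loaded list of image arrays (else read from
#'   disk)
#' @param sparsity optional list (`groups`, `alpha`, `lambda`) adding the
#'   group-level sparsity penalty to the objective (see [sparsify_train()])
#' @return object of class `mr_fit`
#' @export
train_model <- function(net, manifest, split, config = train_config(),
                        amcr = amcr_config(), images = NULL,
                        sparsity = NULL) {
  if (is.null(images)) images <- load_images(manifest)
  size <- net$arch$input_size
  idx_train <- split$idx[split$split == "train"]
  idx_val <- split$idx[split$split == "val"]
  if (length(idx_train) < 2 || length(idx_val) < 1) {
    stop("split must provide at least 2 training and 1 validation item")
  }
  labels <- manifest[, c("length_cm", "weight_g")]
  std <- fit_label_standardizer(labels[idx_train, ])
  y_std <- as.matrix(standardize_labels(labels, std))
  use_amcr <- config$loss == "l1+amcr"
  dens <- if (use_amcr) {
    fit_density(y_std[idx_train, , drop = FALSE], bins = amcr$density_bins,
                eta0 = amcr$eta0)
  }
  aug <- augment_config(size = size)
  val_x <- stack_images(lapply(images[idx_val], eval_transform, size = size))
  val_y <- y_std[idx_val, , drop = FALSE]

  params <- net_params(net)
  opt <- adamw_init(params)
  best <- list(val = Inf, params = params, bn = NULL)
  hist <- vector("list", config$epochs)
  n_tr <- length(idx_train)
  nb <- max(1L, ceiling(n_tr / config$batch_size))

  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(config$lr, epoch, config$epochs, config$scheduler)
    ord <- withr::with_seed(aug_seed(config$seed, epoch, 0L),
                            sample(idx_train))
    ep <- list(total = 0, l1 = 0, amcr = 0, coll = c())
    for (bi in seq_len(nb)) {
      take <- ord[seq((bi - 1L) * config$batch_size + 1L,
                      min(bi * config$batch_size, n_tr))]
      if (length(take) == 0L) next
      seeds <- vapply(take, function(i) aug_seed(config$seed, epoch, i), 0L)
      if (config$augment) {
        if (use_amcr) {
          xb <- batch_two_view(images[take], seeds, aug)
          yb <- y_std[rep(take, each = 2L), , drop = FALSE]
        } else {
          xb <- batch_one_view(images[take], seeds, aug)
          yb <- y_std[take, , drop = FALSE]
        }
      } else {
        ev <- lapply(images[take], eval_transform, size = size)
        if (use_amcr) ev <- rep(ev, each = 2L)
        xb <- stack_images(ev)
        yb <- y_std[if (use_amcr) rep(take, each = 2L) else take, ,
                    drop = FALSE]
      }
      fw <- net_forward(net, xb, training = TRUE)
      err <- fw$output - yb
      nrows <- nrow(yb)
      if (config$loss == "mse") {
        l_r <- mean(rowSums(err^2))
        d_out <- 2 * err / nrows
      } else {
        l_r <- mean(rowSums(abs(err)))
        d_out <- sign(err) / nrows
      }
      l_a <- 0
      out_grads <- list()
      if (use_amcr) {
        zn_raw <- fw$embedding
        nrm <- sqrt(rowSums(zn_raw^2))
        nrm[nrm < 1e-12] <- 1e-12
        zn <- zn_raw / nrm
        batch <- embedding_batch(zn, fw$output, yb)
        asg <- assign_pairs(batch, amcr$omega)
        S <- repulsion_weights(asg, dens, yb, amcr$omega, amcr$s_max)
        l_a <- amcr_loss(batch, asg, S, amcr$tau)$total
        dzn <- amcr_loss_grad(batch, asg, S, amcr$tau) * amcr$beta
        dz <- (dzn - zn * rowSums(dzn * zn)) / nrm
        out_grads[[net$embedding]] <- dz
        ep$coll <- c(ep$coll, collapse_rate(batch, amcr$omega))
      }
      out_grads[[net$output]] <- d_out
      l_tot <- l_r + (if (use_amcr) amcr$beta * l_a else 0)
      if (!is.finite(l_tot)) {
        warning("non-finite loss at epoch ", epoch, "; stopping early")
        hist <- hist[seq_len(epoch - 1L)]
        net <- net_set_params(net, best$params)
        if (!is.null(best$bn)) net <- net_update_bn(net, best$bn)
        return(finish_fit(net, hist, std, dens, config, amcr, best))
      }
      grads <- net_backward(net, fw, out_grads)
      if (!is.null(sparsity)) {
        l_tot <- l_tot + sparsity_penalty(sparsity$groups, net,
                                          sparsity$alpha, sparsity$lambda)
        sg <- sparsity_grads(sparsity$groups, net, sparsity$alpha,
                             sparsity$lambda)
        for (nm in names(sg)) {
          grads[[nm]] <- if (is.null(grads[[nm]])) sg[[nm]]
                         else grads[[nm]] + sg[[nm]]
        }
      }
      stp <- adamw_step(params, grads, opt, lr, config$weight_decay)
      params <- stp$params
      opt <- stp$state
      net <- net_set_params(net, params)
      net <- net_update_bn(net, fw$bn_stats)
      ep$total <- ep$total + l_tot
      ep$l1 <- ep$l1 + l_r
      ep$amcr <- ep$amcr + l_a
    }
    # validation in eval mode
    vf <- net_forward(net, val_x, training = FALSE, keep_cache = FALSE,
                      exact = FALSE)
    v_err <- vf$output - val_y
    val_l1_std <- mean(rowSums(abs(v_err)))
    val_phys <- unstandardize_labels(
      tibble::tibble(length_z = vf$output[, 1], weight_z = vf$output[, 2]), std)
    val_true <- unstandardize_labels(
      tibble::tibble(length_z = val_y[, 1], weight_z = val_y[, 2]), std)
    val_l1_phys <- mean(abs(val_phys$length_cm - val_true$length_cm) +
                          abs(val_phys$weight_g - val_true$weight_g))
    if (val_l1_std < best$val) {
      best$val <- val_l1_std
      best$params <- params
      best$bn <- lapply(net$layers[vapply(net$layers, function(l) l$op == "bn",
                                          TRUE)],
                        function(l) list(mean = l$running_mean,
                                         var = l$running_var))
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr,
      loss_total = ep$total / nb, loss_l1 = ep$l1 / nb,
      loss_amcr = ep$amcr / nb,
      val_l1_std = val_l1_std, val_l1_phys = val_l1_phys,
      collapse_rate = if (length(ep$coll)) mean(ep$coll, na.rm = TRUE)
                      else NA_real_
    )
  }
  net <- net_set_params(net, best$params)
  if (!is.null(best$bn)) net <- net_update_bn(net, best$bn)
  finish_fit(net, hist, std, dens, config, amcr, best)
}

finish_fit <- function(net, hist, std, dens, config, amcr, best) {
  structure(list(net = net,
                 history = dplyr::bind_rows(hist),
                 standardizer = std, density = dens,
                 train_config = config, amcr_config = amcr,
                 best_val_l1 = best$val),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("<mr_fit>", nrow(x$history), "epochs; best val L1 (std):",
      signif(x$best_val_l1, 4), "\n")
  invisible(x)
}

#' Predict physical-unit labels for images
#'
#' @param object an `mr_fit`
#' @param images list of HxWx3 arrays, or a manifest tibble with `path`
#' @param ... unused
#' @return tibble with `length_cm`, `weight_g`
#' @export
predict.mr_fit <- function(object, images, ...) {
  if (is.data.frame(images)) images <- load_images(images)
  size <- object$net$arch$input_size
  x <- stack_images(lapply(images, eval_transform, size = size))
  fw <- net_forward(object$net, x, training = FALSE, keep_cache = FALSE)
  unstandardize_labels(
    tibble::tibble(length_z = fw$output[, 1], weight_z = fw$output[, 2]),
    object$standardizer
  )
}

#' Tidy the training history of a fit
#'
#' @param x an `mr_fit`
#' @param ... unused
#' @return the per-epoch history tibble
#' @export
tidy.mr_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x an `mr_fit`
#' @param ... unused
#' @export
glance.mr_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), best_val_l1 = x$best_val_l1,
                 final_train_loss = h$loss_total[nrow(h)],
                 final_collapse_rate = h$collapse_rate[nrow(h)])
}

#' Loss-curve plot of a training run
#'
#' @param object an `mr_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mr_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[, c("epoch", "loss_total", "loss_l1", "loss_amcr",
                       "val_l1_std")],
    -"epoch", names_to = "trace", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Prediction-vs-truth scatter with the y = x reference
#'
#' @param y_true,y_pred data frames with `length_cm`, `weight_g`
#' @return a ggplot, faceted by target, annotated with per-target R^2
#' @export
plot_predictions <- function(y_true, y_pred) {
  m <- compute_metrics(y_true, y_pred)
  df <- dplyr::bind_rows(
    tibble::tibble(target = "length (cm)", truth = y_true$length_cm,
                   pred = y_pred$length_cm),
    tibble::tibble(target = "weight (kg)", truth = y_true$weight_g / 1000,
                   pred = y_pred$weight_g / 1000)
  )
  lab <- tibble::tibble(
    target = c("length (cm)", "weight (kg)"),
    txt = sprintf("R² = %.3f", m$r2)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$txt),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~target, scales = "free") +
    ggplot2::labs(x = "ground truth", y = "prediction") +
    ggplot2::theme_minimal()
}

#' Absolute-error histograms comparing two prediction sets
#'
#' @param y_true truth data frame
#' @param preds named list of prediction data frames (one per model)
#' @param bins histogram bins
#' @return a ggplot faceted by target
#' @export
plot_error_hist <- function(y_true, preds, bins = 20L) {
  df <- purrr::imap_dfr(preds, function(p, nm) {
    dplyr::bind_rows(
      tibble::tibble(model = nm, target = "length (cm)",
                     abs_error = abs(p$length_cm - y_true$length_cm)),
      tibble::tibble(model = nm, target = "weight (kg)",
                     abs_error = abs(p$weight_g - y_true$weight_g) / 1000)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_error, fill = .data$model)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~target, scales = "free") +
    ggplot2::labs(x = "absolute error", y = "count") +
    ggplot2::theme_minimal()
}

#' Write the evaluation report
#'
#' Writes the loss-curve plot, the prediction scatter, absolute-error
#' histograms (when a comparison prediction set is given) and the metrics
#' JSON into `out_dir`.
#'
#' @param fit an `mr_fit`
#' @param y_true,y_pred evaluation truth and predictions (physical units)
#' @param out_dir output directory
#' @param compare optional named list of additional prediction sets for the
#'   error histogram
#' @return (invisibly) the `mr_metrics` tibble
#' @export
report_results <- function(fit, y_true, y_pred, out_dir, compare = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- compute_metrics(y_true, y_pred)
  jsonlite::write_json(as.data.frame(m), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  ggplot2::ggsave(file.path(out_dir, "loss_curves.png"), autoplot(fit),
                  width = 7, height = 4, dpi = 120)
  ggplot2::ggsave(file.path(out_dir, "pred_scatter.png"),
                  plot_predictions(y_true, y_pred),
                  width = 7, height = 4, dpi = 120)
  preds <- c(list(model = y_pred), compare)
  ggplot2::ggsave(file.path(out_dir, "error_hist.png"),
                  plot_error_hist(y_true, preds),
                  width = 7, height = 4, dpi = 120)
  invisible(m)
}
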