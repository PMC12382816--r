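# Regression network construction and static accounting.
#
# Two backbones are provided: the published MobileNetV3-Small feature
# extractor (width 1.0, inverted residuals with depthwise separable
# convolutions, squeeze-excitation with hard-sigmoid, hard-swish
# activations) producing a 576-dimensional pooled embedding, and a four-stage
# plain-convolution "tiny-cnn" producing a 64-dimensional embedding for fast
# experiments. The regression head is an efficient-channel-attention (ECA)
# recalibration of the pooled embedding followed by a single affine map to
# the two targets (total length, body weight). The 1024-unit classifier
# hidden layer of the stock MobileNetV3-Small is deliberately absent.

#' Adaptive ECA kernel size
#'
#' Kernel size of the efficient-channel-attention 1-D convolution as a
#' function of channel count: `t = (log2(C) + b) / gamma`, rounded to the
#' nearest odd integer (truncate, then step up by one if even), floored at 1
#' and capped at `C`.
#'
#' @param C channel count (positive integer)
#' @param gamma,b integer hyperparameters of the adaptive mapping
#' @return odd integer kernel size
#' @examples
#' eca_kernel_size(576) # 5
#' @export
eca_kernel_size <- function(C, gamma = 2L, b = 1L) {
  if (length(C) != 1L || !is.finite(C) || C < 1) {
    stop("C must be a positive integer")
  }
  t <- (log2(C) + b) / gamma
  k <- floor(t)
  if (k %% 2 == 0) k <- k + 1
  k <- max(1, k)
  min(k, if (C %% 2 == 0) C - 1 else C)
}

#' ECA channel recalibration of a feature vector
#'
#' Applies a same-padded 1-D convolution across channels, a sigmoid gate, and
#' channel-wise multiplication: `z' = sigmoid(conv1d(z, w)) * z`.
#'
#' @param z numeric vector of length C, or an N x C matrix of descriptors
#' @param kernel_weights numeric vector of odd length k
#' @return recalibrated object of the same shape as `z`
#' @export
eca_forward <- function(z, kernel_weights) {
  k <- length(kernel_weights)
  if (k %% 2 == 0) stop("ECA kernel length must be odd")
  vec <- is.null(dim(z))
  zm <- if (vec) matrix(z, 1L) else as.matrix(z)
  if (k > ncol(zm)) stop("ECA kernel longer than channel dimension")
  a <- 1 / (1 + exp(-conv1d_channel_forward(zm, kernel_weights)))
  out <- a * zm
  if (vec) as.vector(out) else out
}

#' Architecture specification
#'
#' @param backbone `"tiny-cnn"` (64-dim embedding, for small images) or
#'   `"mnv3s-feat"` (MobileNetV3-Small features, 576-dim embedding)
#' @param eca include the ECA recalibration in the head
#' @param gamma,b ECA kernel-size hyperparameters
#' @param input_size square input resolution in pixels
#' @return list of class `mr_arch_spec`
#' @export
architecture_spec <- function(backbone = c("tiny-cnn", "mnv3s-feat"),
                              eca = TRUE, gamma = 2L, b = 1L,
                              input_size = if (backbone == "mnv3s-feat") 224L else 64L) {
  backbone <- match.arg(backbone)
  structure(list(backbone = backbone, eca = eca, gamma = gamma, b = b,
                 input_size = as.integer(input_size),
                 embedding_dim = if (backbone == "mnv3s-feat") 576L else 64L,
                 out_dim = 2L),
            class = "mr_arch_spec")
}

make_divisible <- function(v, divisor = 8) {
  nv <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

# seeded initializers (He-normal for conv, torch-style uniform for linear)
init_conv_w <- function(k, cin_per_group, cout) {
  fan_in <- k * k * cin_per_group
  matrix(stats::rnorm(k * k * cin_per_group * cout, sd = sqrt(2 / fan_in)),
         k * k * cin_per_group, cout)
}

init_linear <- function(cin, cout) {
  bound <- 1 / sqrt(cin)
  list(W = matrix(stats::runif(cin * cout, -bound, bound), cin, cout),
       b = stats::runif(cout, -bound, bound))
}

# builder state: growing list of layers with a cursor on the last id
mr_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env$last <- "input"
  env$n <- 0L
  env
}

bd_add <- function(.bd, op, id, inputs = .bd$last, ...) {
  .bd$n <- .bd$n + 1L
  .bd$layers[[id]] <- new_layer(id, op, inputs, ...)
  .bd$last <- id
  invisible(id)
}

bd_conv <- function(bd, id, cin, cout, k, stride = 1L, groups = 1L) {
  pad <- (k - 1L) %/% 2L
  bd_add(bd, "conv", id, k = as.integer(k), stride = as.integer(stride),
         pad = pad, groups = as.integer(groups),
         in_channels = as.integer(cin), out_channels = as.integer(cout),
         W = if (groups == 1L) init_conv_w(k, cin, cout)
             else matrix(stats::rnorm(k * k * cout, sd = sqrt(2 / (k * k))),
                         k * k, cout))
}

bd_bn <- function(bd, id, c) {
  bd_add(bd, "bn", id, channels = as.integer(c),
         gamma = rep(1, c), beta = rep(0, c),
         running_mean = rep(0, c), running_var = rep(1, c),
         eps = 1e-5, momentum = 0.1)
}

bd_act <- function(bd, id, kind) bd_add(bd, "act", id, kind = kind)

bd_se <- function(bd, id, c) {
  x_id <- bd$last
  sq <- make_divisible(c / 4)
  bd_add(bd, "gap", paste0(id, "_pool"), inputs = x_id)
  fc1 <- init_linear(c, sq)
  bd_add(bd, "linear", paste0(id, "_fc1"), in_features = c, out_features = sq,
         W = fc1$W, b = fc1$b)
  bd_act(bd, paste0(id, "_relu"), "relu")
  fc2 <- init_linear(sq, c)
  bd_add(bd, "linear", paste0(id, "_fc2"), in_features = sq, out_features = c,
         W = fc2$W, b = fc2$b)
  bd_act(bd, paste0(id, "_gate"), "hsigmoid")
  bd_add(bd, "scale", paste0(id, "_scale"), inputs = c(x_id, bd$last))
}

# one inverted-residual block of MobileNetV3
bd_bneck <- function(bd, id, cin, exp, cout, k, stride, se, act) {
  block_in <- bd$last
  if (exp != cin) {
    bd_conv(bd, paste0(id, "_expand"), cin, exp, 1L)
    bd_bn(bd, paste0(id, "_expand_bn"), exp)
    bd_act(bd, paste0(id, "_expand_act"), act)
  }
  bd_conv(bd, paste0(id, "_dw"), exp, exp, k, stride = stride, groups = exp)
  bd_bn(bd, paste0(id, "_dw_bn"), exp)
  bd_act(bd, paste0(id, "_dw_act"), act)
  if (se) bd_se(bd, paste0(id, "_se"), exp)
  bd_conv(bd, paste0(id, "_project"), exp, cout, 1L)
  bd_bn(bd, paste0(id, "_project_bn"), cout)
  if (stride == 1L && cin == cout) {
    bd_add(bd, "add", paste0(id, "_add"), inputs = c(bd$last, block_in))
  }
  invisible(bd)
}

# published MobileNetV3-Small block table, width 1.0:
# kernel, expansion, out channels, SE, activation, stride
mnv3s_blocks <- function() {
  list(
    list(3L, 16L, 16L, TRUE, "relu", 2L),
    list(3L, 72L, 24L, FALSE, "relu", 2L),
    list(3L, 88L, 24L, FALSE, "relu", 1L),
    list(5L, 96L, 40L, TRUE, "hswish", 2L),
    list(5L, 240L, 40L, TRUE, "hswish", 1L),
    list(5L, 240L, 40L, TRUE, "hswish", 1L),
    list(5L, 120L, 48L, TRUE, "hswish", 1L),
    list(5L, 144L, 48L, TRUE, "hswish", 1L),
    list(5L, 288L, 96L, TRUE, "hswish", 2L),
    list(5L, 576L, 96L, TRUE, "hswish", 1L),
    list(5L, 576L, 96L, TRUE, "hswish", 1L)
  )
}

#' Build the regression network
#'
#' Constructs the backbone, the optional ECA recalibration head and the
#' affine output map, with seeded from-scratch initialization (no pretrained
#' weights).
#'
#' @param spec an [architecture_spec()]
#' @param seed integer seed for weight initialization
#' @return an `mr_network`
#' @examples
#' net <- build_model(architecture_spec("tiny-cnn"), seed = 1)
#' net
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "mr_arch_spec")) stop("spec must be an architecture_spec()")
  withr::with_seed(as.integer(seed), {
    bd <- mr_builder()
    if (spec$backbone == "tiny-cnn") {
      # stride-4 stem, then two stride-2 stages: 64 px -> 16 -> 8 -> 4
      bd_conv(bd, "conv1", 3L, 16L, 5L, stride = 4L)
      bd_bn(bd, "bn1", 16L)
      bd_act(bd, "act1", "relu")
      bd_conv(bd, "conv2", 16L, 32L, 3L, stride = 2L)
      bd_bn(bd, "bn2", 32L)
      bd_act(bd, "act2", "relu")
      bd_conv(bd, "conv3", 32L, 64L, 3L, stride = 2L)
      bd_bn(bd, "bn3", 64L)
      bd_act(bd, "act3", "relu")
      C <- 64L
    } else {
      bd_conv(bd, "stem", 3L, 16L, 3L, stride = 2L)
      bd_bn(bd, "stem_bn", 16L)
      bd_act(bd, "stem_act", "hswish")
      cin <- 16L
      blocks <- mnv3s_blocks()
      for (i in seq_along(blocks)) {
        p <- blocks[[i]]
        bd_bneck(bd, paste0("b", i), cin, p[[2]], p[[3]], p[[1]], p[[6]],
                 p[[4]], p[[5]])
        cin <- p[[3]]
      }
      bd_conv(bd, "last_conv", cin, 576L, 1L)
      bd_bn(bd, "last_bn", 576L)
      bd_act(bd, "last_act", "hswish")
      C <- 576L
    }
    bd_add(bd, "gap", "embed")
    head_in <- "embed"
    if (spec$eca) {
      k <- eca_kernel_size(C, spec$gamma, spec$b)
      bd_add(bd, "conv1d_ch", "eca_conv", inputs = "embed",
             w = stats::rnorm(k, sd = 1 / sqrt(k)))
      bd_act(bd, "eca_gate", "sigmoid")
      bd_add(bd, "scale_vec", "eca_scale", inputs = c("embed", "eca_gate"))
      head_in <- "eca_scale"
    }
    hd <- init_linear(C, spec$out_dim)
    bd_add(bd, "linear", "head", inputs = head_in,
           in_features = C, out_features = spec$out_dim, W = hd$W, b = hd$b)
    new_network(bd$layers, embedding = "embed", output = "head", arch = spec)
  })
}

layer_param_count <- function(ly) {
  switch(ly$op,
    conv = length(ly$W),
    bn = 2L * ly$channels,
    linear = length(ly$W) + length(ly$b),
    conv1d_ch = length(ly$w),
    0L
  )
}

#' Static model accounting: parameters and multiply-accumulates
#'
#' Counts trainable parameters exactly and multiply-accumulate operations
#' (MACs) analytically per layer at a given input size. Convolutions and
#' affine maps contribute their arithmetic MACs; elementwise layers
#' (batch-norm inference scale-shift, activations, pooling, channel gating,
#' residual additions) are counted at one MAC per output element, the
#' convention of the common FLOP profilers. FLOPs are reported as exactly
#' `2 * macs`.
#'
#' @param net an `mr_network`
#' @param input_size square input resolution; defaults to the architecture's
#' @return object of class `mr_model_summary`: a list with `n_params`,
#'   `macs`, `flops`, and a per-layer tibble `layers`
#' @examples
#' s <- model_summary(build_model(architecture_spec("tiny-cnn"), seed = 1))
#' s$n_params
#' @export
model_summary <- function(net, input_size = net$arch$input_size) {
  shapes <- list(input = c(H = input_size, W = input_size, C = 3))
  rows <- list()
  for (ly in net$layers) {
    s_in <- shapes[[ly$inputs[1]]]
    out_shape <- s_in
    macs <- 0
    switch(ly$op,
      conv = {
        Ho <- (s_in["H"] + 2 * ly$pad - ly$k) %/% ly$stride + 1
        Wo <- (s_in["W"] + 2 * ly$pad - ly$k) %/% ly$stride + 1
        out_shape <- c(H = unname(Ho), W = unname(Wo), C = ly$out_channels)
        macs <- ly$k^2 * (ly$in_channels / ly$groups) * ly$out_channels * Ho * Wo
      },
      bn = macs <- prod(s_in),
      act = macs <- prod(s_in),
      add = macs <- prod(s_in),
      gap = {
        macs <- prod(s_in)
        out_shape <- c(C = unname(s_in["C"]))
      },
      scale = macs <- prod(s_in),
      scale_vec = macs <- prod(s_in),
      linear = {
        macs <- ly$in_features * ly$out_features
        out_shape <- c(C = ly$out_features)
      },
      conv1d_ch = macs <- length(ly$w) * s_in["C"]
    )
    shapes[[ly$id]] <- out_shape
    rows[[ly$id]] <- tibble::tibble(
      layer = ly$id, op = ly$op,
      out_shape = paste(out_shape, collapse = "x"),
      n_params = layer_param_count(ly), macs = unname(macs)
    )
  }
  layers <- dplyr::bind_rows(rows)
  total_macs <- sum(layers$macs)
  structure(
    list(n_params = sum(layers$n_params), macs = total_macs,
         flops = 2 * total_macs, input_size = input_size, layers = layers),
    class = "mr_model_summary"
  )
}

#' @export
print.mr_model_summary <- function(x, ...) {
  cat("<mr_model_summary> at", x$input_size, "px:",
      sprintf("%.2f M params, %.2f GFLOPs (%d MACs x 2)\n",
              x$n_params / 1e6, x$flops / 1e9, x$macs))
  invisible(x)
}

#' Per-layer accounting table of a model summary
#'
#' @param x an `mr_model_summary`
#' @param ... unused
#' @return tibble with one row per layer
#' @export
tidy.mr_model_summary <- function(x, ...) x$layers

#' One-row totals of a model summary
#'
#' @param x an `mr_model_summary`
#' @param ... unused
#' @return tibble with totals and the rounded reporting values
#' @export
glance.mr_model_summary <- function(x, ...) {
  tibble::tibble(n_params = x$n_params, macs = x$macs, flops = x$flops,
                 params_m = round(x$n_params / 1e6, 2),
                 gflops = round(x$flops / 1e9, 2),
                 input_size = x$input_size)
}

#' Turn a morphoreg object into a tidy tibble
#'
#' @param x object
#' @param ... method arguments
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/object summary
#'
#' @param x object
#' @param ... method arguments
#' @export
glance <- function(x, ...) UseMethod("glance")
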