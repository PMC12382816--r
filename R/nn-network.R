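# Network container and the forward/backward engine.
#
# A network (`mr_network`) is an ordered list of layer records executed
# topologically. Each record names its op, its input layer ids ("input" is
# the image batch), and holds its own parameters. Two tensor kinds flow
# through the graph: feature maps (`fm` records, see nn-ops.R) and channel
# descriptors (N x C matrices). The designated `embedding` layer output is
# the pooled feature vector z used by the contrastive regularizer; `output`
# is the regression prediction.

new_layer <- function(id, op, inputs, ...) {
  c(list(id = id, op = op, inputs = inputs), list(...))
}

is_fm <- function(x) is.list(x) && !is.null(x$m)

new_network <- function(layers, embedding, output, arch) {
  ids <- vapply(layers, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate layer ids")
  names(layers) <- ids
  structure(
    list(layers = layers, embedding = embedding, output = output, arch = arch),
    class = "mr_network"
  )
}

#' @export
print.mr_network <- function(x, ...) {
  s <- model_summary(x)
  cat("<mr_network> backbone:", x$arch$backbone,
      " layers:", length(x$layers),
      " params:", format(s$n_params, big.mark = ","), "\n")
  invisible(x)
}

layer_param_names <- function(layer) {
  switch(layer$op,
    conv = "W",
    bn = c("gamma", "beta"),
    linear = c("W", "b"),
    conv1d_ch = "w",
    character(0)
  )
}

# named list of trainable parameters, names "<layer id>.<param>"
net_params <- function(net) {
  out <- list()
  for (ly in net$layers) {
    for (p in layer_param_names(ly)) {
      out[[paste0(ly$id, ".", p)]] <- ly[[p]]
    }
  }
  out
}

net_set_params <- function(net, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    net$layers[[parts[1]]][[parts[2]]] <- params[[nm]]
  }
  net
}

#' Run a network forward
#'
#' @param net an `mr_network`
#' @param x input batch, array of dim `c(H, W, 3, N)`
#' @param training logical; `TRUE` uses batch statistics in batch-norm layers
#'   and the fused GEMM path, `FALSE` uses running statistics and the
#'   channel-ordered accumulation path (deterministic under channel removal)
#' @param keep_cache keep per-layer caches needed by backpropagation
#' @param exact use the channel-ordered accumulation path (default in eval
#'   mode); `FALSE` selects the fused GEMM path
#' @return list with `embedding` (N x D matrix), `output` (N x 2 matrix),
#'   and, when `keep_cache`, the internal activations and caches
#' @export
net_forward <- function(net, x, training = FALSE, keep_cache = training,
                        exact = !training) {
  stopifnot(length(dim(x)) == 4L)
  outs <- list(input = fm_from_array(x))
  caches <- if (keep_cache) list() else NULL
  new_stats <- list()
  for (ly in net$layers) {
    ins <- lapply(ly$inputs, function(i) outs[[i]])
    res <- switch(ly$op,
      conv = {
        r <- conv2d_forward(ins[[1]], ly$W, ly$k, ly$stride, ly$pad,
                            ly$groups, exact = exact)
        if (keep_cache) caches[[ly$id]] <- list(P = r$P, info = r$info)
        r$out
      },
      bn = {
        r <- bn_forward(ins[[1]], ly$gamma, ly$beta, ly$running_mean,
                        ly$running_var, ly$eps, ly$momentum, training)
        if (training) {
          new_stats[[ly$id]] <- list(mean = r$new_mean, var = r$new_var)
          if (keep_cache) caches[[ly$id]] <- list(mu = r$mu, istd = r$istd)
        }
        r$out
      },
      act = {
        xin <- ins[[1]]
        if (is_fm(xin)) {
          out <- fm(act_forward(xin$m, ly$kind), xin$H, xin$W, xin$N)
          if (keep_cache) caches[[ly$id]] <- list(x = xin$m, out = out$m)
        } else {
          out <- act_forward(xin, ly$kind)
          if (keep_cache) caches[[ly$id]] <- list(x = xin, out = out)
        }
        out
      },
      add = fm(ins[[1]]$m + ins[[2]]$m, ins[[1]]$H, ins[[1]]$W, ins[[1]]$N),
      gap = {
        if (keep_cache) caches[[ly$id]] <- list(f_in = ins[[1]])
        gap_forward(ins[[1]])
      },
      scale = {
        f <- ins[[1]]; g <- ins[[2]]
        if (keep_cache) caches[[ly$id]] <- list(f = f, g = g)
        fm(f$m * gate_rows(g, f$H * f$W), f$H, f$W, f$N)
      },
      scale_vec = {
        if (keep_cache) caches[[ly$id]] <- list(x = ins[[1]], g = ins[[2]])
        ins[[1]] * ins[[2]]
      },
      linear = {
        if (keep_cache) caches[[ly$id]] <- list(x = ins[[1]])
        linear_forward(ins[[1]], ly$W, ly$b, exact = exact)
      },
      conv1d_ch = {
        if (keep_cache) caches[[ly$id]] <- list(x = ins[[1]])
        conv1d_channel_forward(ins[[1]], ly$w)
      },
      stop("unknown op: ", ly$op)
    )
    outs[[ly$id]] <- res
  }
  list(embedding = outs[[net$embedding]], output = outs[[net$output]],
       outs = if (keep_cache) outs else NULL, caches = caches,
       bn_stats = new_stats)
}

# Backpropagation. `out_grads` is a named list of loss gradients w.r.t. the
# outputs of the named layers (typically the head and the embedding), each a
# plain matrix in the layer's output layout. Returns parameter gradients
# named as in net_params(). Gradients are not propagated into the image.
net_backward <- function(net, fw, out_grads) {
  acc <- out_grads
  grads <- list()
  outs <- fw$outs
  caches <- fw$caches
  push <- function(id, g) {
    if (id == "input") return(invisible(NULL))
    acc[[id]] <<- if (is.null(acc[[id]])) g else acc[[id]] + g
  }
  for (ly in rev(net$layers)) {
    g <- acc[[ly$id]]
    if (is.null(g)) next
    switch(ly$op,
      conv = {
        need_dx <- ly$inputs[1] != "input"
        r <- conv2d_backward(g, caches[[ly$id]], ly$W, ly$groups, need_dx)
        grads[[paste0(ly$id, ".W")]] <- r$dW
        if (need_dx) push(ly$inputs[1], r$dx)
      },
      bn = {
        r <- bn_backward(g, caches[[ly$id]], ly$gamma,
                         outs[[ly$inputs[1]]]$m)
        grads[[paste0(ly$id, ".gamma")]] <- r$dgamma
        grads[[paste0(ly$id, ".beta")]] <- r$dbeta
        push(ly$inputs[1], r$dx)
      },
      act = {
        cc <- caches[[ly$id]]
        push(ly$inputs[1], act_backward(g, cc$x, cc$out, ly$kind))
      },
      add = {
        push(ly$inputs[1], g)
        push(ly$inputs[2], g)
      },
      gap = push(ly$inputs[1], gap_backward(g, caches[[ly$id]]$f_in)),
      scale = {
        cc <- caches[[ly$id]]
        Mpos <- cc$f$H * cc$f$W
        push(ly$inputs[1], g * gate_rows(cc$g, Mpos))
        push(ly$inputs[2], fm_image_colsums(g * cc$f$m, Mpos, cc$f$N))
      },
      scale_vec = {
        cc <- caches[[ly$id]]
        push(ly$inputs[1], g * cc$g)
        push(ly$inputs[2], g * cc$x)
      },
      linear = {
        cc <- caches[[ly$id]]
        grads[[paste0(ly$id, ".W")]] <- crossprod(cc$x, g)
        grads[[paste0(ly$id, ".b")]] <- colSums(g)
        push(ly$inputs[1], tcrossprod(g, ly$W))
      },
      conv1d_ch = {
        r <- conv1d_channel_backward(g, caches[[ly$id]]$x, ly$w)
        grads[[paste0(ly$id, ".w")]] <- r$dw
        push(ly$inputs[1], r$dz)
      },
      stop("unknown op: ", ly$op)
    )
  }
  grads
}

# fold freshly computed batch-norm running statistics back into the network
net_update_bn <- function(net, bn_stats) {
  for (id in names(bn_stats)) {
    net$layers[[id]]$running_mean <- bn_stats[[id]]$mean
    net$layers[[id]]$running_var <- bn_stats[[id]]$var
  }
  net
}
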