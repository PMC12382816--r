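# Dependency-graph structured channel pruning.
#
# Every layer is decomposed into an input node and an output node. An
# undirected dependency graph connects a producer's output node to its
# consumers' input nodes (inter-layer edges) and joins a layer's own input
# and output nodes whenever the two share a pruning scheme (intra-layer
# edges: batch-norm, activations, residual adds, pooling, channel gating,
# depthwise convolution, the ECA channel convolution). Connected components
# of this graph are the indivisible dependency groups: all parameter slices
# in a group index the same channel space and must be pruned together.
#
# Groups containing the image input, the protected output head, or an ECA
# channel convolution (whose local cross-channel window makes channel
# removal non-exact) are marked unprunable. For prunable groups, zeroing
# index k across all member slices provably changes no network output, and
# the eval-mode forward's channel-ordered accumulation makes the subsequent
# physical removal bit-exact.

# ops whose input and output channel spaces coincide
channel_preserving_ops <- c("bn", "act", "add", "gap", "scale", "scale_vec",
                            "conv1d_ch")

#' Build the dependency graph of a network
#'
#' @param net an `mr_network`
#' @return object of class `mr_depgraph` wrapping an igraph graph
#' @export
build_dependency_graph <- function(net) {
  supported <- c("conv", "linear", channel_preserving_ops)
  from <- character(0); to <- character(0)
  for (ly in net$layers) {
    if (!ly$op %in% supported) {
      stop("unsupported op in dependency graph: ", ly$op, " (layer ", ly$id, ")")
    }
    for (p in ly$inputs) {
      from <- c(from, paste0(p, ":out"))
      to <- c(to, paste0(ly$id, ":in"))
    }
    intra <- ly$op %in% channel_preserving_ops ||
      (ly$op == "conv" && ly$groups > 1L)
    if (intra) {
      from <- c(from, paste0(ly$id, ":in"))
      to <- c(to, paste0(ly$id, ":out"))
    }
  }
  verts <- unique(c(from, to,
                    unlist(lapply(names(net$layers), function(id)
                      paste0(id, c(":in", ":out"))))))
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  structure(list(graph = g, net_layers = names(net$layers)),
            class = "mr_depgraph")
}

# channel-space size seen at a layer node
node_dim <- function(net, id, side) {
  ly <- net$layers[[id]]
  switch(ly$op,
    conv = if (side == "in") ly$in_channels else ly$out_channels,
    linear = if (side == "in") ly$in_features else ly$out_features,
    bn = ly$channels,
    NA_integer_
  )
}

#' Discover dependency groups
#'
#' Maximal connected subgraphs of the dependency graph. Each prunable group
#' lists its member parameter slices (layer, axis) over a common channel
#' index space of size K.
#'
#' @param net an `mr_network`
#' @param graph optionally a prebuilt [build_dependency_graph()]
#' @param protected layer ids whose output dimension must never be pruned;
#'   the regression head is always protected
#' @return list of class `mr_groups`; each element has `members` (tibble
#'   with `layer`, `axis`), `size`, `protected`
#' @export
find_groups <- function(net, graph = build_dependency_graph(net),
                        protected = character(0)) {
  protected <- union(protected, net$output)
  comp <- igraph::components(graph$graph)
  membership <- comp$membership
  groups <- list()
  for (ci in seq_len(comp$no)) {
    verts <- names(membership)[membership == ci]
    members <- list()
    sizes <- integer(0)
    is_protected <- FALSE
    for (v in verts) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1]]
      id <- parts[1]; side <- parts[2]
      if (id == "input") { is_protected <- TRUE; next }
      ly <- net$layers[[id]]
      if (ly$op == "conv1d_ch") is_protected <- TRUE
      if (id %in% protected && side == "out") is_protected <- TRUE
      axis <- NULL
      if (ly$op == "conv" && ly$groups == 1L) {
        axis <- side                                    # "in" or "out"
        sizes <- c(sizes, node_dim(net, id, side))
      } else if (ly$op == "conv" && ly$groups > 1L && side == "out") {
        axis <- "dw"                                    # joint in/out channel
        sizes <- c(sizes, ly$out_channels)
      } else if (ly$op == "bn" && side == "out") {
        axis <- "bn"
        sizes <- c(sizes, ly$channels)
      } else if (ly$op == "linear") {
        axis <- side
        sizes <- c(sizes, node_dim(net, id, side))
      }
      if (!is.null(axis)) {
        members[[length(members) + 1L]] <- tibble::tibble(layer = id,
                                                          axis = axis)
      }
    }
    if (length(members) == 0L) next
    sizes <- unique(sizes)
    if (length(sizes) != 1L) {
      stop("inconsistent channel-space sizes within a dependency group: ",
           paste(sizes, collapse = ", "))
    }
    groups[[length(groups) + 1L]] <- list(
      id = length(groups) + 1L,
      members = dplyr::bind_rows(members),
      size = sizes,
      protected = is_protected
    )
  }
  structure(groups, class = "mr_groups")
}

#' @export
print.mr_groups <- function(x, ...) {
  cat("<mr_groups>", length(x), "dependency groups (",
      sum(vapply(x, function(g) !g$protected, TRUE)), "prunable )\n")
  invisible(x)
}

# per-index squared-L2 contribution of one member slice
slice_sq_norms <- function(net, layer, axis) {
  ly <- net$layers[[layer]]
  switch(paste(ly$op, axis),
    "conv out" = colSums(ly$W^2),
    "conv in" = {
      k2 <- ly$k^2
      m <- array(ly$W^2, c(k2, ly$in_channels, ly$out_channels))
      apply(m, 2, sum)
    },
    "conv dw" = colSums(ly$W^2),
    "bn bn" = ly$gamma^2 + ly$beta^2,
    "linear in" = rowSums(ly$W^2),
    "linear out" = colSums(ly$W^2) + ly$b^2,
    stop("unknown member slice: ", ly$op, " ", axis)
  )
}

#' Group importance and adaptive shrinkage
#'
#' Importance of channel index k in a group is the summed squared L2 norm of
#' all member slices at k. The adaptive shrinkage is
#' `gamma_k = 2^(alpha * (I_max - I_k) / (I_max - I_min))` (all 1 when the
#' importances are constant), so low-importance indices are shrunk hardest.
#'
#' @param group one element of [find_groups()]
#' @param net the network
#' @param alpha shrinkage exponent
#' @return list of class `mr_group_importance` with `I`, `gamma`
#' @export
group_importance <- function(group, net, alpha = 2) {
  if (is.null(group$members) || nrow(group$members) == 0L) {
    stop("empty dependency group")
  }
  I <- numeric(group$size)
  for (r in seq_len(nrow(group$members))) {
    I <- I + slice_sq_norms(net, group$members$layer[r], group$members$axis[r])
  }
  rng <- range(I)
  gam <- if (rng[2] > rng[1]) 2^(alpha * (rng[2] - I) / (rng[2] - rng[1]))
         else rep(1, length(I))
  structure(list(I = I, gamma = gam, I_max = rng[2], I_min = rng[1]),
            class = "mr_group_importance")
}

#' Group-level sparsity penalty
#'
#' `R = lambda * sum_g sum_k gamma_k * I_{g,k}` over prunable groups, with
#' the shrinkage factors treated as constants at each evaluation.
#'
#' @param groups an `mr_groups`
#' @param net the network
#' @param alpha shrinkage exponent
#' @param lambda regularization strength
#' @return scalar penalty value
#' @export
sparsity_penalty <- function(groups, net, alpha = 2, lambda = 1e-4) {
  if (lambda == 0) return(0)
  tot <- 0
  for (g in groups) {
    if (g$protected) next
    gi <- group_importance(g, net, alpha)
    tot <- tot + sum(gi$gamma * gi$I)
  }
  lambda * tot
}

# gradient of the sparsity penalty w.r.t. each member parameter
# (dR/dw = 2 * lambda * gamma_k * w for every w in slice k)
sparsity_grads <- function(groups, net, alpha, lambda) {
  grads <- list()
  addg <- function(nm, g) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  }
  for (g in groups) {
    if (g$protected) next
    gi <- group_importance(g, net, alpha)
    mult <- 2 * lambda * gi$gamma
    for (r in seq_len(nrow(g$members))) {
      id <- g$members$layer[r]; axis <- g$members$axis[r]
      ly <- net$layers[[id]]
      switch(paste(ly$op, axis),
        "conv out" = addg(paste0(id, ".W"),
                          ly$W * rep(mult, each = nrow(ly$W))),
        "conv in" = {
          k2 <- ly$k^2
          rowmult <- rep(mult, each = k2)
          addg(paste0(id, ".W"), ly$W * rowmult)
        },
        "conv dw" = addg(paste0(id, ".W"),
                         ly$W * rep(mult, each = nrow(ly$W))),
        "bn bn" = {
          addg(paste0(id, ".gamma"), ly$gamma * mult)
          addg(paste0(id, ".beta"), ly$beta * mult)
        },
        "linear in" = addg(paste0(id, ".W"), ly$W * mult),
        "linear out" = {
          addg(paste0(id, ".W"), ly$W * rep(mult, each = nrow(ly$W)))
          addg(paste0(id, ".b"), ly$b * mult)
        }
      )
    }
  }
  grads
}

#' Pruning configuration
#'
#' @param global_ratio fraction of prunable channel indices to remove
#' @param alpha adaptive shrinkage exponent
#' @param reg_strength sparsity regularization lambda
#' @param sparsity_epochs epochs of group-sparsity retraining
#' @param finetune_epochs epochs of post-prune fine-tuning
#' @param finetune_lr fine-tuning learning rate
#' @param protected extra layer ids excluded from pruning (the head always
#'   is)
#' @return list of class `mr_prune_config`
#' @export
prune_config <- function(global_ratio = 0.45, alpha = 2, reg_strength = 1e-4,
                         sparsity_epochs = 10L, finetune_epochs = 30L,
                         finetune_lr = 1e-4, protected = character(0)) {
  if (global_ratio < 0 || global_ratio >= 1) stop("global_ratio must be in [0, 1)")
  structure(list(global_ratio = global_ratio, alpha = alpha,
                 reg_strength = reg_strength,
                 sparsity_epochs = as.integer(sparsity_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 finetune_lr = finetune_lr, protected = protected),
            class = "mr_prune_config")
}

# zero index set `ks` of a group across every member slice
zero_group_slices <- function(net, group, ks) {
  for (r in seq_len(nrow(group$members))) {
    id <- group$members$layer[r]; axis <- group$members$axis[r]
    ly <- net$layers[[id]]
    switch(paste(ly$op, axis),
      "conv out" = { ly$W[, ks] <- 0 },
      "conv in" = {
        k2 <- ly$k^2
        rows <- as.vector(outer(seq_len(k2), (ks - 1L) * k2, `+`))
        ly$W[rows, ] <- 0
      },
      "conv dw" = { ly$W[, ks] <- 0 },
      "bn bn" = {
        ly$gamma[ks] <- 0; ly$beta[ks] <- 0
        ly$running_mean[ks] <- 0; ly$running_var[ks] <- 1
      },
      "linear in" = { ly$W[ks, ] <- 0 },
      "linear out" = { ly$W[, ks] <- 0; ly$b[ks] <- 0 }
    )
    net$layers[[id]] <- ly
  }
  net
}

# physically remove all indices of a group except `keep`
slice_group <- function(net, group, keep) {
  for (r in seq_len(nrow(group$members))) {
    id <- group$members$layer[r]; axis <- group$members$axis[r]
    ly <- net$layers[[id]]
    switch(paste(ly$op, axis),
      "conv out" = {
        ly$W <- ly$W[, keep, drop = FALSE]
        ly$out_channels <- length(keep)
      },
      "conv in" = {
        k2 <- ly$k^2
        rows <- as.vector(outer(seq_len(k2), (keep - 1L) * k2, `+`))
        ly$W <- ly$W[rows, , drop = FALSE]
        ly$in_channels <- length(keep)
      },
      "conv dw" = {
        ly$W <- ly$W[, keep, drop = FALSE]
        ly$in_channels <- length(keep)
        ly$out_channels <- length(keep)
        ly$groups <- length(keep)
      },
      "bn bn" = {
        ly$gamma <- ly$gamma[keep]; ly$beta <- ly$beta[keep]
        ly$running_mean <- ly$running_mean[keep]
        ly$running_var <- ly$running_var[keep]
        ly$channels <- length(keep)
      },
      "linear in" = {
        ly$W <- ly$W[keep, , drop = FALSE]
        ly$in_features <- length(keep)
      },
      "linear out" = {
        ly$W <- ly$W[, keep, drop = FALSE]; ly$b <- ly$b[keep]
        ly$out_features <- length(keep)
      }
    )
    net$layers[[id]] <- ly
  }
  net
}

#' Execute structured pruning
#'
#' Ranks prunable channel indices globally by their group-normalized
#' importance (post-sparsity group L2 norm per index, divided by the group
#' mean so groups of different scale are comparable) and removes the lowest
#' until the global ratio is met, whole groups synchronously. Every group
#' retains at least one index (with a warning if the floor binds).
#'
#' @param net an `mr_network`
#' @param groups result of [find_groups()] on this exact network
#' @param config an [prune_config()]
#' @return list with the pruned `net` and a per-group `report` tibble
#' @export
execute_prune <- function(net, groups, config = prune_config()) {
  prunable <- Filter(function(g) !g$protected, groups)
  if (length(prunable) == 0L) stop("no prunable groups discovered")
  cand <- purrr::map_dfr(prunable, function(g) {
    gi <- group_importance(g, net, config$alpha)
    tibble::tibble(group = g$id, k = seq_len(g$size),
                   rel_importance = gi$I / max(mean(gi$I), 1e-300))
  })
  n_total <- nrow(cand)
  n_remove <- floor(config$global_ratio * n_total)
  cand <- dplyr::arrange(cand, .data$rel_importance)
  removed <- vector("list", length(groups))
  left <- vapply(groups, `[[`, 1L, "size")
  names(left) <- vapply(groups, `[[`, 1L, "id")
  taken <- 0L
  floored <- FALSE
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (taken >= n_remove) break
    gid <- as.character(cand$group[i])
    if (left[gid] <= 1L) { floored <- TRUE; next }
    sel[i] <- TRUE
    left[gid] <- left[gid] - 1L
    taken <- taken + 1L
  }
  if (floored) warning("pruning floor reached: some groups kept 1 index")
  drops <- split(cand$k[sel], cand$group[sel])
  report <- list()
  for (g in groups) {
    drop_k <- drops[[as.character(g$id)]]
    keep <- if (g$protected || is.null(drop_k)) seq_len(g$size)
            else setdiff(seq_len(g$size), drop_k)
    if (!g$protected && length(keep) < g$size) {
      net <- slice_group(net, g, sort(keep))
    }
    report[[length(report) + 1L]] <- tibble::tibble(
      group = g$id, protected = g$protected,
      size_before = g$size, size_after = length(keep)
    )
  }
  list(net = net, report = dplyr::bind_rows(report))
}

#' Group-sparsity retraining
#'
#' A short retraining of an already-trained network with the adaptive
#' group-level L2 penalty added to the task loss (the hybrid objective by
#' default), learning a consistent sparsity pattern inside each dependency
#' group before pruning.
#'
#' @param net trained `mr_network`
#' @param manifest,split,images as in [train_model()]
#' @param config an [prune_config()]
#' @param train_cfg task-loss training configuration (epochs overridden by
#'   `config$sparsity_epochs`)
#' @param amcr an [amcr_config()]
#' @return an `mr_fit` whose `net` carries the sparsified weights
#' @export
sparsify_train <- function(net, manifest, split, config = prune_config(),
                           train_cfg = train_config(), amcr = amcr_config(),
                           images = NULL) {
  groups <- find_groups(net, protected = config$protected)
  tc <- train_cfg
  tc$epochs <- config$sparsity_epochs
  train_model(net, manifest, split, tc, amcr, images = images,
              sparsity = list(groups = groups, alpha = config$alpha,
                              lambda = config$reg_strength))
}

#' Post-pruning fine-tuning
#'
#' Retrains the pruned network for a limited number of epochs at a small
#' learning rate on the hybrid loss; zero epochs return the network
#' untouched.
#'
#' @param net pruned `mr_network`
#' @param manifest,split,images as in [train_model()]
#' @param config an [prune_config()]
#' @param train_cfg base training configuration (lr and epochs overridden)
#' @param amcr an [amcr_config()]
#' @return an `mr_fit`
#' @export
finetune <- function(net, manifest, split, config = prune_config(),
                     train_cfg = train_config(), amcr = amcr_config(),
                     images = NULL) {
  if (config$finetune_epochs == 0L) {
    labels <- manifest[, c("length_cm", "weight_g")]
    std <- fit_label_standardizer(labels[split$idx[split$split == "train"], ])
    return(finish_fit(net, list(), std, NULL, train_cfg, amcr,
                      list(val = NA_real_)))
  }
  tc <- train_cfg
  tc$lr <- config$finetune_lr
  tc$epochs <- config$finetune_epochs
  train_model(net, manifest, split, tc, amcr, images = images)
}
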