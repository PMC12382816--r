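# Dependency-graph structured pruning.

test_that("chained convolutions couple producer-out with consumer-in", {
  net <- chain_net()
  groups <- find_groups(net)
  # find the group holding c1's out channels
  g1 <- Filter(function(g) any(g$members$layer == "c1" &
                                 g$members$axis == "out"), groups)[[1]]
  expect_equal(g1$size, 8L)
  expect_true(any(g1$members$layer == "c1_bn" & g1$members$axis == "bn"))
  expect_true(any(g1$members$layer == "c2" & g1$members$axis == "in"))
  expect_false(g1$protected)
})

test_that("groups partition the channel spaces exactly once", {
  for (backbone in c("tiny-cnn", "mnv3s-feat")) {
    net <- build_model(architecture_spec(backbone), seed = 1)
    groups <- find_groups(net)
    seen <- character(0)
    for (g in groups) {
      keys <- paste(g$members$layer, g$members$axis)
      expect_false(any(keys %in% seen))
      seen <- c(seen, keys)
    }
    # every parameterized layer contributes its prunable axes somewhere
    conv_layers <- names(Filter(function(l) l$op == "conv", net$layers))
    for (id in conv_layers) {
      expect_true(any(vapply(groups, function(g)
        any(g$members$layer == id), TRUE)), label = id)
    }
  }
})

test_that("depthwise convolution shares one channel space end to end", {
  net <- build_model(architecture_spec("mnv3s-feat"), seed = 1)
  groups <- find_groups(net)
  # block 4's expanded space: expand-out, depthwise, its bn, SE, project-in
  g <- Filter(function(g) any(g$members$layer == "b4_dw"), groups)[[1]]
  lys <- g$members$layer
  expect_true(all(c("b4_expand", "b4_dw", "b4_dw_bn", "b4_se_fc2",
                    "b4_project") %in% lys))
  expect_equal(g$size, 96L)
})

test_that("residual additions merge the coupled branch spaces", {
  net <- build_model(architecture_spec("mnv3s-feat"), seed = 1)
  groups <- find_groups(net)
  # blocks 4-6 share the 40-channel space through their skip connections
  g <- Filter(function(g) any(g$members$layer == "b4_project" &
                                g$members$axis == "out"), groups)[[1]]
  expect_true(any(g$members$layer == "b5_project" & g$members$axis == "out"))
  expect_true(any(g$members$layer == "b6_project" & g$members$axis == "out"))
  expect_equal(g$size, 40L)
})

test_that("input, head and ECA-fed spaces are protected", {
  net <- build_model(architecture_spec("tiny-cnn"), seed = 1)
  groups <- find_groups(net)
  prot <- Filter(function(g) g$protected, groups)
  expect_gte(length(prot), 3)   # input space, embedding space, head out
  emb <- Filter(function(g) any(g$members$layer == "conv3" &
                                  g$members$axis == "out"), groups)[[1]]
  expect_true(emb$protected)    # ECA's local window forbids exact pruning
})

test_that("unsupported ops fail loudly", {
  net <- chain_net()
  net$layers[["weird"]] <- morphoreg:::new_layer("weird", "softmax", "head")
  expect_error(build_dependency_graph(net), "softmax")
})

test_that("group importance and adaptive shrinkage follow the formula", {
  net <- chain_net()
  groups <- find_groups(net)
  g1 <- Filter(function(g) any(g$members$layer == "c1" &
                                 g$members$axis == "out"), groups)[[1]]
  # force known importances: zero all of c1's out slices except index 1
  net0 <- morphoreg:::zero_group_slices(net, g1, 2:8)
  gi <- group_importance(g1, net0, alpha = 2)
  expect_true(gi$I[1] > 0)
  expect_equal(gi$I[2:8], rep(0, 7))
  expect_equal(gi$gamma[1], 1)
  expect_equal(gi$gamma[2:8], rep(2^2, 7))
  # constant importances degrade to gamma = 1
  netc <- net
  netc$layers$c1$W[] <- 1
  netc$layers$c1_bn$gamma[] <- 1; netc$layers$c1_bn$beta[] <- 0
  netc$layers$c2$W[] <- 0.5
  gic <- group_importance(g1, netc, alpha = 2)
  expect_equal(gic$gamma, rep(1, 8))
  # alpha = 2 with normalized importances {0, 1} gives gamma {4, 1}
  expect_equal(2^(2 * (1 - c(0, 1)) / 1), c(4, 1))
})

test_that("sparsity penalty matches hand arithmetic on a toy net", {
  net <- chain_net()
  groups <- find_groups(net)
  expect_identical(sparsity_penalty(groups, net, alpha = 2, lambda = 0), 0)
  # gamma == 1 case: penalty is lambda * sum of importances
  netc <- net
  netc$layers$c1$W[] <- 2
  netc$layers$c1_bn$gamma[] <- 1; netc$layers$c1_bn$beta[] <- 0
  netc$layers$c2$W[] <- 1
  g1 <- Filter(function(g) any(g$members$layer == "c1" &
                                 g$members$axis == "out"), groups)[[1]]
  I_manual <- rep(3 * 3 * 3 * 4 +      # c1 out slice: 27 weights of 2 -> 108
                    1 + 0 +            # bn gamma^2 + beta^2
                    3 * 3 * 4 * 1,     # c2 in slice: 36 weights of 1
                  8)
  gi <- group_importance(g1, netc)
  expect_equal(gi$I, I_manual)
  # restrict to this group by zeroing the other prunable group's params
  lam <- 1e-3
  contrib <- lam * sum(gi$I)
  pen <- sparsity_penalty(list(g1), netc, alpha = 2, lambda = lam)
  expect_equal(pen, contrib)
})

test_that("group closure: zeroing a whole group silences it, a subset not", {
  net <- randomize_bn(build_model(architecture_spec("tiny-cnn"), seed = 4))
  x <- withr::with_seed(8, array(rnorm(64 * 64 * 3 * 3), c(64, 64, 3, 3)))
  base <- net_forward(net, x)$output
  groups <- find_groups(net)
  for (g in Filter(function(g) !g$protected, groups)) {
    k <- 2L
    netz <- morphoreg:::zero_group_slices(net, g, k)
    oz <- net_forward(netz, x)$output
    pruned <- morphoreg:::slice_group(netz, g, setdiff(seq_len(g$size), k))
    op <- net_forward(pruned, x)$output
    # completeness: the zeroed channel is dead, removal is bit-exact
    expect_identical(oz, op)
    # minimality: zeroing only the producer slice leaves live signal
    # (its batch-norm still emits a nonzero constant on that channel)
    sub <- g
    sub$members <- g$members[g$members$axis == "out", , drop = FALSE][1, ,
                                                                     drop = FALSE]
    netsub <- morphoreg:::zero_group_slices(net, sub, k)
    osub <- net_forward(netsub, x)$output
    prunedsub <- morphoreg:::slice_group(netsub, g,
                                         setdiff(seq_len(g$size), k))
    opsub <- net_forward(prunedsub, x)$output
    expect_false(identical(osub, opsub))
  }
})

test_that("execute_prune respects ratio, protection and the group floor", {
  net <- build_model(architecture_spec("tiny-cnn"), seed = 4)
  groups <- find_groups(net)
  p0 <- model_summary(net)$n_params
  # ratio 0: nothing changes
  r0 <- execute_prune(net, groups, prune_config(global_ratio = 0))
  expect_equal(model_summary(r0$net)$n_params, p0)
  expect_true(all(r0$report$size_before == r0$report$size_after))
  # ratio 0.45: >= 40% of parameters go
  r45 <- execute_prune(net, groups, prune_config(global_ratio = 0.45))
  p45 <- model_summary(r45$net)$n_params
  expect_lt(p45, 0.6 * p0)
  # forward still works at every stage
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  expect_equal(dim(net_forward(r45$net, x)$output), c(2, 2))
  # head and embedding untouched
  expect_equal(r45$net$layers$head$in_features, 64L)
  expect_equal(r45$net$layers$head$out_features, 2L)
  # extreme ratio triggers the keep-one floor
  expect_warning(execute_prune(net, groups, prune_config(global_ratio = 0.99)),
                 "floor")
})

test_that("pruned parameter count is deterministic", {
  net <- build_model(architecture_spec("tiny-cnn"), seed = 10)
  groups <- find_groups(net)
  a <- execute_prune(net, groups, prune_config(global_ratio = 0.45))
  b <- execute_prune(net, groups, prune_config(global_ratio = 0.45))
  expect_identical(model_summary(a$net)$n_params,
                   model_summary(b$net)$n_params)
  expect_identical(a$report, b$report)
})
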