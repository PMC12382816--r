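# Stratified splitting, metrics, the training loop, reporting.

test_that("stratified split honours ratios and determinism", {
  lab <- tibble::tibble(length_cm = rep(25, 10), weight_g = rep(400, 10))
  sp <- suppressWarnings(stratified_split(lab, seed = 1))
  expect_equal(as.vector(table(sp$split)), c(8, 1, 1))
  lab2 <- sample_labels(synth_config(), n = 400, seed = 31)
  sp2 <- stratified_split(lab2, seed = 5)
  expect_identical(sp2, stratified_split(lab2, seed = 5))
  expect_false(identical(sp2$split, stratified_split(lab2, seed = 6)$split))
  tab <- table(sp2$split)
  expect_equal(as.vector(tab) / 400, c(0.8, 0.1, 0.1), tolerance = 0.02)
  # split length means agree within one bin width
  bw <- diff(range(lab2$length_cm)) / 6
  mns <- tapply(lab2$length_cm, sp2$split, mean)
  expect_lt(max(mns) - min(mns), bw)
})

test_that("metrics reproduce hand arithmetic in physical units", {
  y_true <- tibble::tibble(length_cm = c(1, 2, 3), weight_g = c(1, 2, 3) * 1000)
  y_pred <- tibble::tibble(length_cm = c(2, 2, 2), weight_g = c(2, 2, 2) * 1000)
  m <- compute_metrics(y_true, y_pred)
  len <- m[m$target == "length", ]
  expect_equal(len$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(len$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(len$mape_percent, 100 / 3 * (1 + 0 + 1 / 3), tolerance = 1e-9)
  expect_equal(len$r2, 0)
  # weight reported in kg: same numbers here by construction
  wt <- m[m$target == "weight", ]
  expect_equal(wt$unit, "kg")
  expect_equal(wt$rmse, sqrt(2 / 3), tolerance = 1e-12)
  # perfect prediction
  mp <- compute_metrics(y_true, y_true)
  expect_equal(mp$rmse, c(0, 0))
  expect_equal(mp$r2, c(1, 1))
  expect_equal(mp$mape_percent, c(0, 0))
})

test_that("metric invariants hold on random data", {
  set.seed(77)
  for (i in 1:10) {
    y <- tibble::tibble(length_cm = runif(30, 18, 34),
                        weight_g = runif(30, 150, 900))
    p <- tibble::tibble(length_cm = y$length_cm + rnorm(30),
                        weight_g = y$weight_g + rnorm(30, sd = 40))
    m <- compute_metrics(y, p)
    expect_true(all(m$rmse >= m$mae))
    expect_true(all(m$r2 <= 1))
  }
  # zero-variance truth: R^2 undefined
  yz <- tibble::tibble(length_cm = rep(20, 5), weight_g = rep(300, 5))
  expect_warning(expect_warning(mz <- compute_metrics(yz, yz + 0.1),
                                "zero-variance"),
                 "zero-variance")   # one warning per degenerate target
  expect_true(all(is.na(mz$r2)))
})

test_that("an 8-sample toy set is overfit to a fraction of initial loss", {
  fx <- fixture_dataset(n = 10, seed = 57)
  sp <- suppressWarnings(stratified_split(fx$manifest, seed = 3))
  net <- build_model(architecture_spec("tiny-cnn"), seed = 3)
  tc <- train_config(lr = 5e-3, epochs = 50, batch_size = 8, loss = "l1",
                     augment = FALSE, seed = 4)
  fit <- train_model(net, fx$manifest, sp, tc, images = fx$images)
  h <- fit$history
  expect_lt(h$loss_l1[50], 0.1 * h$loss_l1[1])
})

test_that("training is bit-stable under a fixed seed", {
  fx <- fixture_dataset()
  sp <- stratified_split(fx$manifest, seed = 9)
  tc <- train_config(epochs = 2, batch_size = 16, loss = "l1+amcr", seed = 21)
  f1 <- train_model(build_model(architecture_spec("tiny-cnn"), seed = 2),
                    fx$manifest, sp, tc, images = fx$images)
  f2 <- train_model(build_model(architecture_spec("tiny-cnn"), seed = 2),
                    fx$manifest, sp, tc, images = fx$images)
  expect_identical(f1$history, f2$history)
  expect_identical(morphoreg:::net_params(f1$net),
                   morphoreg:::net_params(f2$net))
  # history carries the monitored traces
  expect_true(all(c("loss_total", "loss_l1", "loss_amcr", "val_l1_std",
                    "val_l1_phys", "collapse_rate") %in% names(f1$history)))
  expect_true(all(is.finite(f1$history$collapse_rate)))
})

test_that("the MSE baseline configuration runs without contrastive terms", {
  fx <- fixture_dataset()
  sp <- stratified_split(fx$manifest, seed = 9)
  net <- build_model(architecture_spec("tiny-cnn", eca = FALSE), seed = 2)
  tc <- train_config(epochs = 2, batch_size = 16, loss = "mse", seed = 3)
  fit <- train_model(net, fx$manifest, sp, tc, images = fx$images)
  expect_true(all(fit$history$loss_amcr == 0))
  expect_true(all(is.na(fit$history$collapse_rate)))
  p <- predict(fit, fx$images[1:3])
  expect_equal(dim(p), c(3L, 2L))
  expect_named(p, c("length_cm", "weight_g"))
})

test_that("collapse rate trends downward during training", {
  fx <- fixture_dataset(n = 400, seed = 73)
  sp <- stratified_split(fx$manifest, seed = 1)
  firsts <- c(); lasts <- c()
  for (seed in 1:3) {
    net <- build_model(architecture_spec("tiny-cnn"), seed = seed)
    tc <- train_config(epochs = 18, batch_size = 32, loss = "l1+amcr",
                       seed = seed)
    fit <- train_model(net, fx$manifest, sp, tc, images = fx$images)
    cr <- fit$history$collapse_rate
    firsts <- c(firsts, cr[1])
    lasts <- c(lasts, cr[18])
  }
  expect_lt(median(lasts), median(firsts))
})

test_that("reports round-trip metrics and write the expected artifacts", {
  fx <- fixture_dataset()
  sp <- stratified_split(fx$manifest, seed = 9)
  net <- build_model(architecture_spec("tiny-cnn"), seed = 2)
  tc <- train_config(epochs = 2, batch_size = 16, loss = "l1+amcr", seed = 3)
  fit <- train_model(net, fx$manifest, sp, tc, images = fx$images)
  test_idx <- sp$idx[sp$split == "test"]
  y_true <- fx$manifest[test_idx, c("length_cm", "weight_g")]
  y_pred <- predict(fit, fx$images[test_idx])
  out <- file.path(tempdir(), "mr-report")
  m <- report_results(fit, y_true, y_pred, out,
                      compare = list(baseline = y_true))
  for (f in c("metrics.json", "loss_curves.png", "pred_scatter.png",
              "error_hist.png")) {
    fp <- file.path(out, f)
    expect_true(file.exists(fp))
    expect_gt(file.size(fp), 0)
  }
  back <- jsonlite::read_json(file.path(out, "metrics.json"),
                              simplifyVector = TRUE)
  expect_equal(back$rmse, m$rmse, tolerance = 1e-9)
  expect_equal(back$target, m$target)
})

test_that("finetuning for zero epochs is the identity", {
  fx <- fixture_dataset()
  sp <- stratified_split(fx$manifest, seed = 9)
  net <- build_model(architecture_spec("tiny-cnn"), seed = 2)
  ft <- finetune(net, fx$manifest, sp,
                 prune_config(finetune_epochs = 0L),
                 train_config(epochs = 1, seed = 1), images = fx$images)
  expect_identical(morphoreg:::net_params(ft$net),
                   morphoreg:::net_params(net))
})

test_that("sparsity training shrinks low-importance channels hardest", {
  fx <- fixture_dataset()
  sp <- stratified_split(fx$manifest, seed = 9)
  net <- build_model(architecture_spec("tiny-cnn"), seed = 2)
  # control: lambda = 0 equals plain training
  tc <- train_config(epochs = 1, batch_size = 16, loss = "l1+amcr", seed = 13)
  pc0 <- prune_config(reg_strength = 0, sparsity_epochs = 1L)
  s0 <- sparsify_train(net, fx$manifest, sp, pc0, tc, images = fx$images)
  plain <- train_model(net, fx$manifest, sp, tc, images = fx$images)
  expect_equal(morphoreg:::net_params(s0$net),
               morphoreg:::net_params(plain$net), tolerance = 1e-12)
  # strong penalty: group norms shrink relative to the control
  pc <- prune_config(reg_strength = 5e-3, sparsity_epochs = 2L)
  tc2 <- train_config(epochs = 2, batch_size = 16, loss = "l1+amcr", seed = 13)
  s1 <- sparsify_train(net, fx$manifest, sp, pc, tc2, images = fx$images)
  groups <- find_groups(net)
  g <- Filter(function(g) !g$protected, groups)[[1]]
  I_before <- group_importance(g, net)$I
  I_after <- group_importance(g, s1$net)$I
  expect_lt(mean(I_after), mean(I_before))
  # gamma ordering: the least important index shrinks at least as much
  rel <- I_after / I_before
  expect_lte(rel[which.min(I_before)], max(rel))
})
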