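# helper: small labeled dataset where the class is separable from the mean
# of channel 1 (patch-level signal the network must pick up)
separable_patches <- function(n = 240, seed = 61) {
  set.seed(seed)
  lab <- rep(0:1, length.out = n)
  x <- array(rnorm(15 * 15 * 5 * n, sd = 0.5), dim = c(15, 15, 5, n))
  x[, , 1, lab == 1] <- x[, , 1, lab == 1] + 1.5
  structure(list(patches = x, labels = lab,
                 coords = data.frame(slice_id = 1L, row = 1L, col = 1L),
                 channel_stats = list(mean = rep(0, 5), sd = rep(1, 5)),
                 window = 15L, label_cut = 0.5),
            class = "patch_dataset")
}

test_that("the compact ResNet-18 has the stated topology", {
  net <- resnet18(base_filters = 8, in_channels = 5, seed = 1)
  expect_length(net$blocks, 8)                    # 2 blocks x 4 stages
  widths <- vapply(net$blocks, function(b) ncol(b$conv2$W), integer(1))
  expect_equal(widths, rep(c(8L, 16L, 32L, 64L), each = 2))
  strides <- vapply(net$blocks, `[[`, integer(1), "stride")
  expect_equal(strides, c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L))
  # stride-2 stages use projection shortcuts, identity elsewhere
  expect_null(net$blocks[[1]]$proj)
  expect_false(is.null(net$blocks[[3]]$proj))
  x <- array(rnorm(15 * 15 * 5 * 3), dim = c(15, 15, 5, 3))
  f <- habitatmap:::.net_fwd(net, x, training = FALSE)
  expect_equal(dim(f$logits), c(2L, 3L))
})

test_that("training is deterministic given the config seed", {
  ds <- separable_patches()
  cfg <- train_config(max_epochs = 1, batch_size = 64, seed = 99)
  m1 <- train_hypoxia_cnn(ds, ds, cfg)
  m2 <- train_hypoxia_cnn(ds, ds, cfg)
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_identical(m1$net$fc$W, m2$net$fc$W)
})

test_that("single-class training labels are rejected with advice", {
  ds <- separable_patches(60)
  ds$labels <- rep(0L, 60)
  expect_error(train_hypoxia_cnn(ds, ds, train_config(max_epochs = 1)),
               "single-class")
})

test_that("the network learns a separable patch problem", {
  ds <- separable_patches(480)
  val <- separable_patches(80, seed = 62)
  cfg <- train_config(max_epochs = 10, batch_size = 32, seed = 7,
                      initial_lr = 1e-3, augment = NULL)
  model <- train_hypoxia_cnn(ds, val, cfg)
  prob <- habitatmap:::.predict_prob(model, val$patches)
  expect_true(all(prob >= 0 & prob <= 1))
  acc <- mean((prob >= 0.5) == (val$labels == 1))
  expect_gt(acc, 0.9)
  # validation loss decreased over training
  expect_lt(tail(model$history$val_loss, 1), model$history$val_loss[1])
})

test_that("with constant channels the model predicts the class prior", {
  set.seed(63)
  n <- 200
  ds <- separable_patches(n)
  ds$patches <- array(1, dim = dim(ds$patches))     # no signal at all
  ds$labels <- as.integer(runif(n) < 0.7)
  cfg <- train_config(max_epochs = 25, batch_size = 64, seed = 3,
                      initial_lr = 1e-2, augment = NULL,
                      early_stop_patience = 50)
  model <- train_hypoxia_cnn(ds, ds, cfg)
  prob <- habitatmap:::.predict_prob(model, ds$patches[, , , 1:10, drop = FALSE])
  expect_equal(mean(prob), mean(ds$labels), tolerance = 0.1)
  expect_lt(diff(range(prob)), 1e-6)                # identical inputs, one output
})

test_that("augmentation permutes or resamples window content, preserving labels", {
  set.seed(64)
  x <- array(seq_len(15 * 15 * 5 * 4), dim = c(15, 15, 5, 4))
  # flips and right-angle rotations are pure permutations of each patch
  xa <- habitatmap:::.augment_batch(x, list(hflip = TRUE, vflip = TRUE,
                                            rot = TRUE, shift = 0, zoom = 0))
  for (n in 1:4)
    expect_setequal(as.vector(xa[, , , n]), as.vector(x[, , , n]))
  # shifts and zooms resample from within the same patch (no new values)
  xb <- habitatmap:::.augment_batch(x, list(shift = 2L, zoom = 0.1))
  for (n in 1:4)
    expect_true(all(xb[, , , n] %in% x[, , , n]))
})

test_that("the learning-rate schedule decays by 0.2 after 10 stale epochs", {
  ds <- separable_patches(40)
  cfg <- train_config(max_epochs = 14, batch_size = 40, seed = 5, augment = NULL,
                      initial_lr = 1e-4, lr_patience = 3, early_stop_patience = 50)
  # with a tiny plateauing problem the lr column must show factor-0.2 steps
  model <- suppressWarnings(train_hypoxia_cnn(ds, ds, cfg))
  lrs <- unique(model$history$lr)
  expect_true(all(abs(lrs / lrs[1] - 0.2^(seq_along(lrs) - 1)) < 1e-12))
})
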