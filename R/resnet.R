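# Compact ResNet-18 for 15x15 multiparametric patches.
#
# CIFAR-style variant of the 18-layer residual topology: a 3x3 stem
# convolution (no 7x7/max-pool, appropriate for 15x15 inputs), four stages
# of two basic residual blocks each with stride-2 downsampling between
# stages, global average pooling and a 2-way softmax head. Filter widths are
# base_filters * (1, 2, 4, 8) - "a small number of filters" per stage.
# All tensors are (H, W, C, N) R arrays; the heavy lifting (im2col GEMM
# convolutions, batch norm) is done in compiled code.

.new_conv <- function(cin, cout, ks) {
  list(W = matrix(rnorm(ks * ks * cin * cout, sd = sqrt(2 / (ks * ks * cin))),
                  ks * ks * cin, cout),
       ks = as.integer(ks))
}

.new_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c))
}

.new_block <- function(cin, cout, stride) {
  bl <- list(stride = as.integer(stride),
             conv1 = .new_conv(cin, cout, 3), bn1 = .new_bn(cout),
             conv2 = .new_conv(cout, cout, 3), bn2 = .new_bn(cout),
             proj = NULL)
  if (stride != 1L || cin != cout)
    bl$proj <- list(conv = .new_conv(cin, cout, 1), bn = .new_bn(cout))
  bl
}

#' Construct an untrained compact ResNet-18 patch classifier
#'
#' @param base_filters filters in the first stage; stages use
#'   `base_filters * c(1, 2, 4, 8)`.
#' @param in_channels number of input channels (5 MR channels).
#' @param seed RNG seed for weight initialization.
#' @return network object of class `resnet18`.
#' @export
resnet18 <- function(base_filters = 8L, in_channels = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bf <- as.integer(base_filters)
  widths <- bf * c(1L, 2L, 4L, 8L)
  blocks <- list()
  cin <- bf
  for (st in 1:4) {
    stride <- if (st == 1) 1L else 2L
    blocks[[length(blocks) + 1L]] <- .new_block(cin, widths[st], stride)
    blocks[[length(blocks) + 1L]] <- .new_block(widths[st], widths[st], 1L)
    cin <- widths[st]
  }
  structure(list(
    stem = list(conv = .new_conv(in_channels, bf, 3), bn = .new_bn(bf)),
    blocks = blocks,
    fc = list(W = matrix(rnorm(widths[4] * 2, sd = sqrt(1 / widths[4])),
                         widths[4], 2),
              b = rep(0, 2)),
    base_filters = bf, in_channels = as.integer(in_channels)),
    class = "resnet18")
}

.bn_apply <- function(bn, x, training, momentum = 0.1) {
  bn_fwd(x, bn$gamma, bn$beta, bn$rmean, bn$rvar,
         eps = 1e-5, momentum = momentum, training = training)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# convolution forward with im2col caching for the backward pass; large col
# matrices (early stages at full batch) are cheaper to recompute than to
# keep alive across the whole backward sweep
.conv_cached <- function(x, W, ks, stride, pad, training) {
  d <- dim(x)
  P <- prod(d[1:2], d[4])  # upper bound on output positions
  keep <- training && (P * nrow(W) < 3e6)
  conv2d_fwd_full(x, W, as.integer(ks), as.integer(stride), as.integer(pad),
                  keep)
}

# forward through one residual block; returns output, cache and updated block
.block_fwd <- function(bl, x, training, momentum) {
  c1 <- .conv_cached(x, bl$conv1$W, 3, bl$stride, 1, training)
  f1 <- .bn_apply(bl$bn1, c1$y, training, momentum)
  r1 <- .relu(f1$y)
  c2 <- .conv_cached(r1, bl$conv2$W, 3, 1, 1, training)
  f2 <- .bn_apply(bl$bn2, c2$y, training, momentum)
  if (is.null(bl$proj)) {
    scy <- x
    fsc <- NULL
    csc <- NULL
  } else {
    csc <- .conv_cached(x, bl$proj$conv$W, 1, bl$stride, 0, training)
    fsc <- .bn_apply(bl$proj$bn, csc$y, training, momentum)
    scy <- fsc$y
  }
  pre <- f2$y + scy
  out <- .relu(pre)
  if (training) {
    bl$bn1$rmean <- f1$rmean; bl$bn1$rvar <- f1$rvar
    bl$bn2$rmean <- f2$rmean; bl$bn2$rvar <- f2$rvar
    if (!is.null(fsc)) { bl$proj$bn$rmean <- fsc$rmean; bl$proj$bn$rvar <- fsc$rvar }
  }
  cache <- if (training) list(x = x, f1 = f1[c("xhat", "invstd")], b1y = f1$y,
                              r1 = r1, f2 = f2[c("xhat", "invstd")],
                              fsc = if (is.null(fsc)) NULL else fsc[c("xhat", "invstd")],
                              pre = pre, col1 = c1$col, col2 = c2$col,
                              colsc = if (is.null(csc)) NULL else csc$col) else NULL
  list(out = out, cache = cache, block = bl)
}

.block_bwd <- function(bl, cache, dout) {
  dpre <- dout * (cache$pre > 0)
  # main branch
  b2 <- bn_bwd(dpre, cache$f2$xhat, cache$f2$invstd, bl$bn2$gamma)
  c2 <- conv2d_bwd(cache$r1, bl$conv2$W, b2$dx, 3L, 1L, 1L, cache$col2)
  dr1 <- c2$dx * (cache$b1y > 0)
  b1 <- bn_bwd(dr1, cache$f1$xhat, cache$f1$invstd, bl$bn1$gamma)
  c1 <- conv2d_bwd(cache$x, bl$conv1$W, b1$dx, 3L, bl$stride, 1L, cache$col1)
  grads <- list(conv1 = list(W = c1$dw),
                bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2 = list(W = c2$dw),
                bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  if (is.null(bl$proj)) {
    dx <- c1$dx + dpre
  } else {
    bs <- bn_bwd(dpre, cache$fsc$xhat, cache$fsc$invstd, bl$proj$bn$gamma)
    cs <- conv2d_bwd(cache$x, bl$proj$conv$W, bs$dx, 1L, bl$stride, 0L, cache$colsc)
    grads$proj <- list(conv = list(W = cs$dw),
                       bn = list(gamma = bs$dgamma, beta = bs$dbeta))
    dx <- c1$dx + cs$dx
  }
  list(dx = dx, grads = grads)
}

# full network forward; x is (H, W, C, N)
.net_fwd <- function(net, x, training = FALSE, momentum = 0.1) {
  c0 <- .conv_cached(x, net$stem$conv$W, 3, 1, 1, training)
  f0 <- .bn_apply(net$stem$bn, c0$y, training, momentum)
  h <- .relu(f0$y)
  caches <- vector("list", length(net$blocks))
  stem_cache <- if (training) list(x = x, f0 = f0[c("xhat", "invstd")],
                                   b0y = f0$y, col0 = c0$col) else NULL
  if (training) {
    net$stem$bn$rmean <- f0$rmean; net$stem$bn$rvar <- f0$rvar
  }
  for (i in seq_along(net$blocks)) {
    res <- .block_fwd(net$blocks[[i]], h, training, momentum)
    h <- res$out
    caches[[i]] <- res$cache
    net$blocks[[i]] <- res$block
  }
  d <- dim(h)
  gap <- matrix(colMeans(matrix(h, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  logits <- crossprod(net$fc$W, gap) + net$fc$b   # 2 x N
  list(net = net, logits = logits,
       cache = if (training) list(stem = stem_cache, blocks = caches,
                                  gap = gap, hdim = d) else NULL)
}

.net_bwd <- function(net, cache, dlogits) {
  dW_fc <- cache$gap %*% t(dlogits)
  db_fc <- rowSums(dlogits)
  dgap <- net$fc$W %*% dlogits                   # C x N
  d <- cache$hdim
  dh <- array(rep(as.vector(dgap), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  grads_blocks <- vector("list", length(net$blocks))
  for (i in rev(seq_along(net$blocks))) {
    res <- .block_bwd(net$blocks[[i]], cache$blocks[[i]], dh)
    grads_blocks[[i]] <- res$grads
    dh <- res$dx
  }
  dr0 <- dh * (cache$stem$b0y > 0)
  b0 <- bn_bwd(dr0, cache$stem$f0$xhat, cache$stem$f0$invstd, net$stem$bn$gamma)
  c0 <- conv2d_bwd(cache$stem$x, net$stem$conv$W, b0$dx, 3L, 1L, 1L,
                   cache$stem$col0)
  list(stem = list(conv = list(W = c0$dw),
                   bn = list(gamma = b0$dgamma, beta = b0$dbeta)),
       blocks = grads_blocks,
       fc = list(W = dW_fc, b = db_fc))
}

# ---- parameter tree helpers -------------------------------------------------

.param_names <- c("W", "b", "gamma", "beta")

.skip_names <- c("rmean", "rvar", "ks", "stride", "base_filters", "in_channels")

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    nms <- names(a)
    out <- a
    for (i in seq_along(a)) {
      nm <- if (is.null(nms)) "" else nms[i]
      if (is.null(a[[i]]) || nm %in% .skip_names) next
      bi <- if (nzchar(nm)) b[[nm]] else b[[i]]
      if (is.null(bi)) next
      out[[i]] <- .tree_map2(f, a[[i]], bi)
    }
    out
  } else if (is.numeric(a)) f(a, b) else a
}

.tree_zero <- function(a) .tree_map2(function(x, y) x * 0, a, a)

.net_params <- function(net) list(stem = net$stem, blocks = net$blocks, fc = net$fc)

.net_set_params <- function(net, p) {
  # merge trainables back, keeping buffers (running stats) from `net`
  merge <- function(dst, src) {
    if (!is.list(dst)) return(dst)
    nms <- names(dst)
    for (i in seq_along(dst)) {
      nm <- if (is.null(nms)) "" else nms[i]
      if (is.null(dst[[i]]) || is.null(src[[i]])) next
      if (nm %in% .param_names) dst[[i]] <- src[[i]]
      else if (is.list(dst[[i]])) dst[[i]] <- merge(dst[[i]], src[[i]])
    }
    dst
  }
  net$stem <- merge(net$stem, p$stem)
  net$blocks <- merge(net$blocks, p$blocks)
  net$fc <- merge(net$fc, p$fc)
  net
}

# Adam step over the parameter tree; state holds m, v, t
.adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  p <- .net_params(net)
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  upd <- .tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  p <- .tree_map2(function(w, u) w - lr * u, p, upd)
  list(net = .net_set_params(net, p), state = state)
}

# ---- loss and batching ------------------------------------------------------

# binary cross entropy through a 2-way softmax with one-hot labels
.softmax_ce <- function(logits, labels) {
  z <- sweep(logits, 2, pmax(logits[1, ], logits[2, ]), `-`)
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), `/`)
  n <- ncol(p)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, 2, n)
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / n, prob = p[2, ])
}

# data augmentation on a (H, W, C, N) batch: per-sample random flips,
# right-angle rotation, integer shifts (edge clamp) and nearest-neighbour
# zoom. Labels are untouched: every transform permutes/resamples the window
# around the same center, preserving label semantics.
.augment_batch <- function(x, aug) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  for (n in seq_len(d[4])) {
    slab <- x[, , , n, drop = FALSE]
    dim(slab) <- d[1:3]
    if (isTRUE(aug$hflip) && runif(1) < 0.5) slab <- slab[, W:1, , drop = FALSE]
    if (isTRUE(aug$vflip) && runif(1) < 0.5) slab <- slab[H:1, , , drop = FALSE]
    if (isTRUE(aug$rot)) {
      k <- sample(0:3, 1)
      if (k > 0) for (i in seq_len(k)) {
        slab <- aperm(slab, c(2, 1, 3))[H:1, , , drop = FALSE]
      }
    }
    if (!is.null(aug$shift) && aug$shift > 0) {
      dr <- sample(-aug$shift:aug$shift, 1)
      dc <- sample(-aug$shift:aug$shift, 1)
      ri <- pmin(pmax(seq_len(H) + dr, 1), H)
      ci <- pmin(pmax(seq_len(W) + dc, 1), W)
      slab <- slab[ri, ci, , drop = FALSE]
    }
    if (!is.null(aug$zoom) && aug$zoom > 0) {
      f <- runif(1, 1 - aug$zoom, 1 + aug$zoom)
      cR <- (H + 1) / 2; cC <- (W + 1) / 2
      ri <- pmin(pmax(round(cR + (seq_len(H) - cR) / f), 1), H)
      ci <- pmin(pmax(round(cC + (seq_len(W) - cC) / f), 1), W)
      slab <- slab[ri, ci, , drop = FALSE]
    }
    x[, , , n] <- slab
  }
  x
}

#' Training configuration for the hypoxia patch classifier
#'
#' Defaults follow the published training recipe: binary cross entropy loss,
#' Adam with initial learning rate 1e-4 decayed by a factor of 0.2 when the
#' validation loss has not improved for 10 epochs, and shift / flip /
#' rotation / zoom augmentation. Epoch count, batch size and filter widths
#' are engineering choices exposed here.
#'
#' @param initial_lr initial Adam learning rate.
#' @param lr_decay_factor multiplicative LR decay.
#' @param lr_patience epochs without validation improvement before decay.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (best-validation weights are always restored).
#' @param batch_size minibatch size.
#' @param base_filters filters in the first residual stage.
#' @param augment list of augmentation switches: `hflip`, `vflip`, `rot`
#'   (logical), `shift` (max pixels), `zoom` (max relative factor). Set to
#'   `NULL` to disable augmentation.
#' @param seed RNG seed controlling initialization, shuffling, augmentation.
#' @param verbose print per-epoch losses.
#' @return list of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, lr_decay_factor = 0.2,
                         lr_patience = 10L, max_epochs = 30L,
                         early_stop_patience = 20L, batch_size = 128L,
                         base_filters = 8L,
                         augment = list(hflip = TRUE, vflip = TRUE, rot = TRUE,
                                        shift = 2L, zoom = 0.1),
                         seed = 1L, verbose = FALSE) {
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 base_filters = as.integer(base_filters),
                 augment = augment, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

.forward_loss <- function(net, ds, batch_size = 2048L) {
  n <- length(ds$labels)
  tot <- 0
  for (i in seq(1L, n, by = batch_size)) {
    j <- seq(i, min(i + batch_size - 1L, n))
    xb <- ds$patches[, , , j, drop = FALSE]
    fw <- .net_fwd(net, xb, training = FALSE)
    tot <- tot + .softmax_ce(fw$logits, ds$labels[j])$loss * length(j)
  }
  tot / n
}

#' Train the hypoxia patch classifier
#'
#' Trains the compact ResNet-18 on labeled mpMRI patches with binary cross
#' entropy (2-way softmax on one-hot labels), the Adam optimizer, the stated
#' learning-rate schedule and augmentation. The weights with the best
#' validation loss are retained; the per-epoch training curve is kept in the
#' returned model.
#'
#' @param train_ds,val_ds `patch_dataset`s; `val_ds` should be standardized
#'   with `train_ds$channel_stats`.
#' @param cfg a [train_config()].
#' @return model of class `hypoxia_cnn`: the network, the training channel
#'   statistics, the config and the epoch history.
#' @export
train_hypoxia_cnn <- function(train_ds, val_ds, cfg = train_config()) {
  stopifnot(inherits(train_ds, "patch_dataset"), inherits(val_ds, "patch_dataset"))
  if (length(unique(train_ds$labels)) < 2L)
    stop("training labels are single-class; regenerate or enlarge the training data")
  set.seed(cfg$seed)
  net <- resnet18(cfg$base_filters, dim(train_ds$patches)[3])
  state <- list(m = .tree_zero(.net_params(net)),
                v = .tree_zero(.net_params(net)), t = 0L)
  n <- length(train_ds$labels)
  lr <- cfg$initial_lr
  best_val <- Inf
  best_params <- .net_params(net)
  best_buffers <- NULL
  since_best <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (i in seq(1L, n, by = cfg$batch_size)) {
      j <- perm[seq(i, min(i + cfg$batch_size - 1L, n))]
      xb <- train_ds$patches[, , , j, drop = FALSE]
      if (!is.null(cfg$augment)) xb <- .augment_batch(xb, cfg$augment)
      fw <- .net_fwd(net, xb, training = TRUE)
      net <- fw$net
      sc <- .softmax_ce(fw$logits, train_ds$labels[j])
      ep_loss <- ep_loss + sc$loss * length(j)
      grads <- .net_bwd(net, fw$cache, sc$dlogits)
      upd <- .adam_step(net, grads, state, lr)
      net <- upd$net
      state <- upd$state
    }
    ep_loss <- ep_loss / n
    val_loss <- .forward_loss(net, val_ds)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = val_loss, lr = lr))
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, ep_loss, val_loss, lr))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss
      best_params <- .net_params(net)
      best_buffers <- list(stem = net$stem$bn[c("rmean", "rvar")],
                           blocks = lapply(net$blocks, function(b) list(
                             bn1 = b$bn1[c("rmean", "rvar")],
                             bn2 = b$bn2[c("rmean", "rvar")],
                             proj = if (is.null(b$proj)) NULL else
                               b$proj$bn[c("rmean", "rvar")])))
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > 0L && since_best %% cfg$lr_patience == 0L)
        lr <- lr * cfg$lr_decay_factor
      if (since_best >= cfg$early_stop_patience) break
    }
  }
  net <- .net_set_params(net, best_params)
  if (!is.null(best_buffers)) {
    net$stem$bn$rmean <- best_buffers$stem$rmean
    net$stem$bn$rvar <- best_buffers$stem$rvar
    for (i in seq_along(net$blocks)) {
      net$blocks[[i]]$bn1$rmean <- best_buffers$blocks[[i]]$bn1$rmean
      net$blocks[[i]]$bn1$rvar <- best_buffers$blocks[[i]]$bn1$rvar
      net$blocks[[i]]$bn2$rmean <- best_buffers$blocks[[i]]$bn2$rmean
      net$blocks[[i]]$bn2$rvar <- best_buffers$blocks[[i]]$bn2$rvar
      if (!is.null(net$blocks[[i]]$proj)) {
        net$blocks[[i]]$proj$bn$rmean <- best_buffers$blocks[[i]]$proj$rmean
        net$blocks[[i]]$proj$bn$rvar <- best_buffers$blocks[[i]]$proj$rvar
      }
    }
  }
  structure(list(net = net, channel_stats = train_ds$channel_stats,
                 channel_names = mp_channels, window = train_ds$window,
                 label_cut = train_ds$label_cut, cfg = cfg,
                 history = hist, cutoff = NA_real_),
            class = "hypoxia_cnn")
}

# predict class-1 (hypoxic) probabilities for a patch dataset
.predict_prob <- function(model, patches, batch_size = 2048L) {
  n <- dim(patches)[4]
  out <- numeric(n)
  for (i in seq(1L, n, by = batch_size)) {
    j <- seq(i, min(i + batch_size - 1L, n))
    xb <- patches[, , , j, drop = FALSE]
    fw <- .net_fwd(model$net, xb, training = FALSE)
    out[j] <- .softmax_ce(fw$logits, rep(0L, length(j)))$prob
  }
  out
}
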