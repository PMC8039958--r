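# Independent brute-force oracles used across the suite. These deliberately
# use naive scalar loops so they share no code path with the implementation.

# even-odd point-in-polygon + Bresenham ring, parity (XOR) across polygons
oracle_rasterize <- function(poly) {
  nr <- poly$canvas_shape[1]; nc <- poly$canvas_shape[2]
  out <- matrix(FALSE, nr, nc)
  for (p in poly$polygons) {
    if (nrow(p) < 3) next
    m <- matrix(FALSE, nr, nc)
    V <- nrow(p)
    for (y in 0:(nr - 1)) for (x in 0:(nc - 1)) {
      cnt <- 0
      for (i in seq_len(V)) {
        j <- i %% V + 1
        r1 <- p[i, 1]; c1 <- p[i, 2]; r2 <- p[j, 1]; c2 <- p[j, 2]
        if ((r1 <= y && r2 > y) || (r2 <= y && r1 > y)) {
          xi <- c1 + (y - r1) * (c2 - c1) / (r2 - r1)
          if (xi > x) cnt <- cnt + 1
        }
      }
      if (cnt %% 2 == 1) m[y + 1, x + 1] <- TRUE
    }
    for (i in seq_len(V)) {
      j <- i %% V + 1
      seg <- bresenham_line(p[i, ], p[j, ])
      keep <- seg[, 1] >= 0 & seg[, 1] < nr & seg[, 2] >= 0 & seg[, 2] < nc
      m[seg[keep, , drop = FALSE] + 1] <- TRUE
    }
    out <- xor(out, m)
  }
  out
}

# exhaustive 256-candidate between-class variance maximizer from raw pixels
oracle_otsu <- function(gray, tissue) {
  g <- gray[tissue]
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 1:255) {
    g0 <- g[g < t]; g1 <- g[g >= t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(g); w1 <- 1 - w0
    v <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# per-pixel scalar loops for the DCE maps
oracle_dce <- function(series) {
  d <- dim(series$signal)
  auc <- slope <- ttm <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- series$signal[i, j, ]
    auc[i, j] <- sum(s)
    if (all(is.na(s))) next
    imax <- which.max(s)               # earliest maximum
    b <- series$baseline_index
    dt <- series$times[imax] - series$times[b]
    ttm[i, j] <- dt
    slope[i, j] <- if (dt == 0) 0 else (s[imax] - s[b]) / dt
  }
  list(auc = auc, slope = slope, ttm = ttm)
}

# pairwise Mann-Whitney AUROC with half-credit for ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive threshold scan for the Youden index (rule: positive if >= t)
oracle_youden <- function(scores, labels) {
  best <- list(cutoff = NA_real_, J = -Inf)
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    if (sens + spec - 1 > best$J + 1e-12)
      best <- list(cutoff = t, J = sens + spec - 1, sens = sens, spec = spec)
  }
  best
}

# brute-force per-histology-pixel point mapping for resample_to_mri
oracle_resample <- function(mask_h, tf, mri_shape, scale) {
  out <- matrix(0, mri_shape[1], mri_shape[2])
  for (i in seq_len(nrow(mask_h))) for (j in seq_len(ncol(mask_h))) {
    if (!mask_h[i, j]) next
    y <- tf$A %*% c(i - 1, j - 1) + tf$t
    mr <- floor((y[1] + 0.5) / scale) + 1
    mc <- floor((y[2] + 0.5) / scale) + 1
    if (mr >= 1 && mr <= mri_shape[1] && mc >= 1 && mc <= mri_shape[2])
      out[mr, mc] <- out[mr, mc] + 1 / scale^2
  }
  out
}

# random non-degenerate affine (rotation / anisotropic scale / shear / shift)
random_affine <- function() {
  repeat {
    th <- runif(1, 0, 2 * pi)
    sc <- runif(2, 0.6, 1.5)
    sh <- runif(1, -0.3, 0.3)
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      diag(sc) %*% matrix(c(1, 0, sh, 1), 2, 2)
    if (abs(det(A)) > 1e-3) break
  }
  affine2d(A, runif(2, -10, 10))
}

# small synthetic mp slice with a given tumor mask and constant channels
toy_slice <- function(H = 20, W = 20, tumor = NULL, slice_id = 1L) {
  if (is.null(tumor)) {
    tumor <- matrix(FALSE, H, W)
    tumor[3:(H - 3), 3:(W - 3)] <- TRUE
  }
  ch <- array(rnorm(H * W * 5), dim = c(H, W, 5),
              dimnames = list(NULL, NULL, mp_channels))
  list(channels = ch, tumor_mask = tumor, slice_id = slice_id,
       subject_id = 1L)
}
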