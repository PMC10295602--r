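# Shared fixtures: small seeded synthetic configurations used across files.

tiny_sim_config <- function(seed = 11L, size = 64L) {
  vesselSimConfig(imageSize = c(size, size), nTrees = 2L, branchDepth = 3L,
                  rootWidthPx = 2, seed = as.integer(seed))
}

tiny_model_config <- function() {
  modelConfig(depth = 3L, baseChannels = 8L, fusionChannels = 16L)
}

# Independent per-pixel double-loop confusion oracle.
confusion_oracle <- function(pred, truth, roi = NULL) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (!is.null(roi) && roi[i, j] == 0) next
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Independent double-loop bilateral filter oracle (edge replication).
bilateral_oracle <- function(img, diameter, sigma_color, sigma_space) {
  r <- (diameter - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      num <- 0; den <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          ii <- min(H, max(1, i + dy)); jj <- min(W, max(1, j + dx))
          w <- exp(-(dy^2 + dx^2) / (2 * sigma_space^2)) *
            exp(-(img[ii, jj] - img[i, j])^2 / (2 * sigma_color^2))
          num <- num + w * img[ii, jj]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Closed-form parameter-count oracle, written from the layer arithmetic
# (conv k: k^2*cin*cout + cout; batch norm: 2*cout).
param_count_oracle <- function(cfg) {
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  bn <- function(c) 2 * c
  res <- function(cin, cout) {
    n <- conv(3, cin, cout) + bn(cout) + conv(3, cout, cout) + bn(cout)
    if (cin != cout) n <- n + conv(1, cin, cout)
    n
  }
  L <- cfg@depth
  ec <- cfg@baseChannels * 2^(seq_len(L) - 1)
  bc <- cfg@bottleneckChannels
  fc <- cfg@fusionChannels
  total <- 0
  cin <- cfg@inChannels
  for (i in seq_len(L)) {
    total <- total + res(cin, ec[i])
    cin <- ec[i]
  }
  for (k in c(1, 3, 5)) total <- total + conv(k, ec[L], bc) + bn(bc)
  total <- total + conv(1, 3 * bc, bc) + bn(bc)
  for (t in seq.int(L - 1, 1)) {
    for (l in seq_len(L)) {
      sc <- if (l == L) bc else ec[l]
      total <- total + conv(3, sc, fc) + bn(fc)
    }
    total <- total + res(L * fc, ec[t])
  }
  total + conv(1, ec[1], 1)
}
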