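# Minimal reverse-mode autodiff over 4-d feature maps (H, W, C, N).
#
# A "tape" records nodes in forward order; backward() walks them in reverse
# creation order (a valid reverse topological order for any DAG built during
# a forward pass) and accumulates gradients into parents and, for leaf
# parameter nodes, into the model's gradient store. Heavy kernels
# (convolution, pooling, bilinear resize) are C++ (src/kernels.cpp);
# elementwise ops stay vectorised R.

new_tape <- function(training = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$training <- training
  tp
}

tp_node <- function(tape, value, parents = list(), backward = NULL,
                    param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

tp_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Run reverse-mode accumulation from `loss` (a scalar-valued node whose
# gradient seed is 1). Parameter gradients land in `grads` (an environment
# keyed by parameter name).
tape_backward <- function(tape, loss, grads) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      nm <- nd$param
      if (is.null(grads[[nm]])) grads[[nm]] <- nd$grad
      else grads[[nm]] <- grads[[nm]] + nd$grad
    }
    if (!is.null(nd$backward)) {
      pg <- nd$backward(nd)
      for (j in seq_along(pg)) {
        if (!is.null(pg[[j]])) tp_accum(nd$parents[[j]], pg[[j]])
      }
    }
    nd$grad <- NULL  # free memory as we go
  }
  invisible(NULL)
}

op_leaf <- function(tape, value, param = NULL) {
  tp_node(tape, value, param = param)
}

op_conv2d <- function(tape, x, w, b) {
  out <- cpp_conv2d_fw(x$value, w$value, b$value)
  tp_node(tape, out, parents = list(x, w, b), backward = function(nd) {
    g <- cpp_conv2d_bw(nd$parents[[1]]$value, nd$parents[[2]]$value, nd$grad)
    list(g$gx, g$gw, g$gb)
  })
}

op_relu <- function(tape, x) {
  v <- x$value
  v[v < 0] <- 0
  tp_node(tape, v, parents = list(x), backward = function(nd) {
    list(nd$grad * (nd$value > 0))
  })
}

op_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, parents = list(a, b),
          backward = function(nd) list(nd$grad, nd$grad))
}

op_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$value))
  tp_node(tape, v, parents = list(x), backward = function(nd) {
    list(nd$grad * nd$value * (1 - nd$value))
  })
}

op_maxpool <- function(tape, x, factor) {
  fw <- cpp_maxpool_fw(x$value, as.integer(factor))
  xd <- dim(x$value)
  nd <- tp_node(tape, fw$out, parents = list(x), backward = function(nd) {
    list(cpp_maxpool_bw(nd$grad, nd$idx, nd$xdim))
  })
  nd$idx <- fw$idx
  nd$xdim <- as.integer(xd)
  nd
}

op_upsample <- function(tape, x, factor) {
  xd <- dim(x$value)
  nd <- tp_node(tape, cpp_upsample_fw(x$value, as.integer(factor)),
                parents = list(x), backward = function(nd) {
    list(cpp_upsample_bw(nd$grad, nd$factor, nd$xdim[1], nd$xdim[2]))
  })
  nd$factor <- as.integer(factor)
  nd$xdim <- as.integer(xd)
  nd
}

op_concat_ch <- function(tape, xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  H <- dims[[1]][1]; W <- dims[[1]][2]; N <- dims[[1]][4]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  out <- array(0, c(H, W, sum(cs), N))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, , off + seq_len(cs[i]), ] <- xs[[i]]$value
    off <- off + as.integer(cs[i])
  }
  nd <- tp_node(tape, out, parents = xs, backward = function(nd) {
    off <- 0L
    lapply(seq_along(nd$cs), function(i) {
      ci <- nd$cs[i]
      g <- nd$grad[, , off + seq_len(ci), , drop = FALSE]
      off <<- off + as.integer(ci)
      g
    })
  })
  nd$cs <- cs
  nd
}

# channel-wise helpers for batch norm: x reshaped to (H*W, C, N)
.bn_chan_sum <- function(xr) {
  d <- dim(xr)
  rowSums(matrix(colSums(matrix(xr, d[1], d[2] * d[3])), d[2], d[3]))
}

op_batchnorm <- function(tape, x, gamma, beta, menv, name,
                         eps = 1e-5, momentum = 0.1) {
  dims <- dim(x$value)
  HW <- dims[1] * dims[2]; C <- dims[3]; N <- dims[4]
  xr <- x$value
  dim(xr) <- c(HW, C, N)
  m <- HW * N
  if (tape$training) {
    mu <- .bn_chan_sum(xr) / m
    xc <- sweep(xr, 2, mu, "-")
    va <- .bn_chan_sum(xc * xc) / m
    rk_m <- paste0(name, ".running_mean"); rk_v <- paste0(name, ".running_var")
    menv$state[[rk_m]] <- (1 - momentum) * menv$state[[rk_m]] + momentum * mu
    # unbiased variance in running stats, matching common framework practice
    ub <- if (m > 1) va * m / (m - 1) else va
    menv$state[[rk_v]] <- (1 - momentum) * menv$state[[rk_v]] + momentum * ub
  } else {
    mu <- menv$state[[paste0(name, ".running_mean")]]
    va <- menv$state[[paste0(name, ".running_var")]]
    xc <- sweep(xr, 2, mu, "-")
  }
  sd_c <- sqrt(va + eps)
  xhat <- sweep(xc, 2, sd_c, "/")
  y <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  dim(y) <- dims
  nd <- tp_node(tape, y, parents = list(x, gamma, beta),
                backward = function(nd) {
    g <- nd$grad
    dim(g) <- c(nd$HW, nd$C, nd$N)
    dgamma <- .bn_chan_sum(g * nd$xhat)
    dbeta <- .bn_chan_sum(g)
    dxhat <- sweep(g, 2, nd$parents[[2]]$value, "*")
    if (nd$train_stats) {
      mh <- nd$HW * nd$N
      t1 <- .bn_chan_sum(dxhat) / mh
      t2 <- .bn_chan_sum(dxhat * nd$xhat) / mh
      dx <- sweep(dxhat, 2, t1, "-") - sweep(nd$xhat, 2, t2, "*")
      dx <- sweep(dx, 2, nd$sd_c, "/")
    } else {
      dx <- sweep(dxhat, 2, nd$sd_c, "/")
    }
    dim(dx) <- nd$dims
    list(dx, dgamma, dbeta)
  })
  nd$xhat <- xhat
  nd$sd_c <- sd_c
  nd$HW <- HW; nd$C <- C; nd$N <- N; nd$dims <- dims
  nd$train_stats <- tape$training
  nd
}

# Mean binary cross-entropy from logits, optionally restricted by a 0/1
# weight mask (padding-validity); numerically stable log1p form.
op_bce_logits <- function(tape, z, target, wmask = NULL) {
  zv <- z$value
  p <- 1 / (1 + exp(-zv))
  ll <- pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))
  if (is.null(wmask)) {
    mtot <- length(zv)
    loss <- sum(ll) / mtot
  } else {
    mtot <- sum(wmask)
    loss <- sum(ll * wmask) / mtot
  }
  nd <- tp_node(tape, loss, parents = list(z), backward = function(nd) {
    g <- nd$grad * (nd$p - nd$target) / nd$mtot
    if (!is.null(nd$wmask)) g <- g * nd$wmask
    list(g)
  })
  nd$p <- p; nd$target <- target; nd$wmask <- wmask; nd$mtot <- mtot
  nd
}

# Soft Dice loss on probabilities: 1 - (2*sum(p*t)+s)/(sum(p)+sum(t)+s)
op_dice_loss <- function(tape, p, target, smooth = 1) {
  pv <- p$value
  num <- 2 * sum(pv * target) + smooth
  den <- sum(pv) + sum(target) + smooth
  nd <- tp_node(tape, 1 - num / den, parents = list(p), backward = function(nd) {
    list(nd$grad * (nd$num / nd$den^2 - 2 * nd$target / nd$den))
  })
  nd$num <- num; nd$den <- den; nd$target <- target
  nd
}

op_scale_add <- function(tape, a, b, wa = 1, wb = 1) {
  tp_node(tape, wa * a$value + wb * b$value, parents = list(a, b),
          backward = function(nd) list(nd$grad * nd$wa, nd$grad * nd$wb)) -> nd
  nd$wa <- wa; nd$wb <- wb
  nd
}
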