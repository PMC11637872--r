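# A minimal reverse-mode tape for the detector. Values are H x W x C
# arrays; parameters live in a flat named list and gradients are
# accumulated into an environment keyed by parameter name. Convolution and
# max-pooling run through the package's Armadillo kernels; everything else
# is vectorized R. This is deliberately small: just the ops the detector
# needs (conv+SiLU, residual add, channel concat, nearest upsample x2,
# max-pool, squeeze-excitation, efficient channel attention).

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

tape_push <- function(tape, value, parents = integer(), bw = NULL) {
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(value = value, parents = parents, bw = bw)
  id
}

tape_value <- function(tape, id) {
  force(id)  # id may be a promise that pushes nodes onto the tape
  tape$nodes[[id]]$value
}

# Run reverse-mode accumulation from `seed_grads` (named by node id) into
# gradient environment G (param name -> accumulated gradient).
tape_backward <- function(tape, seed_grads, G) {
  n <- length(tape$nodes)
  dvals <- vector("list", n)
  for (id in names(seed_grads)) dvals[[as.integer(id)]] <- seed_grads[[id]]
  for (id in n:1) {
    dy <- dvals[[id]]
    if (is.null(dy)) next
    node <- tape$nodes[[id]]
    if (is.null(node$bw)) next
    pg <- node$bw(dy, G)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      dvals[[p]] <- if (is.null(dvals[[p]])) pg[[j]] else dvals[[p]] + pg[[j]]
    }
    dvals[[id]] <- NULL  # free
  }
  invisible(NULL)
}

acc_grad <- function(G, name, g) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) g else cur + g
}

silu <- function(x) x * sigmoid(x)

# conv (+ optional SiLU) node; params[[name]] = list(W, b, k, stride, pad).
# The im2col patch matrix and the SiLU sigmoid are cached for the backward
# pass.
op_conv <- function(tape, xid, params, name, act = TRUE) {
  p <- params[[name]]
  x <- tape_value(tape, xid)
  d <- dim(x)
  f <- conv2d_fwc_cpp(x, p$W, p$b, p$k, p$stride, p$pad)
  pre <- f$y
  s <- if (act) sigmoid(pre) else NULL
  y <- if (act) pre * s else pre
  tape_push(tape, y, parents = xid, bw = function(dy, G) {
    if (act) dy <- dy * (s * (1 + pre * (1 - s)))
    g <- conv2d_bwc_cpp(f$cols, p$W, p$k, p$stride, p$pad, dy,
                        d[1], d[2], d[3])
    acc_grad(G, paste0(name, ".W"), g$dW)
    acc_grad(G, paste0(name, ".b"), as.numeric(g$db))
    list(g$dx)
  })
}

op_add <- function(tape, aid, bid) {
  y <- tape_value(tape, aid) + tape_value(tape, bid)
  tape_push(tape, y, parents = c(aid, bid),
            bw = function(dy, G) list(dy, dy))
}

op_concat <- function(tape, ids) {
  vals <- lapply(ids, tape_value, tape = tape)
  d <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  y <- array(0, c(d[1], d[2], sum(cs)))
  off <- 0L
  for (v in vals) {
    y[, , off + seq_len(dim(v)[3])] <- v
    off <- off + dim(v)[3]
  }
  tape_push(tape, y, parents = ids, bw = function(dy, G) {
    out <- vector("list", length(ids))
    off <- 0L
    for (j in seq_along(ids)) {
      out[[j]] <- dy[, , off + seq_len(cs[j]), drop = FALSE]
      off <- off + cs[j]
    }
    out
  })
}

op_upsample2 <- function(tape, xid) {
  x <- tape_value(tape, xid)
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
         drop = FALSE]
  tape_push(tape, y, parents = xid, bw = function(dy, G) {
    odd_r <- seq(1, 2 * d[1], by = 2); odd_c <- seq(1, 2 * d[2], by = 2)
    dx <- dy[odd_r, odd_c, , drop = FALSE] +
          dy[odd_r + 1, odd_c, , drop = FALSE] +
          dy[odd_r, odd_c + 1, , drop = FALSE] +
          dy[odd_r + 1, odd_c + 1, , drop = FALSE]
    list(dx)
  })
}

op_maxpool <- function(tape, xid, k = 5L, stride = 1L, pad = 2L) {
  x <- tape_value(tape, xid)
  f <- maxpool_fw_cpp(x, k, stride, pad)
  d <- dim(x)
  tape_push(tape, f$y, parents = xid, bw = function(dy, G) {
    list(maxpool_bw_cpp(f$idx, dy, d[1], d[2], d[3]))
  })
}

# squeeze-excitation node; params[[name]] = list(W1, W2)
op_se <- function(tape, xid, params, name) {
  p <- params[[name]]
  x <- tape_value(tape, xid)
  d <- dim(x)
  z <- global_average_pool(x)
  a <- as.numeric(p$W1 %*% z)
  ar <- pmax(a, 0)
  s <- as.numeric(p$W2 %*% ar)
  w <- sigmoid(s)
  y <- scale_channels(x, w)
  tape_push(tape, y, parents = xid, bw = function(dy, G) {
    dw <- vapply(seq_len(d[3]), function(c) sum(dy[, , c] * x[, , c]),
                 numeric(1))
    dx <- dy * rep(w, each = d[1] * d[2])
    ds <- dw * w * (1 - w)
    acc_grad(G, paste0(name, ".W2"), outer(ds, ar))
    dar <- as.numeric(t(p$W2) %*% ds)
    da <- dar * (a > 0)
    acc_grad(G, paste0(name, ".W1"), outer(da, z))
    dz <- as.numeric(t(p$W1) %*% da)
    dx <- dx + rep(dz / (d[1] * d[2]), each = d[1] * d[2])
    list(dx)
  })
}

# efficient-channel-attention node; params[[name]] = list(kernel)
op_eca <- function(tape, xid, params, name) {
  p <- params[[name]]
  kern <- p$kernel
  x <- tape_value(tape, xid)
  d <- dim(x)
  z <- global_average_pool(x)
  s <- conv1d_channel(z, kern)
  w <- sigmoid(s)
  y <- scale_channels(x, w)
  tape_push(tape, y, parents = xid, bw = function(dy, G) {
    dw <- vapply(seq_len(d[3]), function(c) sum(dy[, , c] * x[, , c]),
                 numeric(1))
    dx <- dy * rep(w, each = d[1] * d[2])
    ds <- dw * w * (1 - w)
    half <- (length(kern) - 1L) / 2L
    zp <- c(rep(0, half), z, rep(0, half))
    dkern <- vapply(seq_along(kern), function(j) {
      sum(ds * zp[seq_along(z) + (j - 1L)])
    }, numeric(1))
    acc_grad(G, paste0(name, ".kernel"), dkern)
    dz <- conv1d_channel(ds, rev(kern))
    dx <- dx + rep(dz / (d[1] * d[2]), each = d[1] * d[2])
    list(dx)
  })
}
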