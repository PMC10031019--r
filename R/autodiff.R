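# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# Every node is an environment holding a value, an accumulated gradient and a
# backward closure that maps the node's gradient to gradients for its parents.
# Nodes are numbered at creation, so reverse creation order is a valid
# topological order for backpropagation.  Activations are [H, W, C, N] arrays;
# channel vectors are [C, N]; per-sample reductions are length-N vectors;
# losses are scalars.  The heavy convolution arithmetic lives in src/ and is
# reached through the .conv2d_* kernels.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

# GEMM precision for the convolution kernels: single (default) is
# training-grade and ~1.5x faster; double backs the finite-difference
# gradient verification.
conv_prec <- function() {
  if (identical(getOption("symsegda.precision", "single"), "double")) 0L
  else 1L
}

ad_node <- function(value, parents = NULL, backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  .ad$counter <- .ad$counter + 1L
  e$id <- .ad$counter
  class(e) <- "ad_node"
  e
}

#' @noRd
ad_leaf <- function(value) ad_node(value)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

is_ad <- function(x) inherits(x, "ad_node")

# Detach: value flows, gradient does not.
ad_detach <- function(x) ad_leaf(x$value)

ad_backward <- function(root) {
  stopifnot(is_ad(root))
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- vector("list", 64L)
  n <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n <- n + 1L
    if (n > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n]] <- nd
    if (!is.null(nd$parents)) for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n)]
  ord <- order(vapply(nodes, function(nd) nd$id, integer(1)), decreasing = TRUE)
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim(root$value))
  for (nd in nodes[ord]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

ad_zero_grads <- function(nodes) {
  for (nd in nodes) nd$grad <- NULL
  invisible(NULL)
}

## ---- convolution -----------------------------------------------------------

# w: [kh, kw, Cin, Cout]; x: [H, W, Cin, N].  Padding is replicate (clamped)
# by default so constant inputs stay constant through normalized stacks.
ad_conv <- function(x, w, b, stride = 1L, pad = 1L, pad_mode = 1L) {
  xd <- dim(x$value); wd <- dim(w$value)
  sp <- conv_prec()
  y <- .conv2d_fwd(x$value, w$value, b$value, as.integer(stride),
                   as.integer(pad), pad_mode, sp)
  ad_node(y, list(x, w, b), function(g) {
    gf <- .conv2d_bwd_filter(x$value, g, wd[1L], wd[2L],
                             as.integer(stride), as.integer(pad), pad_mode,
                             sp)
    gx <- .conv2d_bwd_data(g, w$value, as.integer(stride), as.integer(pad),
                           xd[1L], xd[2L], pad_mode, sp)
    list(gx, gf$gw, gf$gb)
  })
}

# Transposed convolution with stride 2 (kernel 4, pad 1 doubles H and W).
# Weight uses the conv layout of the adjoint map: [kh, kw, Cout, Cin].
ad_convt <- function(x, w, b, stride = 2L, pad = 1L) {
  xd <- dim(x$value); wd <- dim(w$value)
  Ho <- xd[1L] * stride; Wo <- xd[2L] * stride
  sp <- conv_prec()
  y <- .conv2d_bwd_data(x$value, w$value, as.integer(stride), as.integer(pad),
                        Ho, Wo, 0L, sp)
  Cout <- wd[3L]
  bfull <- rep(b$value, each = Ho * Wo)
  y <- y + rep(bfull, times = xd[4L])
  dim(y) <- c(Ho, Wo, Cout, xd[4L])
  ad_node(y, list(x, w, b), function(g) {
    gx <- .conv2d_fwd(g, w$value, numeric(xd[3L]),
                      as.integer(stride), as.integer(pad), 0L, sp)
    gf <- .conv2d_bwd_filter(g, x$value, wd[1L], wd[2L],
                             as.integer(stride), as.integer(pad), 0L, sp)
    gb <- colSums(matrix(g, ncol = Cout * xd[4L]))
    dim(gb) <- c(Cout, xd[4L])
    list(gx, gf$gw, rowSums(gb))
  })
}

## ---- pointwise activations -------------------------------------------------

ad_relu <- function(x) {
  y <- .act_fwd(x$value, 0L, 0)
  ad_node(y, list(x), function(g) list(.act_bwd(x$value, g, 0L, 0)))
}

ad_lrelu <- function(x, slope = 0.2) {
  y <- .act_fwd(x$value, 1L, slope)
  ad_node(y, list(x), function(g) list(.act_bwd(x$value, g, 1L, slope)))
}

ad_sigmoid <- function(x) {
  y <- .act_fwd(x$value, 2L, 0)
  ad_node(y, list(x), function(g) list(.act_bwd(y, g, 2L, 0)))
}

ad_tanh <- function(x) {
  y <- .act_fwd(x$value, 3L, 0)
  ad_node(y, list(x), function(g) list(.act_bwd(y, g, 3L, 0)))
}

# y = a * x + b with scalar constants (used for the [0,1] <-> [-1,1] remap)
ad_affine <- function(x, a, b) {
  y <- a * x$value + b
  dim(y) <- dim(x$value)
  ad_node(y, list(x), function(g) list(a * g))
}

ad_add <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

## ---- normalization ---------------------------------------------------------

# Instance normalization: statistics over H, W for each (channel, sample).
# gamma, beta: length-C parameter nodes.
ad_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  fw <- .instnorm_fwd(x$value, gamma$value, beta$value, eps)
  ad_node(fw$y, list(x, gamma, beta), function(g) {
    bw <- .instnorm_bwd(fw$xhat, fw$inv, gamma$value, g, as.integer(d))
    list(bw$gx, bw$ggamma, bw$gbeta)
  })
}

## ---- shape ops -------------------------------------------------------------

ad_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L], da[4L] == db[4L])
  HW <- da[1L] * da[2L]; N <- da[4L]
  am <- array(a$value, c(HW, da[3L], N))
  bm <- array(b$value, c(HW, db[3L], N))
  y <- array(0, c(HW, da[3L] + db[3L], N))
  y[, seq_len(da[3L]), ] <- am
  y[, da[3L] + seq_len(db[3L]), ] <- bm
  dim(y) <- c(da[1L], da[2L], da[3L] + db[3L], N)
  ad_node(y, list(a, b), function(g) {
    gm <- array(g, c(HW, da[3L] + db[3L], N))
    ga <- gm[, seq_len(da[3L]), , drop = FALSE]
    gb <- gm[, da[3L] + seq_len(db[3L]), , drop = FALSE]
    dim(ga) <- da; dim(gb) <- db
    list(ga, gb)
  })
}

# Concatenate along the batch (4th) axis.  Because N is the slowest-varying
# dimension this is a plain memory concatenation; instance norm is per-sample,
# so batching passes this way is semantically identical to separate passes.
ad_concat_n <- function(nodes) {
  ds <- lapply(nodes, function(nd) dim(nd$value))
  ns <- vapply(ds, `[`, 0L, 4L)
  d <- ds[[1L]]
  y <- unlist(lapply(nodes, `[[`, "value"), use.names = FALSE)
  dim(y) <- c(d[1:3], sum(ns))
  per <- prod(d[1:3])
  offs <- cumsum(c(0L, ns))
  ad_node(y, nodes, function(g) {
    lapply(seq_along(nodes), function(k) {
      gk <- g[(offs[k] * per + 1L):(offs[k + 1L] * per)]
      dim(gk) <- ds[[k]]
      gk
    })
  })
}

# Slice samples [from, to] out of the batch axis
ad_slice_n <- function(x, from, to) {
  d <- dim(x$value)
  per <- prod(d[1:3])
  y <- x$value[((from - 1L) * per + 1L):(to * per)]
  dim(y) <- c(d[1:3], to - from + 1L)
  ad_node(y, list(x), function(g) {
    gx <- array(0, d)
    gx[((from - 1L) * per + 1L):(to * per)] <- g
    list(gx)
  })
}

ad_upsample2 <- function(x) {
  d <- dim(x$value)
  H <- d[1L]; W <- d[2L]
  y <- x$value[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , ,
               drop = FALSE]
  ad_node(y, list(x), function(g) {
    io <- seq(1L, 2L * H, by = 2L); jo <- seq(1L, 2L * W, by = 2L)
    gx <- g[io, jo, , , drop = FALSE] + g[io + 1L, jo, , , drop = FALSE] +
      g[io, jo + 1L, , , drop = FALSE] + g[io + 1L, jo + 1L, , , drop = FALSE]
    list(gx)
  })
}

# Global average pool: [H,W,C,N] -> [C,N]
ad_gap <- function(x) {
  d <- dim(x$value)
  HW <- d[1L] * d[2L]
  y <- colMeans(matrix(x$value, nrow = HW))
  dim(y) <- c(d[3L], d[4L])
  ad_node(y, list(x), function(g) {
    gx <- rep(as.vector(g) / HW, each = HW)
    dim(gx) <- d
    list(gx)
  })
}

# Per-pixel mean and max over channels: [H,W,C,N] -> [H,W,2,N]
ad_channel_meanmax <- function(x) {
  d <- dim(x$value)
  HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  a <- array(x$value, c(HW, C, N))
  mx <- a[, 1L, , drop = FALSE]
  arg <- array(1L, c(HW, 1L, N))
  if (C > 1L) for (c in 2:C) {
    sl <- a[, c, , drop = FALSE]
    upd <- sl > mx
    mx[upd] <- sl[upd]
    arg[upd] <- c
  }
  mn <- matrix(0, HW, N)
  for (c in seq_len(C)) mn <- mn + a[, c, ]
  mn <- mn / C
  y <- array(0, c(HW, 2L, N))
  y[, 1L, ] <- mn
  y[, 2L, ] <- mx
  dim(y) <- c(d[1L], d[2L], 2L, N)
  ad_node(y, list(x), function(g) {
    gm <- array(g, c(HW, 2L, N))
    gx <- array(0, c(HW, C, N))
    for (c in seq_len(C)) {
      gx[, c, ] <- gm[, 1L, ] / C + gm[, 2L, ] * (arg[, 1L, ] == c)
    }
    dim(gx) <- d
    list(gx)
  })
}

# x:[H,W,C,N] scaled per (channel, sample) by g:[C,N]
ad_scale_channel <- function(x, g) {
  d <- dim(x$value)
  HW <- d[1L] * d[2L]
  gexp <- rep(as.vector(g$value), each = HW)
  y <- x$value * gexp
  dim(y) <- d
  ad_node(y, list(x, g), function(gr) {
    gx <- gr * gexp
    dim(gx) <- d
    gg <- colSums(matrix(gr * x$value, nrow = HW))
    dim(gg) <- c(d[3L], d[4L])
    list(gx, gg)
  })
}

# x:[H,W,C,N] scaled per pixel by s:[H,W,1,N] (broadcast over channels)
ad_scale_spatial <- function(x, s) {
  d <- dim(x$value)
  HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  sm <- matrix(s$value, nrow = HW)               # HW x N
  sexp <- sm[, rep(seq_len(N), each = C), drop = FALSE]
  y <- x$value * as.vector(sexp)
  dim(y) <- d
  ad_node(y, list(x, s), function(gr) {
    gx <- gr * as.vector(sexp)
    dim(gx) <- d
    prod <- array(gr * x$value, c(HW, C, N))
    gs <- matrix(0, HW, N)
    for (c in seq_len(C)) gs <- gs + prod[, c, ]
    dim(gs) <- dim(s$value)
    list(gx, gs)
  })
}

# Dense layer on channel vectors: x:[Cin,N], w:[Cout,Cin], b:[Cout]
ad_dense <- function(x, w, b) {
  y <- w$value %*% x$value + b$value
  ad_node(y, list(x, w, b), function(g) {
    list(crossprod(w$value, g), g %*% t(x$value), rowSums(g))
  })
}

## ---- reductions and loss heads ---------------------------------------------

# Sum over H, W, C per sample: [H,W,C,N] -> length-N vector
ad_sum_hwc <- function(x) {
  d <- dim(x$value)
  y <- colSums(matrix(x$value, ncol = d[4L]))
  ad_node(y, list(x), function(g) {
    gx <- rep(g, each = d[1L] * d[2L] * d[3L])
    dim(gx) <- d
    list(gx)
  })
}

# Sum of the elementwise product per sample (Dice numerator)
ad_sum_prod_hwc <- function(a, b) {
  d <- dim(a$value)
  stopifnot(identical(d, dim(b$value)))
  y <- colSums(matrix(a$value * b$value, ncol = d[4L]))
  ad_node(y, list(a, b), function(g) {
    ge <- rep(g, each = d[1L] * d[2L] * d[3L])
    ga <- ge * b$value; gb <- ge * a$value
    dim(ga) <- d; dim(gb) <- d
    list(ga, gb)
  })
}

# Elementwise ops on length-N vectors
ad_vaffine <- function(x, a, b) {
  ad_node(a * x$value + b, list(x), function(g) list(a * g))
}

ad_vadd <- function(a, b) ad_node(a$value + b$value, list(a, b),
                                  function(g) list(g, g))

ad_vdiv <- function(a, b) {
  y <- a$value / b$value
  ad_node(y, list(a, b), function(g) {
    list(g / b$value, -g * y / b$value)
  })
}

ad_vmean <- function(x) {
  n <- length(x$value)
  ad_node(mean(x$value), list(x), function(g) list(rep(g / n, n)))
}

# mean |a - b| over all elements (L1 reconstruction losses)
ad_mean_abs_diff <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  dlt <- a$value - b$value
  n <- length(dlt)
  ad_node(mean(abs(dlt)), list(a, b), function(g) {
    ga <- g * sign(dlt) / n
    list(ga, -ga)
  })
}

# mean(-log s) and mean(-log(1 - s)) with scores clamped away from {0,1}
ad_bce_real <- function(s, eps = 1e-7) {
  v <- pmax(s$value, eps)
  n <- length(v)
  ad_node(mean(-log(v)), list(s), function(g) {
    gs <- ifelse(s$value > eps, -g / (n * v), 0)
    dim(gs) <- dim(s$value)
    list(gs)
  })
}

ad_bce_fake <- function(s, eps = 1e-7) {
  v <- pmax(1 - s$value, eps)
  n <- length(v)
  ad_node(mean(-log(v)), list(s), function(g) {
    gs <- ifelse(1 - s$value > eps, g / (n * v), 0)
    dim(gs) <- dim(s$value)
    list(gs)
  })
}

# Weighted sum of scalar nodes
ad_lincomb <- function(nodes, weights) {
  stopifnot(length(nodes) == length(weights))
  v <- sum(vapply(nodes, function(nd) nd$value, numeric(1)) * weights)
  ad_node(v, nodes, function(g) as.list(g * weights))
}
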