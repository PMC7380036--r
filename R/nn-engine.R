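# Minimal CNN engine backing the three pipeline stages.
#
# A network body is an ordered list of layers (conv / relu / pool / flatten)
# followed by one or more fully connected heads on the flattened features.
# Batches are (H, W, C, N) arrays. Forward passes cache what the backward
# pass needs; parameters are updated by SGD with momentum.

init_conv <- function(kh, kw, cin, cout) {
  list(kind = "conv",
       w = array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_fc <- function(n_in, n_out, w_sd = 0.01, b_init = 0) {
  list(w = matrix(rnorm(n_in * n_out, sd = w_sd), n_out, n_in),
       b = rep(b_init, n_out))
}

# Forward through the body; returns features (F x N) and per-layer caches.
body_forward <- function(layers, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      if (keep_cache) caches[[i]] <- list(x = x)
      x <- .cpp_conv2d_forward(x, ly$w, ly$b)
    } else if (ly$kind == "relu") {
      x <- pmax(x, 0)
      if (keep_cache) caches[[i]] <- list(mask = x > 0)
    } else if (ly$kind == "pool") {
      res <- .cpp_pool2_forward(x, if (ly$mode == "max") 0L else 1L)
      if (keep_cache) caches[[i]] <- list(argmax = res$argmax, in_dim = dim(x))
      x <- res$y
    } else if (ly$kind == "flatten") {
      if (keep_cache) caches[[i]] <- list(in_dim = dim(x))
      d <- dim(x)
      x <- matrix(x, prod(d[1:3]), d[4])
    } else {
      stop("unknown layer kind: ", ly$kind)
    }
  }
  list(features = x, caches = caches)
}

body_backward <- function(layers, caches, dfeat) {
  grads <- vector("list", length(layers))
  dx <- dfeat
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ch <- caches[[i]]
    if (ly$kind == "conv") {
      bk <- .cpp_conv2d_backward(ch$x, ly$w, dx)
      grads[[i]] <- list(dw = bk$dw, db = bk$db)
      dx <- bk$dx
    } else if (ly$kind == "relu") {
      dx <- dx * ch$mask
    } else if (ly$kind == "pool") {
      dx <- .cpp_pool2_backward(dx, ch$argmax, as.integer(ch$in_dim),
                                if (ly$mode == "max") 0L else 1L)
    } else if (ly$kind == "flatten") {
      dx <- array(dx, dim = ch$in_dim)
    }
  }
  list(grads = grads, dx = dx)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Full forward with caches for training.
net_forward_cached <- function(net, x) {
  bf <- body_forward(net$layers, x, keep_cache = TRUE)
  f <- bf$features
  heads <- lapply(net$heads, function(h) h$w %*% f + h$b)
  list(features = f, caches = bf$caches, head_z = heads)
}

# Backward from head-logit gradients (list matching net$heads).
net_backward <- function(net, fwd, d_head_z) {
  dfeat <- 0
  head_grads <- list()
  for (nm in names(net$heads)) {
    dz <- d_head_z[[nm]]
    if (is.null(dz)) next
    h <- net$heads[[nm]]
    head_grads[[nm]] <- list(dw = dz %*% t(fwd$features), db = rowSums(dz))
    dfeat <- dfeat + t(h$w) %*% dz
  }
  bb <- body_backward(net$layers, fwd$caches, dfeat)
  list(layers = bb$grads, heads = head_grads)
}

# -- parameter flattening / SGD ----------------------------------------

zero_like_grads <- function(net) {
  list(layers = lapply(net$layers, function(ly) {
    if (ly$kind == "conv") list(dw = array(0, dim(ly$w)), db = numeric(length(ly$b)))
    else NULL
  }),
  heads = lapply(net$heads, function(h) {
    list(dw = matrix(0, nrow(h$w), ncol(h$w)), db = numeric(length(h$b)))
  }))
}

# Adam state: first/second moment per parameter, plus the step counter.
init_adam <- function(net) {
  zeros <- zero_like_grads(net)
  list(m = zeros, v = zeros, t = 0L)
}

adam_update <- function(net, state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  for (i in seq_along(net$layers)) {
    if (is.null(grads$layers[[i]])) next
    up <- step(net$layers[[i]]$w, grads$layers[[i]]$dw,
               state$m$layers[[i]]$dw, state$v$layers[[i]]$dw)
    net$layers[[i]]$w <- up$w
    state$m$layers[[i]]$dw <- up$m; state$v$layers[[i]]$dw <- up$v
    up <- step(net$layers[[i]]$b, grads$layers[[i]]$db,
               state$m$layers[[i]]$db, state$v$layers[[i]]$db)
    net$layers[[i]]$b <- up$w
    state$m$layers[[i]]$db <- up$m; state$v$layers[[i]]$db <- up$v
  }
  for (nm in names(net$heads)) {
    g <- grads$heads[[nm]]
    if (is.null(g)) next
    up <- step(net$heads[[nm]]$w, g$dw, state$m$heads[[nm]]$dw, state$v$heads[[nm]]$dw)
    net$heads[[nm]]$w <- up$w
    state$m$heads[[nm]]$dw <- up$m; state$v$heads[[nm]]$dw <- up$v
    up <- step(net$heads[[nm]]$b, g$db, state$m$heads[[nm]]$db, state$v$heads[[nm]]$db)
    net$heads[[nm]]$b <- up$w
    state$m$heads[[nm]]$db <- up$m; state$v$heads[[nm]]$db <- up$v
  }
  list(net = net, state = state)
}

sgd_update <- function(net, vel, grads, lr, momentum) {
  for (i in seq_along(net$layers)) {
    if (is.null(grads$layers[[i]])) next
    vel$layers[[i]]$dw <- momentum * vel$layers[[i]]$dw + grads$layers[[i]]$dw
    vel$layers[[i]]$db <- momentum * vel$layers[[i]]$db + grads$layers[[i]]$db
    net$layers[[i]]$w <- net$layers[[i]]$w - lr * vel$layers[[i]]$dw
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * vel$layers[[i]]$db
  }
  for (nm in names(net$heads)) {
    g <- grads$heads[[nm]]
    if (is.null(g)) next
    vel$heads[[nm]]$dw <- momentum * vel$heads[[nm]]$dw + g$dw
    vel$heads[[nm]]$db <- momentum * vel$heads[[nm]]$db + g$db
    net$heads[[nm]]$w <- net$heads[[nm]]$w - lr * vel$heads[[nm]]$dw
    net$heads[[nm]]$b <- net$heads[[nm]]$b - lr * vel$heads[[nm]]$db
  }
  list(net = net, vel = vel)
}

# Stack a list of H x W x 3 images into an (H, W, 3, N) batch.
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

# Input normalization applied before every network: center intensities.
normalize_batch <- function(x) (x - 0.5) * 2
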