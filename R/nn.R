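# Minimal neural-network machinery for the rPPG estimator and SpO2 head.
#
# Layers operate on arrays of dim (C, T, H, W). A network is a list of layer
# specs plus a flat named list of parameter arrays; forward passes optionally
# retain per-layer caches so that net_backward() can return analytic
# gradients aligned with the parameter list. Optimization is plain Adam.
# All randomness (initialization, shuffling) is driven by explicit seeds.

CNORM_EPS <- 1e-5

new_layer <- function(type, ...) c(list(type = type), list(...))

init_conv_params <- function(name, cin, cout, kt, kh, kw) {
  k <- cin * kt * kh * kw
  W <- matrix(stats::rnorm(cout * k, sd = sqrt(2 / k)), nrow = cout)
  p <- list(W = W, b = numeric(cout))
  names(p) <- paste0(name, c(".W", ".b"))
  p
}

init_cnorm_params <- function(name, ch) {
  p <- list(g = rep(1, ch), b = numeric(ch))
  names(p) <- paste0(name, c(".g", ".b"))
  p
}

layer_forward <- function(layer, params, x, keep) {
  switch(layer$type,
    standardize = {
      mu <- rowMeans(x, dims = 1)
      v <- rowMeans(x^2, dims = 1) - mu^2
      y <- (x - mu) / sqrt(pmax(v, 0) + CNORM_EPS)
      list(out = y, cache = NULL)
    },
    conv = {
      y <- cpp_conv3d_forward(
        x, dim(x),
        params[[paste0(layer$name, ".W")]], params[[paste0(layer$name, ".b")]],
        layer$kt, layer$kh, layer$kw, layer$dil
      )
      list(out = y, cache = if (keep) list(x = x))
    },
    cnorm = {
      g <- params[[paste0(layer$name, ".g")]]
      mu <- rowMeans(x, dims = 1)
      v <- pmax(rowMeans(x^2, dims = 1) - mu^2, 0)
      inv <- 1 / sqrt(v + CNORM_EPS)
      xhat <- (x - mu) * inv
      y <- g * xhat + params[[paste0(layer$name, ".b")]]
      list(out = y, cache = if (keep) list(xhat = xhat, inv = inv))
    },
    relu = {
      y <- x * (x > 0)
      list(out = y, cache = if (keep) list(mask = x > 0))
    },
    pool = {
      y <- cpp_avgpool3d_forward(x, dim(x), layer$kernel, layer$stride)
      list(out = y, cache = if (keep) list(in_dims = dim(x)))
    },
    interp2 = {
      d <- dim(x)
      t2 <- d[2]
      tt <- 2L * t2
      src <- (seq_len(tt) - 1 + 0.5) / 2 - 0.5
      i0 <- pmin(pmax(floor(src), 0), t2 - 1)
      wt <- pmin(pmax(src - i0, 0), 1)
      i1 <- pmin(i0 + 1, t2 - 1)
      xm <- x
      dim(xm) <- c(d[1], t2, d[3] * d[4])
      y <- array(0, c(d[1], tt, d[3] * d[4]))
      for (i in seq_len(tt)) {
        y[, i, ] <- (1 - wt[i]) * xm[, i0[i] + 1, ] + wt[i] * xm[, i1[i] + 1, ]
      }
      dim(y) <- c(d[1], tt, d[3], d[4])
      list(out = y, cache = if (keep) list(i0 = i0, i1 = i1, wt = wt, in_dims = d))
    },
    stop_state(paste0("unknown layer type '", layer$type, "'"))
  )
}

layer_backward <- function(layer, params, cache, dy, need_dx) {
  switch(layer$type,
    standardize = list(dx = NULL, grads = list()),
    conv = {
      wmat <- params[[paste0(layer$name, ".W")]]
      res <- cpp_conv3d_backward(
        cache$x, dim(cache$x), wmat,
        dy, layer$kt, layer$kh, layer$kw, layer$dil, FALSE
      )
      g <- list(res$dW, as.numeric(res$db))
      names(g) <- paste0(layer$name, c(".W", ".b"))
      dx <- if (need_dx) {
        cpp_conv3d_dx(dy, dim(dy), wmat, layer$cin,
                      layer$kt, layer$kh, layer$kw, layer$dil)
      }
      list(dx = dx, grads = g)
    },
    cnorm = {
      g <- params[[paste0(layer$name, ".g")]]
      xhat <- cache$xhat
      dxhat <- dy * g
      m1 <- rowMeans(dxhat, dims = 1)
      m2 <- rowMeans(dxhat * xhat, dims = 1)
      dx <- (dxhat - m1 - xhat * m2) * cache$inv
      gr <- list(rowSums(dy * xhat, dims = 1), rowSums(dy, dims = 1))
      names(gr) <- paste0(layer$name, c(".g", ".b"))
      list(dx = dx, grads = gr)
    },
    relu = list(dx = dy * cache$mask, grads = list()),
    pool = {
      dx <- cpp_avgpool3d_backward(dy, cache$in_dims, layer$kernel, layer$stride)
      list(dx = dx, grads = list())
    },
    interp2 = {
      d <- cache$in_dims
      t2 <- d[2]
      tt <- 2L * t2
      dym <- dy
      dim(dym) <- c(d[1], tt, d[3] * d[4])
      dx <- array(0, c(d[1], t2, d[3] * d[4]))
      for (i in seq_len(tt)) {
        dx[, cache$i0[i] + 1, ] <- dx[, cache$i0[i] + 1, ] + (1 - cache$wt[i]) * dym[, i, ]
        dx[, cache$i1[i] + 1, ] <- dx[, cache$i1[i] + 1, ] + cache$wt[i] * dym[, i, ]
      }
      dim(dx) <- d
      list(dx = dx, grads = list())
    }
  )
}

net_forward <- function(layers, params, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], params, x, keep)
    x <- res$out
    if (keep) caches[[i]] <- res$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(layers, params, caches, dy) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    need_dx <- i > 1
    res <- layer_backward(layers[[i]], params, caches[[i]], dy, need_dx)
    grads <- c(grads, res$grads)
    if (!need_dx) break
    dy <- res$dx
  }
  grads
}

accumulate_grads <- function(total, g, scale = 1) {
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] * scale else total[[nm]] + g[[nm]] * scale
  }
  total
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
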