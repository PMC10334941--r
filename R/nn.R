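# Minimal CNN engine with explicit backpropagation.
#
# Batches use the (C, H, W, N) layout (channel fastest) so convolutions
# reduce to one im2col (C++ kernel) plus one BLAS GEMM per layer.  All
# arithmetic is double precision; with a fixed seed and a single-threaded
# BLAS the training trajectory is bit-reproducible.
#
# A network is a list of layer descriptors; parameters live in a flat named
# list (e.g. "conv1.W") so the student and EMA teacher can share structure.

layer_conv <- function(name, cin, cout, k = 3L, stride = 1L, pad = 1L)
  list(type = "conv", name = name, cin = cin, cout = cout, k = k,
       stride = stride, pad = pad)
layer_relu <- function() list(type = "relu")
layer_pool <- function() list(type = "pool")
layer_gap  <- function() list(type = "gap")
layer_resblock <- function(name, cin, cout)
  list(type = "resblock", name = name, cin = cin, cout = cout,
       a = layer_conv(paste0(name, ".a"), cin, cout),
       b = layer_conv(paste0(name, ".b"), cout, cout),
       proj = if (cin != cout)
         layer_conv(paste0(name, ".proj"), cin, cout, k = 1L, pad = 0L))

# He-normal initialization; draw order is fixed by the layer order so a
# seed fully determines the parameter vector.
init_conv <- function(layer) {
  fan_in <- layer$cin * layer$k^2
  W <- matrix(rnorm(layer$cout * fan_in, sd = sqrt(2 / fan_in)),
              layer$cout, fan_in)
  setNames(list(W, numeric(layer$cout)),
           paste0(layer$name, c(".W", ".b")))
}

init_net <- function(net) {
  params <- list()
  for (ly in net) {
    if (ly$type == "conv") params <- c(params, init_conv(ly))
    if (ly$type == "resblock") {
      params <- c(params, init_conv(ly$a), init_conv(ly$b))
      if (!is.null(ly$proj)) params <- c(params, init_conv(ly$proj))
    }
  }
  params
}

conv_fwd <- function(layer, params, x) {
  d <- dim(x)
  cols <- .nn_im2col(x, d[1], d[2], d[3], d[4], layer$k, layer$pad,
                     layer$stride)
  W <- params[[paste0(layer$name, ".W")]]
  b <- params[[paste0(layer$name, ".b")]]
  y <- W %*% cols + b
  ho <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1
  wo <- (d[3] + 2 * layer$pad - layer$k) %/% layer$stride + 1
  dim(y) <- c(layer$cout, ho, wo, d[4])
  list(y = y, cache = list(cols = cols, xdim = d))
}

conv_bwd <- function(layer, params, cache, dy, need_dx = TRUE) {
  d <- dim(dy)
  dim(dy) <- c(d[1], prod(d[2:4]))
  dW <- tcrossprod(dy, cache$cols)
  db <- rowSums(dy)
  grads <- setNames(list(dW, db), paste0(layer$name, c(".W", ".b")))
  if (!need_dx) return(list(dx = NULL, grads = grads))
  W <- params[[paste0(layer$name, ".W")]]
  dcols <- crossprod(W, dy)
  xd <- cache$xdim
  dx <- .nn_col2im(dcols, xd[1], xd[2], xd[3], xd[4], layer$k, layer$pad,
                   layer$stride)
  list(dx = dx, grads = grads)
}

net_forward <- function(net, params, x, keep_cache = TRUE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (ly$type == "conv") {
      r <- conv_fwd(ly, params, x)
      x <- r$y
      if (keep_cache) caches[[i]] <- r$cache
    } else if (ly$type == "relu") {
      if (keep_cache) caches[[i]] <- x > 0
      x <- x * (x > 0)
    } else if (ly$type == "pool") {
      d <- dim(x)
      r <- .nn_maxpool(x, d[1], d[2], d[3], d[4])
      if (keep_cache) caches[[i]] <- list(argmax = r$argmax, xdim = d)
      x <- r$y
    } else if (ly$type == "gap") {
      d <- dim(x)
      dim(x) <- c(d[1], d[2] * d[3], d[4])
      if (keep_cache) caches[[i]] <- d
      x <- colMeans(aperm(x, c(2, 1, 3)), dims = 1)
    } else if (ly$type == "resblock") {
      ra <- conv_fwd(ly$a, params, x)
      mask_a <- ra$y > 0
      h <- ra$y * mask_a
      rb <- conv_fwd(ly$b, params, h)
      if (!is.null(ly$proj)) {
        rp <- conv_fwd(ly$proj, params, x)
        skip <- rp$y
      } else {
        rp <- NULL
        skip <- x
      }
      pre <- rb$y + skip
      mask_out <- pre > 0
      if (keep_cache)
        caches[[i]] <- list(a = ra$cache, b = rb$cache,
                            proj = if (!is.null(rp)) rp$cache,
                            mask_a = mask_a, mask_out = mask_out)
      x <- pre * mask_out
    }
  }
  list(out = x, caches = caches)
}

net_backward <- function(net, params, caches, dy) {
  grads <- list()
  for (i in rev(seq_along(net))) {
    ly <- net[[i]]
    cc <- caches[[i]]
    if (ly$type == "conv") {
      # the input image needs no gradient, so the first layer skips dx
      r <- conv_bwd(ly, params, cc, dy, need_dx = i > 1)
      dy <- r$dx
      grads <- c(grads, r$grads)
    } else if (ly$type == "relu") {
      dy <- dy * cc
    } else if (ly$type == "pool") {
      d <- cc$xdim
      dy <- .nn_maxpool_bwd(dy, cc$argmax, d[1], d[2], d[3], d[4])
    } else if (ly$type == "gap") {
      d <- cc
      hw <- d[2] * d[3]
      dx <- apply(dy / hw, 2, function(col) rep(col, hw))
      dim(dx) <- d
      dy <- dx
    } else if (ly$type == "resblock") {
      dpre <- dy * cc$mask_out
      rb <- conv_bwd(ly$b, params, cc$b, dpre)
      dh <- rb$dx * cc$mask_a
      ra <- conv_bwd(ly$a, params, cc$a, dh)
      dx <- ra$dx
      if (!is.null(ly$proj)) {
        rp <- conv_bwd(ly$proj, params, cc$proj, dpre)
        dx <- dx + rp$dx
        grads <- c(grads, rp$grads)
      } else {
        dx <- dx + dpre
      }
      grads <- c(grads, rb$grads, ra$grads)
    }
  }
  list(dx = dy, grads = grads)
}
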