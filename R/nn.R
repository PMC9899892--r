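# Minimal convolutional network core for the density translator.
#
# Everything operates on single images (batch size 1) stored as H x W x C
# arrays. Convolutions are implemented by im2col + matrix multiply, with
# hand-derived backward passes; parameters live in per-layer environments
# and are updated with Adam. Forward passes return a tape (per-layer cache)
# so the same network can appear several times in one computation graph,
# as the cycle objective requires.

# ---- im2col index cache ----------------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(h, w, cin, k, stride, pad) {
  key <- paste(h, w, cin, k, stride, pad, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  oy <- rep(seq(0L, by = stride, length.out = ho), times = wo)
  ox <- rep(seq(0L, by = stride, length.out = wo), each = ho)
  # columns: kernel row, kernel col, channel (fastest to slowest)
  cols <- matrix(0L, ho * wo, k * k * cin)
  j <- 0L
  for (c in seq_len(cin)) {
    for (kx in seq_len(k)) {
      for (ky in seq_len(k)) {
        j <- j + 1L
        cols[, j] <- (oy + ky) + (ox + kx - 1L) * hp + (c - 1L) * hp * wp
      }
    }
  }
  out <- list(idx = cols, ho = ho, wo = wo, hp = hp, wp = wp)
  .im2col_cache[[key]] <- out
  out
}

# ---- activations -----------------------------------------------------------

act_forward <- function(z, act) {
  switch(act,
    none = z,
    relu = pmax(z, 0),
    lrelu = ifelse(z > 0, z, 0.2 * z),
    tanh = tanh(z),
    sigmoid = 1 / (1 + exp(-z))
  )
}

act_backward <- function(da, z, a, act) {
  switch(act,
    none = da,
    relu = da * (z > 0),
    lrelu = da * ifelse(z > 0, 1, 0.2),
    tanh = da * (1 - a^2),
    sigmoid = da * a * (1 - a)
  )
}

# ---- conv layer ------------------------------------------------------------

conv_layer <- function(cin, cout, k = 3L, stride = 1L, act = "relu", init_sd = 0.1) {
  ly <- new.env(parent = emptyenv())
  ly$cin <- cin; ly$cout <- cout; ly$k <- as.integer(k)
  ly$stride <- as.integer(stride); ly$pad <- as.integer(k %/% 2); ly$act <- act
  ly$W <- matrix(stats::rnorm(k * k * cin * cout, 0, init_sd), k * k * cin, cout)
  ly$b <- numeric(cout)
  ly$gW <- ly$W * 0; ly$gb <- ly$b * 0
  ly$mW <- ly$W * 0; ly$vW <- ly$W * 0; ly$mb <- ly$b * 0; ly$vb <- ly$b * 0
  ly
}

conv_forward <- function(ly, x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  ic <- im2col_indices(h, w, ly$cin, ly$k, ly$stride, ly$pad)
  if (ly$pad > 0) {
    xp <- array(0, c(ic$hp, ic$wp, ly$cin))
    xp[(ly$pad + 1):(ly$pad + h), (ly$pad + 1):(ly$pad + w), ] <- x
  } else xp <- x
  col <- matrix(xp[ic$idx], nrow(ic$idx), ncol(ic$idx))
  z <- col %*% ly$W
  z <- sweep(z, 2, ly$b, `+`)
  a <- act_forward(z, ly$act)
  list(out = array(a, c(ic$ho, ic$wo, ly$cout)),
       cache = list(col = col, z = z, a = a, h = h, w = w, ic = ic))
}

conv_backward <- function(ly, cache, dy, accumulate = TRUE) {
  ic <- cache$ic
  da <- matrix(dy, ic$ho * ic$wo, ly$cout)
  dz <- act_backward(da, cache$z, cache$a, ly$act)
  if (accumulate) {
    ly$gW <- ly$gW + crossprod(cache$col, dz)
    ly$gb <- ly$gb + colSums(dz)
  }
  dcol <- tcrossprod(dz, ly$W)
  dxp <- numeric(ic$hp * ic$wp * ly$cin)
  for (j in seq_len(ncol(ic$idx))) {
    jj <- ic$idx[, j]
    dxp[jj] <- dxp[jj] + dcol[, j]
  }
  dxp <- array(dxp, c(ic$hp, ic$wp, ly$cin))
  p <- ly$pad
  if (p > 0) dxp[(p + 1):(p + cache$h), (p + 1):(p + cache$w), , drop = FALSE]
  else dxp
}

# ---- sequential net --------------------------------------------------------

net_forward <- function(net, x) {
  tapes <- vector("list", length(net))
  for (i in seq_along(net)) {
    fw <- conv_forward(net[[i]], x)
    x <- fw$out
    tapes[[i]] <- fw$cache
  }
  list(out = x, tapes = tapes)
}

net_backward <- function(net, tapes, dy, accumulate = TRUE) {
  for (i in rev(seq_along(net))) {
    dy <- conv_backward(net[[i]], tapes[[i]], dy, accumulate = accumulate)
  }
  dy
}

net_zero_grad <- function(net) {
  for (ly in net) { ly$gW[] <- 0; ly$gb[] <- 0 }
  invisible(net)
}

net_adam_step <- function(net, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8, t = 1) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (ly in net) {
    ly$mW <- beta1 * ly$mW + (1 - beta1) * ly$gW
    ly$vW <- beta2 * ly$vW + (1 - beta2) * ly$gW^2
    ly$W <- ly$W - lr * (ly$mW / bc1) / (sqrt(ly$vW / bc2) + eps)
    ly$mb <- beta1 * ly$mb + (1 - beta1) * ly$gb
    ly$vb <- beta2 * ly$vb + (1 - beta2) * ly$gb^2
    ly$b <- ly$b - lr * (ly$mb / bc1) / (sqrt(ly$vb / bc2) + eps)
  }
  invisible(net)
}

net_params <- function(net) {
  purrr::map(net, function(ly) list(W = ly$W, b = ly$b))
}

net_set_params <- function(net, params) {
  for (i in seq_along(net)) {
    net[[i]]$W <- params[[i]]$W
    net[[i]]$b <- params[[i]]$b
  }
  invisible(net)
}

n_params <- function(net) sum(purrr::map_dbl(net, function(ly) length(ly$W) + length(ly$b)))

# ---- generator / discriminator builders ------------------------------------

# Residual generator: y = x + 0.5 * tanh(conv stack). Near-identity at
# initialisation, bounded residual, single grayscale channel.
build_generator <- function(ngf = 8L) {
  list(
    conv_layer(1L, ngf, act = "relu"),
    conv_layer(ngf, ngf, act = "relu"),
    conv_layer(ngf, 1L, act = "tanh")
  )
}

gen_forward <- function(gen, x) {
  x <- as_chw(x)
  fw <- net_forward(gen, x)
  list(out = x + 0.5 * fw$out, tapes = fw$tapes, x = x)
}

gen_backward <- function(gen, fwd, dy, accumulate = TRUE) {
  dx_resid <- net_backward(gen, fwd$tapes, 0.5 * dy, accumulate = accumulate)
  dy + dx_resid
}

# Patch discriminator: three strided convs ending in per-patch sigmoid
# probabilities of "real".
build_discriminator <- function(ndf = 8L) {
  list(
    conv_layer(1L, ndf, stride = 2L, act = "lrelu"),
    conv_layer(ndf, 2L * ndf, stride = 2L, act = "lrelu"),
    conv_layer(2L * ndf, 1L, stride = 1L, act = "sigmoid")
  )
}

as_chw <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}
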