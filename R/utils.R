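# Internal helpers shared across modules.
#
# Image convention: a mammogram is a numeric matrix in [0,1], dimension
# height x width; row index = y (downward), column index = x (rightward).
# Lesion boxes are 0-based half-open rectangles [x, x+w) x [y, y+h).

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label; keeps
# independent stages decoupled while remaining fully determined by the
# parent seed. Result is a non-negative integer < 2^31 - 1.
derive_seed <- function(seed, label) {
  u <- utf8ToInt(paste0(label, ":", as.integer(seed)))
  h <- 0
  for (ch in u) h <- (h * 31 + ch) %% 2147483563
  as.integer(h)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Separable Gaussian blur with reflective padding; sigma = 0 is identity.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), `+`)
    idx[idx < 1] <- 2 - idx[idx < 1]        # reflect
    idx[idx > n] <- 2 * n - idx[idx > n]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2 * r + 1)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

# Bilinear resize to out_h x out_w (align-corners = FALSE convention).
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c * wy * (1 - wx) + d * wy * wx
}

is_image <- function(x) is.matrix(x) && is.numeric(x)

stopifnot_image <- function(x, name = "image") {
  if (!is_image(x)) stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
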