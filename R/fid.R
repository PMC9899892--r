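#' Deterministic image feature extraction for Frechet-distance scoring
#'
#' The default extractor is a fixed-seed convolutional projection: each
#' image is resized to a common working resolution, filtered with a bank of
#' seeded random convolution kernels at two scales, rectified, and
#' average-pooled over a coarse spatial grid to a `d`-dimensional embedding.
#' It needs no pretrained weights, is identical across runs and machines for
#' a given spec, and preserves the distance protocol's logic; absolute
#' distance values are of course specific to the extractor, so published
#' Inception-feature values are not comparable.
#'
#' @param images List of numeric matrices (or a manifest tibble with an
#'   `image` list-column).
#' @param extractor_spec Spec from [feature_extractor_spec()].
#' @return An `n x d` feature matrix.
#' @export
extract_features <- function(images, extractor_spec = feature_extractor_spec()) {
  if (is.data.frame(images)) images <- images$image
  if (length(images) == 0) stop("image set is empty", call. = FALSE)
  filters <- extractor_filters(extractor_spec)
  feats <- purrr::map(images, extract_one, spec = extractor_spec, filters = filters)
  do.call(rbind, feats)
}

#' @param d Embedding dimension (default 64).
#' @param work_size Common `c(height, width)` images are resized to.
#' @param kernel_size Convolution kernel side length.
#' @param pool_grid Pooling grid (`g x g` cells per filter map).
#' @param seed Seed fixing the random filter bank.
#' @rdname extract_features
#' @export
feature_extractor_spec <- function(d = 64, work_size = c(64, 40), kernel_size = 5,
                                   pool_grid = 2, seed = 1234) {
  n_filters <- d / (pool_grid^2)
  if (n_filters != round(n_filters)) {
    stop("d must be divisible by pool_grid^2", call. = FALSE)
  }
  structure(list(d = as.integer(d), work_size = as.integer(work_size),
                 kernel_size = as.integer(kernel_size),
                 pool_grid = as.integer(pool_grid),
                 n_filters = as.integer(n_filters), seed = as.integer(seed)),
            class = "feature_extractor_spec")
}

extractor_filters <- function(spec) {
  with_seed(spec$seed, {
    k <- spec$kernel_size
    purrr::map(seq_len(spec$n_filters), function(i) {
      f <- matrix(stats::rnorm(k * k), k, k)
      f - mean(f)  # zero-mean: respond to structure, not brightness offset
    })
  })
}

extract_one <- function(img, spec, filters) {
  stopifnot_image(img)
  x <- resize_bilinear(img, spec$work_size[1], spec$work_size[2])
  g <- spec$pool_grid
  h <- nrow(x); w <- ncol(x)
  ybrk <- round(seq(0, h, length.out = g + 1))
  xbrk <- round(seq(0, w, length.out = g + 1))
  out <- numeric(0)
  for (f in filters) {
    resp <- pmax(conv2_valid_same(x, f), 0)
    for (iy in seq_len(g)) for (ix in seq_len(g)) {
      cell <- resp[(ybrk[iy] + 1):ybrk[iy + 1], (xbrk[ix] + 1):xbrk[ix + 1]]
      out <- c(out, mean(cell))
    }
  }
  out
}

# Same-size 2-D convolution with zero padding (direct, small kernels).
conv2_valid_same <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2; pw <- kw %/% 2
  h <- nrow(x); w <- ncol(x)
  xp <- matrix(0, h + 2 * ph, w + 2 * pw)
  xp[(ph + 1):(ph + h), (pw + 1):(pw + w)] <- x
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    out <- out + k[i, j] * xp[i:(i + h - 1), j:(j + w - 1)]
  }
  out
}

#' Frechet distance between two feature samples
#'
#' Gaussian-fit Frechet distance
#' \eqn{|\mu_A-\mu_B|^2 + Tr(C_A + C_B - 2 (C_A C_B)^{1/2})} with sample
#' means and covariances. The matrix square root is taken through symmetric
#' eigendecompositions; covariances are regularised by `eps` on the diagonal
#' only when near-singular, and negative eigenvalue tails are clipped at
#' zero, so the result is always finite, real, non-negative in practice and
#' symmetric in its arguments.
#'
#' @param features_A,features_B `n x d` feature matrices (same `d`).
#' @param eps Ridge added to near-singular covariances.
#' @return A non-negative scalar.
#' @examples
#' a <- cbind(c(-1, 0, 1))          # sample mean 0, sample var 1
#' b <- cbind(c(0, 1, 2))           # sample mean 1, sample var 1
#' frechet_distance(a, b)           # closed form: 1
#' @export
frechet_distance <- function(features_A, features_B, eps = 1e-6) {
  A <- as.matrix(features_A); B <- as.matrix(features_B)
  if (ncol(A) != ncol(B)) stop("feature dimensions differ", call. = FALSE)
  muA <- colMeans(A); muB <- colMeans(B)
  CA <- safe_cov(A, eps); CB <- safe_cov(B, eps)
  # sqrt(CA) via symmetric eigendecomposition
  eA <- eigen(CA, symmetric = TRUE)
  sqA <- eA$vectors %*% (sqrt(pmax(eA$values, 0)) * t(eA$vectors))
  M <- sqA %*% CB %*% sqA                       # similar to CA %*% CB, symmetric PSD
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  tr_sqrt <- sum(sqrt(pmax(eM$values, 0)))
  sum((muA - muB)^2) + sum(diag(CA)) + sum(diag(CB)) - 2 * tr_sqrt
}

safe_cov <- function(X, eps) {
  C <- stats::cov(X)
  if (nrow(X) < 2) C <- matrix(0, ncol(X), ncol(X))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eps) C <- C + diag(eps, ncol(X))
  C
}

#' Frechet-distance bounds protocol for a synthetic image set
#'
#' Because the Frechet distance has no absolute scale, it is bounded with
#' real data: the lower bound is the distance between two seeded halves of
#' the real high-density set (what "same distribution" looks like at this
#' sample size), the upper bound the distance between real low-density and
#' real high-density sets (the gap translation is meant to close). The
#' synthetic set is scored against the full real high-density set and judged
#' in-bounds when `lower <= value <= upper`.
#'
#' @param real_low_manifest,real_high_manifest,synthetic_manifest Manifest
#'   tibbles with `image` list-columns (or plain lists of matrices).
#' @param extractor_spec See [feature_extractor_spec()].
#' @param seed Seed for the half/half split of the real high-density set.
#' @param min_split Minimum images required per half.
#' @return An object of class `fid_bounds_report`: list with `lower`,
#'   `upper`, `value`, `in_bounds`, `n_low`, `n_high`, `n_synthetic`.
#' @export
fid_bounds <- function(real_low_manifest, real_high_manifest, synthetic_manifest,
                       extractor_spec = feature_extractor_spec(), seed = 1,
                       min_split = 5) {
  get_imgs <- function(m) if (is.data.frame(m)) m$image else m
  lo <- get_imgs(real_low_manifest)
  hi <- get_imgs(real_high_manifest)
  sy <- get_imgs(synthetic_manifest)
  if (length(hi) < 2 * min_split) {
    stop(sprintf("need at least %d real high-density images for the bound split",
                 2 * min_split), call. = FALSE)
  }
  f_lo <- extract_features(lo, extractor_spec)
  f_hi <- extract_features(hi, extractor_spec)
  f_sy <- extract_features(sy, extractor_spec)
  half <- with_seed(derive_seed(seed, "fid-split"),
                    sample(length(hi), floor(length(hi) / 2)))
  lower <- frechet_distance(f_hi[half, , drop = FALSE], f_hi[-half, , drop = FALSE])
  upper <- frechet_distance(f_lo, f_hi)
  value <- frechet_distance(f_sy, f_hi)
  structure(list(lower = lower, upper = upper, value = value,
                 in_bounds = lower <= value && value <= upper,
                 n_low = length(lo), n_high = length(hi), n_synthetic = length(sy)),
            class = "fid_bounds_report")
}

#' @export
print.fid_bounds_report <- function(x, ...) {
  cat(sprintf("<fid_bounds_report> lower %.3f <= value %.3f <= upper %.3f : %s\n",
              x$lower, x$value, x$upper, if (x$in_bounds) "in bounds" else "OUT OF BOUNDS"))
  invisible(x)
}

#' @method tidy fid_bounds_report
#' @export
tidy.fid_bounds_report <- function(x, ...) {
  tibble::tibble(bound = c("lower", "value", "upper"),
                 fid = c(x$lower, x$value, x$upper))
}

#' @method glance fid_bounds_report
#' @export
glance.fid_bounds_report <- function(x, ...) {
  tibble::tibble(lower = x$lower, value = x$value, upper = x$upper,
                 in_bounds = x$in_bounds, n_low = x$n_low, n_high = x$n_high,
                 n_synthetic = x$n_synthetic)
}
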