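#' Loss terms of the cycle-consistent translation objective
#'
#' The translator is trained with the classic unpaired-translation objective:
#' two adversarial terms (one per mapping direction, binary cross entropy on
#' the discriminator outputs) plus an L1 cycle-consistency term weighted by
#' `lambda_cyc` (default 10):
#' \deqn{L(G,F,D_X,D_Y) = L_{GAN}(G,D_Y) + L_{GAN}(F,D_X) + \lambda L_{cyc}(G,F)}
#'
#' `adversarial_loss()` evaluates the printed expectation form
#' \eqn{E[\log D(real)] + E[\log(1 - D(fake))]}; larger is better for the
#' discriminator, and a perfect discriminator attains 0. Outputs are clamped
#' away from 0/1 by `eps` so the logs stay finite.
#'
#' `cycle_loss()` is the mean absolute reconstruction error of the
#' source-side pair plus that of the target-side pair.
#'
#' @param d_real_outputs,d_fake_outputs Discriminator outputs in (0,1)
#'   (any shape; patch outputs are averaged).
#' @param eps Clamp width inside the logarithms.
#' @param x,y Original images; `x_reconstructed`, `y_reconstructed` their
#'   round-trip reconstructions F(G(x)) and G(F(y)).
#' @param l_gan_xy,l_gan_yx,l_cyc Loss components.
#' @param lambda_cyc Cycle-consistency weight (default 10).
#' @return A scalar loss value.
#' @examples
#' adversarial_loss(1, 0)                     # perfect discriminator: 0
#' total_loss(0, 0, 1)                        # default weighting: 10
#' @name translation_losses
NULL

#' @rdname translation_losses
#' @export
adversarial_loss <- function(d_real_outputs, d_fake_outputs, eps = 1e-7) {
  if (length(d_real_outputs) == 0 || length(d_fake_outputs) == 0) {
    stop("discriminator output batches must be nonempty", call. = FALSE)
  }
  # one-sided clamps: only the log singularities need protection, so the
  # perfect-discriminator corner (real -> 1, fake -> 0) evaluates to exactly 0
  r <- pmax(as.numeric(d_real_outputs), eps)
  f <- pmin(as.numeric(d_fake_outputs), 1 - eps)
  mean(log(r)) + mean(log(1 - f))
}

#' @rdname translation_losses
#' @export
cycle_loss <- function(x, x_reconstructed, y, y_reconstructed) {
  if (!identical(dim(x), dim(x_reconstructed)) ||
      !identical(dim(y), dim(y_reconstructed))) {
    stop("reconstruction shapes must match their originals", call. = FALSE)
  }
  mean(abs(x_reconstructed - x)) + mean(abs(y_reconstructed - y))
}

#' @rdname translation_losses
#' @export
total_loss <- function(l_gan_xy, l_gan_yx, l_cyc, lambda_cyc = 10) {
  if (lambda_cyc < 0) stop("lambda_cyc must be >= 0", call. = FALSE)
  l_gan_xy + l_gan_yx + lambda_cyc * l_cyc
}

#' Translator training configuration
#'
#' Defaults follow the full-scale recipe: lambda 10, a maximum of 200 epochs
#' at batch size 1, Adam at learning rate 2e-4 with linear decay to zero over
#' the second half of training. [desk_translator_config()] is the CPU desk
#' preset: 64 x 64 images, 400 iterations, learning rate 1e-3 — the larger
#' step suits the small residual network and short schedule.
#'
#' @param lambda_cyc Cycle-consistency weight.
#' @param epochs Maximum training epochs (one epoch = one pass over the
#'   source manifest at batch size 1).
#' @param iterations If non-`NULL`, total iteration count overriding
#'   `epochs`.
#' @param batch_size Images per update (the recipe uses 1).
#' @param image_size `c(height, width)` the model operates at.
#' @param ngf,ndf Base channel widths of generator and discriminator.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param adv_mode `"bce"` (binary cross entropy, the printed form) or
#'   `"lsgan"` (least-squares, the reference framework's default).
#' @param eps Log clamp used in the adversarial loss.
#' @param ... Passed to `translator_config()`.
#' @return A list of class `translator_config`.
#' @export
translator_config <- function(lambda_cyc = 10, epochs = 200, iterations = NULL,
                              batch_size = 1, image_size = c(64, 64),
                              ngf = 8, ndf = 8, lr = 2e-4,
                              beta1 = 0.5, beta2 = 0.999,
                              adv_mode = c("bce", "lsgan"), eps = 1e-7) {
  structure(list(
    lambda_cyc = lambda_cyc, epochs = epochs, iterations = iterations,
    batch_size = batch_size, image_size = as.integer(image_size),
    ngf = as.integer(ngf), ndf = as.integer(ndf), lr = lr,
    beta1 = beta1, beta2 = beta2, adv_mode = match.arg(adv_mode), eps = eps
  ), class = "translator_config")
}

#' @rdname translator_config
#' @export
desk_translator_config <- function(...) {
  cfg <- translator_config(...)
  dots <- names(list(...))
  if (!"iterations" %in% dots) cfg$iterations <- 400L
  if (!"lr" %in% dots) cfg$lr <- 1e-3
  cfg
}

#' Plan the translator model registry for a set of datasets
#'
#' One translator is trained per dataset and view, except that datasets too
#' small to split by view get a single combined CC+MLO model. With one small
#' and two large datasets this yields the five-model registry
#' (one `All`-view model plus per-view models for each large dataset).
#'
#' @param dataset_specs A data frame with columns `dataset`, `n_cc`, `n_mlo`
#'   and optionally `split_threshold` (minimum per-view count needed to train
#'   view-specific models; default 100).
#' @param split_threshold Default threshold used where the spec has none.
#' @return A tibble of model configs: `model_id`, `dataset`, `view`
#'   (`"CC"`, `"MLO"` or `"All"`), `n_train`.
#' @examples
#' specs <- data.frame(dataset = c("BC", "CS", "OP"),
#'                     n_cc = c(55, 463, 894), n_mlo = c(43, 366, 786))
#' build_model_registry(specs)
#' @export
build_model_registry <- function(dataset_specs, split_threshold = 100) {
  if (!is.data.frame(dataset_specs) || nrow(dataset_specs) == 0) {
    stop("dataset_specs must be a nonempty data frame", call. = FALSE)
  }
  purrr::pmap_dfr(dataset_specs, function(dataset, n_cc, n_mlo, ...) {
    thr <- list(...)$split_threshold %||% split_threshold
    if (min(n_cc, n_mlo) < thr) {
      tibble::tibble(model_id = paste0(dataset, "-All"), dataset = dataset,
                     view = "All", n_train = n_cc + n_mlo)
    } else {
      tibble::tibble(
        model_id = paste0(dataset, c("-CC", "-MLO")), dataset = dataset,
        view = c("CC", "MLO"), n_train = c(n_cc, n_mlo)
      )
    }
  })
}

assert_healthy <- function(manifest, label) {
  bad <- manifest$pathology == "mass" |
    purrr::map_int(manifest$lesions, ~ if (is.null(.x)) 0L else nrow(.x)) > 0
  if (any(bad)) {
    stop(sprintf(
      "%s manifest contains %d record(s) with masses; translators train on healthy images only to avoid feature hallucination",
      label, sum(bad)
    ), call. = FALSE)
  }
}

#' Train an unpaired low-to-high-density translator
#'
#' Trains generators G (low to high density) and F (high to low) against
#' patch discriminators DY and DX with the objective in
#' [translation_losses]: alternating discriminator and generator updates,
#' batch size 1, unpaired seeded sampling of the two manifests. Training
#' refuses records containing masses — translators are fit on healthy images
#' only so they cannot learn to hallucinate (or remove) lesions.
#'
#' @param source_manifest Manifest tibble of low-density (domain X) records.
#' @param target_manifest Manifest tibble of high-density (domain Y) records.
#' @param config A [translator_config()].
#' @param seed Integer seed for initialisation and sampling; the same inputs
#'   and seed reproduce the loss history exactly.
#' @return An object of class `density_translator` with elements `G`, `F`,
#'   `DX`, `DY` (parameter lists), `config`, `seed`, and `history`, a tibble
#'   of per-iteration `l_gan_xy`, `l_gan_yx`, `l_cyc`, `l_total` satisfying
#'   `l_total = l_gan_xy + l_gan_yx + lambda * l_cyc`.
#' @export
train_translator <- function(source_manifest, target_manifest,
                             config = desk_translator_config(), seed = 1) {
  stopifnot(is.data.frame(source_manifest), is.data.frame(target_manifest))
  if (nrow(source_manifest) == 0 || nrow(target_manifest) == 0) {
    stop("training manifests must be nonempty", call. = FALSE)
  }
  assert_healthy(source_manifest, "source")
  assert_healthy(target_manifest, "target")
  hh <- config$image_size[1]; ww <- config$image_size[2]
  xs <- purrr::map(source_manifest$image, resize_bilinear, out_h = hh, out_w = ww)
  ys <- purrr::map(target_manifest$image, resize_bilinear, out_h = hh, out_w = ww)

  n_iter <- config$iterations %||% (config$epochs * length(xs))
  lambda <- config$lambda_cyc
  eps <- config$eps

  with_seed(derive_seed(seed, "translator"), {
    G <- build_generator(config$ngf)
    Fg <- build_generator(config$ngf)
    DX <- build_discriminator(config$ndf)
    DY <- build_discriminator(config$ndf)
    x_order <- sample(rep_len(seq_along(xs), n_iter))
    y_order <- sample(rep_len(seq_along(ys), n_iter))

    hist <- matrix(0, n_iter, 4)
    for (t in seq_len(n_iter)) {
      lr_t <- config$lr * lr_decay_factor(t, n_iter)
      x <- xs[[x_order[t]]]
      y <- as_chw(ys[[y_order[t]]])

      g_x <- gen_forward(G, x)            # y_hat = G(x)
      f_y <- gen_forward(Fg, y)           # x_hat = F(y)
      f_gx <- gen_forward(Fg, g_x$out)    # x_rec
      g_fy <- gen_forward(G, f_y$out)     # y_rec

      # --- discriminator updates (maximise the printed adversarial form)
      dY_real <- net_forward(DY, y)
      dY_fake <- net_forward(DY, g_x$out)
      dX_real <- net_forward(DX, as_chw(x))
      dX_fake <- net_forward(DX, f_y$out)

      l_gan_xy <- adversarial_loss(dY_real$out, dY_fake$out, eps)
      l_gan_yx <- adversarial_loss(dX_real$out, dX_fake$out, eps)
      l_cyc <- cycle_loss(as_chw(x), f_gx$out, y, g_fy$out)

      net_zero_grad(DY); net_zero_grad(DX)
      disc_accumulate(DY, dY_real, dY_fake, eps, config$adv_mode)
      disc_accumulate(DX, dX_real, dX_fake, eps, config$adv_mode)
      net_adam_step(DY, lr_t, config$beta1, config$beta2, t = t)
      net_adam_step(DX, lr_t, config$beta1, config$beta2, t = t)

      # --- generator updates: adversarial (non-saturating) + lambda * cycle
      net_zero_grad(G); net_zero_grad(Fg)

      dY_fake2 <- net_forward(DY, g_x$out)
      dX_fake2 <- net_forward(DX, f_y$out)
      d_yhat <- net_backward(DY, dY_fake2$tapes,
                             gen_adv_grad(dY_fake2$out, eps, config$adv_mode),
                             accumulate = FALSE)
      d_xhat <- net_backward(DX, dX_fake2$tapes,
                             gen_adv_grad(dX_fake2$out, eps, config$adv_mode),
                             accumulate = FALSE)

      # cycle gradients: d/d rec of lambda * mean|rec - orig|
      n_px <- length(x)
      d_xrec <- lambda * sign(f_gx$out - as_chw(x)) / n_px
      d_yrec <- lambda * sign(g_fy$out - y) / n_px
      d_yhat <- d_yhat + gen_backward(Fg, f_gx, d_xrec)     # through F into y_hat
      d_xhat <- d_xhat + gen_backward(G, g_fy, d_yrec)      # through G into x_hat
      gen_backward(G, g_x, d_yhat)
      gen_backward(Fg, f_y, d_xhat)

      net_adam_step(G, lr_t, config$beta1, config$beta2, t = t)
      net_adam_step(Fg, lr_t, config$beta1, config$beta2, t = t)

      hist[t, ] <- c(l_gan_xy, l_gan_yx, l_cyc,
                     total_loss(l_gan_xy, l_gan_yx, l_cyc, lambda))
    }

    structure(list(
      G = net_params(G), F = net_params(Fg),
      DX = net_params(DX), DY = net_params(DY),
      config = config, seed = as.integer(seed),
      history = tibble::tibble(
        iteration = seq_len(n_iter),
        l_gan_xy = hist[, 1], l_gan_yx = hist[, 2],
        l_cyc = hist[, 3], l_total = hist[, 4]
      )
    ), class = "density_translator")
  })
}

# Linear decay to zero over the second half of training.
lr_decay_factor <- function(t, n_iter) {
  half <- n_iter / 2
  if (t <= half) 1 else max(0, (n_iter - t) / max(1, n_iter - half))
}

# Discriminator gradient of the (negated) adversarial objective, backprop'd
# through its own net with weight accumulation.
disc_accumulate <- function(D, fw_real, fw_fake, eps, mode) {
  r <- fw_real$out; f <- fw_fake$out
  n <- length(r); m <- length(f)
  if (mode == "bce") {
    rc <- pmin(pmax(r, eps), 1 - eps)
    fc <- pmin(pmax(f, eps), 1 - eps)
    d_real <- -1 / (n * rc)          # minimise -E log D(real)
    d_fake <- 1 / (m * (1 - fc))     # minimise -E log(1 - D(fake))
  } else {                           # least-squares: (D(real)-1)^2 + D(fake)^2
    d_real <- 2 * (r - 1) / n
    d_fake <- 2 * f / m
  }
  net_backward(D, fw_real$tapes, array(d_real, dim(r)))
  net_backward(D, fw_fake$tapes, array(d_fake, dim(f)))
  invisible(D)
}

# Generator-side adversarial gradient at the discriminator output on fakes.
gen_adv_grad <- function(d_fake, eps, mode) {
  m <- length(d_fake)
  if (mode == "bce") {
    fc <- pmin(pmax(d_fake, eps), 1 - eps)
    array(-1 / (m * fc), dim(d_fake))        # non-saturating: minimise -E log D(fake)
  } else {
    array(2 * (d_fake - 1) / m, dim(d_fake)) # least-squares generator target 1
  }
}

#' Translate a record's image to the high-density domain
#'
#' Applies generator G to a record, producing a synthetic high-density copy:
#' same image shape, values clipped to \[0,1\], lesion boxes carried over
#' unchanged, `provenance` set to `"synthetic"` and a `parent_id` column
#' recording the source record. Inference is deterministic.
#'
#' @param model A `density_translator`.
#' @param record A one-row manifest tibble whose image matches the model's
#'   configured size (use `resize = TRUE` to translate records of other sizes
#'   by resizing through the model resolution and back).
#' @param direction `"forward"` (G: low to high density) or `"backward"` (F).
#' @param resize Allow sizes other than the configured one.
#' @return A one-row manifest tibble.
#' @export
translate <- function(model, record, direction = c("forward", "backward"),
                      resize = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "density_translator"), is.data.frame(record))
  img <- record$image[[1]]
  hh <- model$config$image_size[1]; ww <- model$config$image_size[2]
  orig_dim <- dim(img)
  if (!identical(as.integer(orig_dim), c(hh, ww))) {
    if (!resize) {
      stop(sprintf("record image is %dx%d but the model expects %dx%d",
                   orig_dim[1], orig_dim[2], hh, ww), call. = FALSE)
    }
    img <- resize_bilinear(img, hh, ww)
  }
  net <- build_generator(model$config$ngf)
  net_set_params(net, if (direction == "forward") model$G else model$F)
  out <- gen_forward(net, img)$out[, , 1]
  out <- clip01(out)
  if (!identical(as.integer(orig_dim), c(hh, ww))) {
    out <- clip01(resize_bilinear(out, orig_dim[1], orig_dim[2]))
  }
  rec <- record
  rec$image <- list(out)
  rec$provenance <- "synthetic"
  rec$parent_id <- record$id
  rec$id <- paste0(record$id, "-syn")
  rec
}

#' @method tidy density_translator
#' @export
tidy.density_translator <- function(x, ...) x$history

#' @method glance density_translator
#' @export
glance.density_translator <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    iterations = nrow(x$history),
    lambda_cyc = x$config$lambda_cyc,
    adv_mode = x$config$adv_mode,
    final_l_cyc = last$l_cyc,
    final_l_total = last$l_total,
    n_parameters = 2 * sum(purrr::map_dbl(x$G, ~ length(.x$W) + length(.x$b))) +
      2 * sum(purrr::map_dbl(x$DX, ~ length(.x$W) + length(.x$b))),
    seed = x$seed
  )
}

#' @export
print.density_translator <- function(x, ...) {
  cat(sprintf(
    "<density_translator> %d iterations at %dx%d (lambda = %g, %s adversarial loss)\n",
    nrow(x$history), x$config$image_size[1], x$config$image_size[2],
    x$config$lambda_cyc, x$config$adv_mode
  ))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: gan_xy %.4f, gan_yx %.4f, cyc %.4f, total %.4f\n",
              last$l_gan_xy, last$l_gan_yx, last$l_cyc, last$l_total))
  invisible(x)
}
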