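#' @title Mammogram phantoms with controllable fibroglandular density
#'
#' @description
#' [generate_phantom()] draws a single seedable, fully deterministic
#' mammogram-like phantom: a half-elliptical breast on a dark background
#' (chest wall at the left edge), band-pass textured fibroglandular tissue
#' concentrated toward the chest wall and thresholded to cover a requested
#' fraction of the breast area, an MLO pectoral wedge when asked for, a
#' vendor-style appearance transform, and optional bright elliptical masses
#' with ground-truth bounding boxes.
#'
#' The phantom's truth density is an area fraction, i.e. it lives on the
#' LIBRA-style percent-density scale, and its BI-RADS category is assigned
#' with [map_libra()].
#'
#' @param view `"CC"` or `"MLO"`. MLO adds a bright pectoral wedge; the wedge
#'   is excluded from the breast mask used for density accounting, as density
#'   software excludes the pectoral muscle.
#' @param target_density_percent Desired fibroglandular area percentage of
#'   the breast mask, in \[0, 100\].
#' @param domain_style Vendor-style appearance tag; see [domain_styles()].
#' @param n_masses Number of bright masses to insert (each gets a lesion box).
#' @param size Integer `c(height, width)`. The default 256 x 160 keeps the
#'   clinical 1332:800 aspect ratio at desk scale; pass `c(1332, 800)` for
#'   full scale.
#' @param seed Integer seed; equal inputs and seed give byte-identical output.
#' @return A one-row tibble (the manifest row) with columns `id`, `view`,
#'   `density_percent`, `density_source`, `birads`, `domain`, `provenance`,
#'   `pathology`, and list-columns `image` (height x width matrix in \[0,1\]),
#'   `mask` (logical breast mask) and `lesions` (tibble with `x`, `y`, `w`,
#'   `h`, 0-based half-open pixel boxes).
#' @examples
#' rec <- generate_phantom("CC", 50, n_masses = 1, size = c(128, 80), seed = 7)
#' measure_density(rec$image[[1]], rec$mask[[1]])
#' @export
generate_phantom <- function(view = c("CC", "MLO"), target_density_percent = 25,
                             domain_style = "hologic-like", n_masses = 0,
                             size = c(256, 160), seed = 1) {
  view <- match.arg(view)
  if (!is.numeric(target_density_percent) || length(target_density_percent) != 1 ||
      is.na(target_density_percent) ||
      target_density_percent < 0 || target_density_percent > 100) {
    stop("target_density_percent must be a single value in [0, 100]", call. = FALSE)
  }
  style <- lookup_style(domain_style)
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (h < 32 || w < 20) stop("image size too small for a phantom", call. = FALSE)

  with_seed(derive_seed(seed, paste("phantom", view, target_density_percent,
                                    domain_style, n_masses, h, w)), {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)

    # breast outline: half ellipse anchored on the chest wall (left edge)
    cy <- h * (0.5 + stats::runif(1, -0.03, 0.03))
    ay <- h * (if (view == "CC") 0.42 else 0.47) * stats::runif(1, 0.95, 1.05)
    ax <- w * (if (view == "CC") 0.88 else 0.95) * stats::runif(1, 0.95, 1.0)
    outline <- ((xx - 1) / ax)^2 + ((yy - cy) / ay)^2 <= 1

    # MLO pectoral wedge: triangle descending from the top-left corner
    if (view == "MLO") {
      y0 <- h * stats::runif(1, 0.42, 0.5)
      x0 <- w * stats::runif(1, 0.38, 0.45)
      wedge <- outline & (xx - 1) < x0 * (1 - (yy - 1) / y0)
    } else {
      wedge <- matrix(FALSE, h, w)
    }
    mask <- outline & !wedge
    n_mask <- sum(mask)

    # fat background with smooth low-frequency variation
    img <- matrix(0, h, w)
    fat <- 0.40 + 0.05 * gaussian_blur(matrix(stats::rnorm(h * w), h, w), h / 16)
    img[outline] <- clip01(fat[outline] + stats::rnorm(sum(outline), 0, 0.01))

    # fibroglandular texture: band-pass noise biased toward the chest wall,
    # thresholded at the exact order statistic for the target area fraction
    z <- matrix(stats::rnorm(h * w), h, w)
    band <- gaussian_blur(z, 1.2) - gaussian_blur(z, 4.0)
    band <- band / stats::sd(band)
    field <- band + 1.1 * (1 - (xx - 1) / w)
    dense <- matrix(FALSE, h, w)
    k <- round(n_mask * target_density_percent / 100)
    if (k > 0 && n_mask > 0) {
      midx <- which(mask)
      dense[midx[order(field[midx], decreasing = TRUE)[seq_len(k)]]] <- TRUE
    }
    img[dense] <- clip01(0.74 + 0.06 * band[dense] + stats::rnorm(sum(dense), 0, 0.02))

    if (view == "MLO") {
      img[wedge] <- clip01(0.78 + 0.10 * (1 - (xx[wedge] - 1) / w) +
                             stats::rnorm(sum(wedge), 0, 0.015))
    }

    # lesions: bright gaussian-profile elliptical masses, non-overlapping
    lesions <- place_masses(img, mask, n_masses, h, w)
    img <- lesions$image

    # vendor-style appearance: blur, gamma, additive noise
    img <- gaussian_blur(img, style$blur)
    img <- clip01(img)^style$gamma
    img <- clip01(img + stats::rnorm(h * w, 0, style$noise))
    img[!outline & !wedge] <- pmax(img[!outline & !wedge] - 0.3, 0)  # keep background dark

    id <- sprintf("ph-%s-%03d-%s-%d", tolower(view),
                  round(target_density_percent), substr(domain_style, 1, 2),
                  as.integer(seed) %% 100000L)
    tibble::tibble(
      id = id,
      view = view,
      density_percent = target_density_percent,
      density_source = "phantom_truth",
      birads = as.character(map_libra(target_density_percent)),
      domain = domain_style,
      provenance = "real",
      pathology = if (nrow(lesions$boxes) > 0) "mass" else "normal",
      image = list(img),
      mask = list(mask),
      lesions = list(lesions$boxes)
    )
  })
}

# Insert n bright elliptical masses inside the mask without box overlap.
place_masses <- function(img, mask, n_masses, h, w) {
  boxes <- tibble::tibble(x = integer(0), y = integer(0), w = integer(0), h = integer(0))
  if (n_masses <= 0) return(list(image = img, boxes = boxes))
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_masses)) {
    placed <- FALSE
    for (attempt in seq_len(300)) {
      ry <- round(stats::runif(1, 0.028, 0.05) * h)
      rx <- round(stats::runif(1, 0.045, 0.08) * w)
      cym <- round(stats::runif(1, ry + 2, h - ry - 1))
      cxm <- round(stats::runif(1, rx + 2, w - rx - 1))
      bx <- cxm - rx - 1L; by <- cym - ry - 1L
      bw <- 2L * rx + 1L; bh <- 2L * ry + 1L
      inside <- mask[cym, cxm] &&
        all(mask[pmax(1, cym - ry):pmin(h, cym + ry), pmax(1, cxm - rx):pmin(w, cxm + rx)])
      if (!inside) next
      overlap <- nrow(boxes) > 0 && any(
        boxes$x < bx + bw & bx < boxes$x + boxes$w &
        boxes$y < by + bh & by < boxes$y + boxes$h
      )
      if (overlap) next
      d2 <- ((xx - cxm) / rx)^2 + ((yy - cym) / ry)^2
      img <- clip01(img + 0.32 * exp(-2 * d2))
      boxes <- dplyr::bind_rows(boxes, tibble::tibble(
        x = as.integer(bx), y = as.integer(by),
        w = as.integer(bw), h = as.integer(bh)
      ))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place requested number of masses without overlap", call. = FALSE)
    }
  }
  list(image = img, boxes = boxes)
}

#' Fixed intensity threshold separating fibroglandular from fatty tissue
#'
#' Phantom fat is rendered around 0.40 and dense tissue around 0.74, so 0.55
#' cleanly separates the two under every built-in domain style.
#' @return A scalar threshold in (0, 1).
#' @export
dense_threshold <- function() 0.55

#' Measure the fibroglandular density of an image
#'
#' Area percent density: 100 times the fraction of breast-mask pixels whose
#' intensity exceeds a fixed threshold. This is the phantom-world proxy for
#' the percentages that Volpara/LIBRA report on clinical images.
#'
#' @param image Numeric matrix in \[0,1\].
#' @param breast_mask Logical matrix of the same dimension; must be nonempty.
#' @param threshold Intensity cut point, default [dense_threshold()].
#' @return Percentage in \[0, 100\].
#' @export
measure_density <- function(image, breast_mask, threshold = dense_threshold()) {
  stopifnot_image(image)
  if (!is.logical(breast_mask) || !identical(dim(breast_mask), dim(image))) {
    stop("breast_mask must be a logical matrix matching the image", call. = FALSE)
  }
  n <- sum(breast_mask)
  if (n == 0) stop("breast mask is empty", call. = FALSE)
  100 * sum(image[breast_mask] > threshold) / n
}

#' Built-in vendor-style appearance domains
#'
#' Appearance domains emulate vendor differences (sharpness, tone curve,
#' noise floor): `"hologic-like"` is sharp and clean; `"siemens-like"` is
#' softer with a slightly compressive tone curve and more noise.
#' @return A character vector of style names.
#' @export
domain_styles <- function() c("hologic-like", "siemens-like")

lookup_style <- function(name) {
  switch(name,
    "hologic-like" = list(blur = 0, gamma = 1.00, noise = 0.010),
    "siemens-like" = list(blur = 0.9, gamma = 1.12, noise = 0.020),
    stop(sprintf("unknown domain style '%s'", name), call. = FALSE)
  )
}

#' Largest-remainder apportionment of n records to categories
#'
#' Floors `n * p` and hands remaining units to the categories with the
#' largest fractional remainders (ties to the earlier category), so counts
#' always sum exactly to `n`.
#' @param n Total count.
#' @param p Numeric vector of proportions summing to 1.
#' @return Integer vector of counts, same length and names as `p`.
#' @export
largest_remainder <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  }
  raw <- n * p
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Generate a phantom cohort manifest
#'
#' Draws `n` phantoms whose BI-RADS composition follows a given category
#' distribution via largest-remainder rounding, with per-record densities
#' uniform inside each category's LIBRA-style interval (category D capped at
#' 95% to avoid degenerate fully-dense images).
#'
#' Two presets mirror published compositions: `birads_distribution =
#' c(A = .09, B = .50, C = .36, D = .05)` reproduces a screening training-set
#' imbalance (9% A, 5% D), and `c(A = .36, B = .35, C = .22, D = .07)` the
#' composition reported for a small public FFDM collection.
#'
#' @param n Number of records (>= 1).
#' @param birads_distribution Named or ordered numeric vector of proportions
#'   over A--D summing to 1.
#' @param mass_prevalence Probability that a record carries one mass.
#' @param view_mix Probability that a record is a CC view (rest are MLO).
#' @param domain_style Style tag or vector of tags sampled uniformly.
#' @param size Image size `c(height, width)` passed to [generate_phantom()].
#' @param seed Integer seed.
#' @return A manifest tibble, one row per record, as in [generate_phantom()].
#' @examples
#' m <- generate_cohort(12, c(A = .25, B = .25, C = .25, D = .25),
#'                      size = c(64, 40), seed = 3)
#' table(m$birads)
#' @export
generate_cohort <- function(n, birads_distribution = c(A = 0.09, B = 0.50, C = 0.36, D = 0.05),
                            mass_prevalence = 0, view_mix = 0.5,
                            domain_style = "hologic-like", size = c(256, 160), seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(birads_distribution) != 4) {
    stop("birads_distribution must have four entries (A, B, C, D)", call. = FALSE)
  }
  counts <- largest_remainder(n, birads_distribution)
  cats <- rep(birads_levels, counts)
  iv <- density_interval(cats, source = "phantom_truth")
  with_seed(derive_seed(seed, "cohort"), {
    dens <- stats::runif(n, iv[, "lo"], iv[, "hi"])
    views <- ifelse(stats::runif(n) < view_mix, "CC", "MLO")
    styles <- if (length(domain_style) == 1) rep(domain_style, n) else
      sample(domain_style, n, replace = TRUE)
    has_mass <- stats::runif(n) < mass_prevalence
    rec_seeds <- sample.int(2147483000L, n)
  })
  recs <- purrr::pmap(
    list(views, dens, styles, as.integer(has_mass), rec_seeds, seq_len(n)),
    function(v, d, s, m, rs, i) {
      r <- generate_phantom(v, d, s, n_masses = m, size = size, seed = rs)
      r$id <- sprintf("rec-%04d", i)
      r
    }
  )
  dplyr::bind_rows(recs)
}

#' Mean-contrast of a lesion over its surrounding annulus
#'
#' Contrast is defined as mean intensity inside the lesion box minus the mean
#' over a surrounding annulus of `margin` pixels (clipped at image bounds).
#' Inserted phantom masses have positive contrast by construction, and a
#' trained translator is expected to preserve the sign.
#'
#' @param image Numeric matrix.
#' @param box One-row data frame or list with `x`, `y`, `w`, `h` (0-based).
#' @param margin Annulus width in pixels.
#' @return Scalar contrast (positive means brighter than surroundings).
#' @export
lesion_contrast <- function(image, box, margin = 4) {
  h <- nrow(image); w <- ncol(image)
  x0 <- box$x + 1L; y0 <- box$y + 1L
  x1 <- box$x + box$w; y1 <- box$y + box$h
  inner <- image[y0:y1, x0:x1]
  ox0 <- max(1L, x0 - margin); oy0 <- max(1L, y0 - margin)
  ox1 <- min(w, x1 + margin); oy1 <- min(h, y1 + margin)
  outer_box <- image[oy0:oy1, ox0:ox1]
  ann_sum <- sum(outer_box) - sum(inner)
  ann_n <- length(outer_box) - length(inner)
  if (ann_n == 0) return(NA_real_)
  mean(inner) - ann_sum / ann_n
}
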