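#' Intersection-over-union of two pixel boxes
#'
#' Boxes are 0-based half-open rectangles `[x, x+w) x [y, y+h)`, so two
#' boxes that merely touch have IoU 0.
#'
#' @param boxA,boxB Lists or one-row data frames with `x`, `y`, `w`, `h`;
#'   both extents must be positive.
#' @return IoU in \[0, 1\].
#' @examples
#' iou(list(x = 0, y = 0, w = 10, h = 10), list(x = 0, y = 0, w = 2, h = 10))
#' @export
iou <- function(boxA, boxB) {
  if (boxA$w <= 0 || boxA$h <= 0 || boxB$w <= 0 || boxB$h <= 0) {
    stop("boxes must have positive extents", call. = FALSE)
  }
  ix <- min(boxA$x + boxA$w, boxB$x + boxB$w) - max(boxA$x, boxB$x)
  iy <- min(boxA$y + boxA$h, boxB$y + boxB$h) - max(boxA$y, boxB$y)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (boxA$w * boxA$h + boxB$w * boxB$h - inter)
}

#' Match detections to ground-truth lesions
#'
#' Greedy one-to-one matching in descending score order: each detection is a
#' true positive iff it overlaps an unclaimed ground-truth box with IoU
#' strictly greater than the threshold (the free-response convention here
#' uses a permissive 10% overlap). Score ties are broken by box coordinates
#' lexicographically so results do not depend on input order.
#'
#' @param detections Tibble with `x`, `y`, `w`, `h`, `score`.
#' @param ground_truths Tibble with `x`, `y`, `w`, `h`.
#' @param iou_threshold Overlap strictly required for a TP (default 0.10).
#' @return A list with `detections` (input plus logical `tp` and `matched_gt`
#'   index, ordered by descending score) and `gt` (input plus logical `hit`
#'   and `matched_by` detection score).
#' @export
match_detections <- function(detections, ground_truths, iou_threshold = 0.10) {
  det <- tibble::as_tibble(detections)
  gt <- tibble::as_tibble(ground_truths)
  n_det <- nrow(det); n_gt <- nrow(gt)
  tp <- logical(n_det); matched_gt <- rep(NA_integer_, n_det)
  gt_hit <- logical(n_gt); gt_score <- rep(NA_real_, n_gt)
  if (n_det > 0) {
    ord <- order(-det$score, det$x, det$y, det$w, det$h)
    det <- det[ord, , drop = FALSE]
    claimed <- logical(n_gt)
    for (i in seq_len(n_det)) {
      best <- 0; best_j <- NA_integer_
      for (j in seq_len(n_gt)) {
        if (claimed[j]) next
        o <- iou(det[i, ], gt[j, ])
        if (o > best) { best <- o; best_j <- j }
      }
      if (!is.na(best_j) && best > iou_threshold) {
        tp[i] <- TRUE; matched_gt[i] <- best_j
        claimed[best_j] <- TRUE
        gt_hit[best_j] <- TRUE; gt_score[best_j] <- det$score[i]
      }
    }
  }
  det$tp <- tp
  det$matched_gt <- matched_gt
  gt$hit <- gt_hit
  gt$matched_by <- gt_score
  list(detections = det, gt = gt)
}

#' Free-response ROC curve and partial AUC over FPPI in (0,1)
#'
#' Detections across all images are matched once (greedy, descending score,
#' one-to-one per image), then the score threshold is swept over every
#' distinct detection score: at each threshold, sensitivity is the fraction
#' of all lesions hit by a retained TP detection and FPPI is the number of
#' retained false positives per image. The partial AUC is the trapezoidal
#' area of sensitivity over FPPI clipped to \[0,1\] — with linear
#' interpolation at FPPI = 1, and the last sensitivity carried to FPPI = 1
#' if the sweep ends earlier — reported as a percent of the unit box.
#'
#' @param per_image_detections List (one element per image) of detection
#'   tibbles (`x`, `y`, `w`, `h`, `score`).
#' @param per_image_ground_truths List of ground-truth box tibbles, same
#'   length and order.
#' @param iou_threshold Matching threshold passed to [match_detections()].
#' @return An object of class `froc_curve`: list with `points` (tibble
#'   `threshold`, `fppi`, `sensitivity`), `auc_percent`, `n_images`,
#'   `n_lesions`.
#' @export
froc_curve <- function(per_image_detections, per_image_ground_truths,
                       iou_threshold = 0.10) {
  stopifnot(length(per_image_detections) == length(per_image_ground_truths))
  n_img <- length(per_image_detections)
  n_lesions <- sum(purrr::map_int(per_image_ground_truths, nrow))
  if (n_lesions == 0) stop("FROC requires at least one ground-truth lesion", call. = FALSE)

  matched <- purrr::map2(per_image_detections, per_image_ground_truths,
                         match_detections, iou_threshold = iou_threshold)
  all_det <- purrr::map_dfr(matched, "detections")
  if (nrow(all_det) == 0) {
    pts <- tibble::tibble(threshold = numeric(0), fppi = numeric(0),
                          sensitivity = numeric(0))
    return(new_froc(pts, 0, n_img, n_lesions))
  }
  thresholds <- sort(unique(all_det$score), decreasing = TRUE)
  pts <- purrr::map_dfr(thresholds, function(th) {
    keep <- all_det$score >= th
    tibble::tibble(
      threshold = th,
      fppi = sum(keep & !all_det$tp) / n_img,
      sensitivity = sum(keep & all_det$tp) / n_lesions
    )
  })
  new_froc(pts, froc_partial_auc(pts$fppi, pts$sensitivity), n_img, n_lesions)
}

new_froc <- function(points, auc_percent, n_images, n_lesions) {
  structure(list(points = points, auc_percent = auc_percent,
                 n_images = n_images, n_lesions = n_lesions),
            class = "froc_curve")
}

# Trapezoidal partial area over fppi in [0,1]; curve starts at (0,0) and the
# final sensitivity is held flat to fppi = 1 when the sweep stops short.
froc_partial_auc <- function(fppi, sens) {
  xs <- c(0, fppi); ys <- c(0, sens)
  if (max(xs) < 1) { xs <- c(xs, 1); ys <- c(ys, ys[length(ys)]) }
  auc <- 0
  for (i in seq_len(length(xs) - 1)) {
    x0 <- xs[i]; x1 <- xs[i + 1]; y0 <- ys[i]; y1 <- ys[i + 1]
    if (x0 >= 1) break
    if (x1 > 1) {  # linear interpolation at the fppi = 1 boundary
      y1 <- y0 + (y1 - y0) * (1 - x0) / (x1 - x0)
      x1 <- 1
    }
    auc <- auc + (x1 - x0) * (y0 + y1) / 2
  }
  100 * auc
}

#' @export
print.froc_curve <- function(x, ...) {
  cat(sprintf("<froc_curve> %d images, %d lesions, %d thresholds\n",
              x$n_images, x$n_lesions, nrow(x$points)))
  cat(sprintf("  partial AUC over FPPI in (0,1): %.2f%%\n", x$auc_percent))
  invisible(x)
}

#' @method tidy froc_curve
#' @export
tidy.froc_curve <- function(x, ...) x$points

#' @method glance froc_curve
#' @export
glance.froc_curve <- function(x, ...) {
  tibble::tibble(auc_percent = x$auc_percent, n_images = x$n_images,
                 n_lesions = x$n_lesions, n_thresholds = nrow(x$points))
}

#' Case-level scores for the paired ROC comparison
#'
#' Reduces free-response output to a case-level ROC problem: one positive
#' score per ground-truth lesion (the score of its matched detection, 0 when
#' missed) and one negative score per retained false positive, keeping at
#' most `fppi_cap` of the highest-scoring false positives per image.
#'
#' @inheritParams froc_curve
#' @param fppi_cap Maximum false positives retained per image (default 10).
#' @return A list with numeric vectors `positives` and `negatives`.
#' @export
build_case_scores <- function(per_image_detections, per_image_ground_truths,
                              fppi_cap = 10, iou_threshold = 0.10) {
  stopifnot(length(per_image_detections) == length(per_image_ground_truths))
  matched <- purrr::map2(per_image_detections, per_image_ground_truths,
                         match_detections, iou_threshold = iou_threshold)
  positives <- unlist(purrr::map(matched, function(m) {
    s <- m$gt$matched_by
    s[is.na(s)] <- 0
    s
  }))
  negatives <- unlist(purrr::map(matched, function(m) {
    fp <- m$detections$score[!m$detections$tp]
    utils::head(sort(fp, decreasing = TRUE), fppi_cap)
  }))
  list(positives = as.numeric(positives %||% numeric(0)),
       negatives = as.numeric(negatives %||% numeric(0)))
}

# Midrank-based ROC AUC and DeLong structural components.
midrank_placements <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n          # per-positive placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m  # per-negative placements
  list(auc = sum(v10) / m, v10 = v10, v01 = v01)
}

#' Paired DeLong comparison of two case-score sets
#'
#' Computes both ROC AUCs via midrank placement values, the DeLong
#' variance/covariance of the paired AUC difference from the structural
#' components, and a two-sided normal p-value. The two score sets must be
#' paired: built from the same lesions and images in the same order.
#'
#' @param case_scores_A,case_scores_B Lists with `positives` and `negatives`
#'   as returned by [build_case_scores()], of equal lengths pairwise.
#' @return An object of class `delong_comparison`: list with `auc_A`,
#'   `auc_B`, `delta`, `variance`, `z`, `p_value`, `n_pos`, `n_neg`.
#' @examples
#' a <- list(positives = c(.9, .8, .7, .4), negatives = c(.3, .2, .5, .1))
#' delong_compare(a, a)$p_value  # identical inputs: 1
#' @export
delong_compare <- function(case_scores_A, case_scores_B) {
  pa <- case_scores_A$positives; na <- case_scores_A$negatives
  pb <- case_scores_B$positives; nb <- case_scores_B$negatives
  if (length(pa) != length(pb) || length(na) != length(nb)) {
    stop("score sets are not paired (unequal positive or negative counts)", call. = FALSE)
  }
  m <- length(pa); n <- length(na)
  if (m < 2 || n < 2) {
    stop("need at least 2 positives and 2 negatives", call. = FALSE)
  }
  A <- midrank_placements(pa, na)
  B <- midrank_placements(pb, nb)
  s10 <- stats::cov(cbind(A$v10, B$v10))  # covariance across positives
  s01 <- stats::cov(cbind(A$v01, B$v01))  # covariance across negatives
  S <- s10 / m + s01 / n                  # covariance matrix of (auc_A, auc_B)
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- A$auc - B$auc
  if (var_delta <= 0 || delta == 0) {
    z <- 0; p <- 1
    if (delta != 0 && var_delta <= 0) { z <- Inf * sign(delta); p <- 0 }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_A = A$auc, auc_B = B$auc, delta = delta,
                 variance = var_delta, z = z, p_value = p,
                 n_pos = m, n_neg = n),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("<delong_comparison> AUC A %.4f vs AUC B %.4f (delta %+.4f)\n",
              x$auc_A, x$auc_B, x$delta))
  cat(sprintf("  z = %.3f, two-sided p = %.4g (%d positives, %d negatives)\n",
              x$z, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy delong_comparison
#' @export
tidy.delong_comparison <- function(x, ...) {
  tibble::tibble(auc_A = x$auc_A, auc_B = x$auc_B, delta = x$delta,
                 variance = x$variance, z = x$z, p_value = x$p_value)
}

#' @method glance delong_comparison
#' @export
glance.delong_comparison <- function(x, ...) tidy.delong_comparison(x)

#' Built-in difference-of-Gaussians blob detector
#'
#' A deliberately simple, fully deterministic stand-in for a learned
#' detector so the pipeline runs end to end: candidate blobs are connected
#' components of the thresholded difference of two Gaussian smoothings,
#' filtered by area and border contact, and scored by normalised blob
#' contrast (mean band-pass response weighted by blob extent).
#'
#' @param image Numeric matrix in \[0,1\].
#' @param sigma_small,sigma_large Gaussian scales of the band-pass, chosen
#'   near the expected mass radius so that finer fibroglandular speckle is
#'   suppressed.
#' @param dog_threshold Threshold on the DoG response.
#' @param min_area Minimum blob area in pixels.
#' @param max_area_frac Blobs covering more than this fraction of the image
#'   are rejected (anatomy-scale structures such as the pectoral wedge).
#' @param max_detections Keep at most this many highest-scoring blobs.
#' @return A detection tibble with `x`, `y`, `w`, `h`, `score` (possibly
#'   empty), scores in \[0,1\].
#' @export
baseline_detector <- function(image, sigma_small = 2.5, sigma_large = 8,
                              dog_threshold = 0.02, min_area = 12,
                              max_area_frac = 0.03, max_detections = 25) {
  stopifnot_image(image)
  dog <- gaussian_blur(image, sigma_small) - gaussian_blur(image, sigma_large)
  cand <- dog > dog_threshold
  empty <- tibble::tibble(x = integer(0), y = integer(0), w = integer(0),
                          h = integer(0), score = numeric(0))
  if (!any(cand)) return(empty)
  labels <- label_components(cand)
  n_lab <- max(labels)
  if (n_lab == 0) return(empty)
  h_img <- nrow(image); w_img <- ncol(image)
  out <- purrr::map_dfr(seq_len(n_lab), function(l) {
    px <- which(labels == l, arr.ind = TRUE)
    if (nrow(px) < min_area) return(NULL)
    if (nrow(px) > max_area_frac * h_img * w_img) return(NULL)
    # border-touching blobs are breast-outline or pectoral edges, not masses
    if (any(px[, 1] %in% c(1L, h_img)) || any(px[, 2] %in% c(1L, w_img))) {
      return(NULL)
    }
    y0 <- min(px[, 1]); y1 <- max(px[, 1])
    x0 <- min(px[, 2]); x1 <- max(px[, 2])
    box <- list(x = x0 - 1L, y = y0 - 1L, w = x1 - x0 + 1L, h = y1 - y0 + 1L)
    # masses are broad coherent bumps; small fibroglandular islands have
    # similar peak contrast but far smaller extent, so the score combines
    # the blob's mean band-pass response with its area
    resp <- mean(dog[labels == l])
    tibble::tibble(x = as.integer(box$x), y = as.integer(box$y),
                   w = as.integer(box$w), h = as.integer(box$h),
                   score = clip01(resp * sqrt(nrow(px)) / 1.5))
  })
  if (nrow(out) == 0) return(empty)
  out <- out[order(-out$score, out$x, out$y), , drop = FALSE]
  utils::head(out, max_detections)
}

# Connected-component labelling (8-connectivity); uses EBImage when
# available, otherwise a queue-based flood fill.
label_components <- function(mask) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask)))
  }
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  lab <- 0L
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (start in which(mask & labels == 0L)) {
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      cy <- (cur - 1L) %% h + 1L; cx <- (cur - 1L) %/% h + 1L
      for (o in seq_len(nrow(offs))) {
        ny <- cy + offs$dy[o]; nx <- cx + offs$dx[o]
        if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
            mask[ny, nx] && labels[ny, nx] == 0L) {
          labels[ny, nx] <- lab
          queue <- c(queue, (nx - 1L) * h + ny)
        }
      }
    }
  }
  labels
}

#' Density-stratified FROC report
#'
#' Runs [froc_curve()] within each BI-RADS stratum of a result set and
#' reports per-category partial AUC and sensitivity at a reference FPPI,
#' plus the fairness gap (max minus min sensitivity across categories).
#'
#' @param per_image_detections,per_image_ground_truths As in [froc_curve()],
#'   aligned with `manifest` rows.
#' @param manifest Manifest tibble labelling each image (`birads` column).
#' @param at_fppi Reference FPPI at which stratum sensitivity is read off.
#' @param iou_threshold Matching threshold.
#' @return A list with `by_category` (tibble: `birads`, `n_images`,
#'   `n_lesions`, `auc_percent`, `sensitivity_at_fppi`) and `fairness_gap`.
#' @export
stratified_report <- function(per_image_detections, per_image_ground_truths,
                              manifest, at_fppi = 0.5, iou_threshold = 0.10) {
  stopifnot(nrow(manifest) == length(per_image_detections))
  cats <- sort(unique(as.character(manifest$birads)))
  rows <- purrr::map_dfr(cats, function(cat) {
    idx <- which(manifest$birads == cat)
    n_les <- sum(purrr::map_int(per_image_ground_truths[idx], nrow))
    if (n_les == 0) {
      return(tibble::tibble(birads = cat, n_images = length(idx), n_lesions = 0L,
                            auc_percent = NA_real_, sensitivity_at_fppi = NA_real_))
    }
    fr <- froc_curve(per_image_detections[idx], per_image_ground_truths[idx],
                     iou_threshold = iou_threshold)
    tibble::tibble(
      birads = cat, n_images = length(idx), n_lesions = fr$n_lesions,
      auc_percent = fr$auc_percent,
      sensitivity_at_fppi = sensitivity_at(fr, at_fppi)
    )
  })
  sens <- rows$sensitivity_at_fppi[!is.na(rows$sensitivity_at_fppi)]
  gap <- if (length(sens) > 0) max(sens) - min(sens) else NA_real_
  list(by_category = rows, fairness_gap = gap, at_fppi = at_fppi)
}

# Sensitivity of a FROC curve at a given FPPI (step interpolation: the
# highest sensitivity attained at FPPI <= the target).
sensitivity_at <- function(froc, fppi) {
  pts <- froc$points
  ok <- pts$fppi <= fppi
  if (!any(ok)) return(0)
  max(pts$sensitivity[ok])
}
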