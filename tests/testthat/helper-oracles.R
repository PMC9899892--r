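# Independent oracles and fixture builders used across the suite.
# Every oracle recomputes its quantity by a different route than the
# package (pixel-set enumeration, exhaustive pair counting, naive O(n^2)
# statistics) so agreement is informative.

# IoU by literal pixel-set enumeration on half-open integer boxes.
oracle_iou <- function(a, b) {
  cells <- function(bx) {
    as.vector(outer((bx$x):(bx$x + bx$w - 1), (bx$y):(bx$y + bx$h - 1),
                    function(x, y) paste(x, y)))
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# Greedy descending-score one-to-one matcher, written independently with
# pixel-set IoU; returns logical TP flags aligned with score-desc order.
oracle_match <- function(det, gt, thr = 0.10) {
  if (nrow(det) == 0) return(logical(0))
  det <- det[order(-det$score, det$x, det$y, det$w, det$h), , drop = FALSE]
  used <- rep(FALSE, nrow(gt))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ious <- if (nrow(gt) == 0) numeric(0) else
      sapply(seq_len(nrow(gt)), function(j) oracle_iou(det[i, ], gt[j, ]))
    ious[used] <- -1
    if (length(ious) > 0 && max(ious) > thr) {
      j <- which.max(ious)
      tp[i] <- TRUE
      used[j] <- TRUE
    }
  }
  tp
}

# FROC partial AUC by exhaustive threshold enumeration with independent
# re-matching at every threshold, integrated segment by segment.
oracle_froc_auc <- function(per_det, per_gt) {
  n_img <- length(per_det)
  n_les <- sum(vapply(per_gt, nrow, 1L))
  scores <- sort(unique(unlist(lapply(per_det, function(d) d$score))),
                 decreasing = TRUE)
  pts_x <- 0; pts_y <- 0
  for (th in scores) {
    tp <- 0; fp <- 0
    for (k in seq_len(n_img)) {
      d <- per_det[[k]]
      d <- d[d$score >= th, , drop = FALSE]
      flags <- oracle_match(d, per_gt[[k]])
      tp <- tp + sum(flags); fp <- fp + sum(!flags)
    }
    pts_x <- c(pts_x, fp / n_img)
    pts_y <- c(pts_y, tp / n_les)
  }
  if (max(pts_x) < 1) { pts_x <- c(pts_x, 1); pts_y <- c(pts_y, pts_y[length(pts_y)]) }
  auc <- 0
  for (i in seq_len(length(pts_x) - 1)) {
    x0 <- pts_x[i]; x1 <- pts_x[i + 1]; y0 <- pts_y[i]; y1 <- pts_y[i + 1]
    a <- max(x0, 0); b <- min(x1, 1)
    if (b <= a) next
    ya <- if (x1 == x0) y0 else y0 + (y1 - y0) * (a - x0) / (x1 - x0)
    yb <- if (x1 == x0) y1 else y0 + (y1 - y0) * (b - x0) / (x1 - x0)
    auc <- auc + (b - a) * (ya + yb) / 2
  }
  100 * auc
}

# Empirical ROC AUC by exhaustive concordant/discordant pair counting with
# half credit for ties.
oracle_pair_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Naive O(n^2) DeLong structural components for a paired comparison.
oracle_delong <- function(pa, na_, pb, nb) {
  psi <- function(x, y) outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  PA <- psi(pa, na_); PB <- psi(pb, nb)
  aucA <- mean(PA); aucB <- mean(PB)
  v10A <- rowMeans(PA); v10B <- rowMeans(PB)
  v01A <- colMeans(PA); v01B <- colMeans(PB)
  m <- length(pa); n <- length(na_)
  cv <- function(u, v) sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
  var_delta <- (cv(v10A, v10A) + cv(v10B, v10B) - 2 * cv(v10A, v10B)) / m +
    (cv(v01A, v01A) + cv(v01B, v01B) - 2 * cv(v01A, v01B)) / n
  list(aucA = aucA, aucB = aucB, var = var_delta)
}

# Random detection/ground-truth instance on a small pixel grid.
random_instance <- function(n_images = 8, max_boxes = 4, grid = 32, seed = 1) {
  set.seed(seed)
  rand_boxes <- function(n) {
    if (n == 0) {
      return(tibble::tibble(x = integer(0), y = integer(0),
                            w = integer(0), h = integer(0)))
    }
    tibble::tibble(
      x = sample(0:(grid - 10), n, replace = TRUE),
      y = sample(0:(grid - 10), n, replace = TRUE),
      w = sample(3:9, n, replace = TRUE),
      h = sample(3:9, n, replace = TRUE)
    )
  }
  per_gt <- lapply(seq_len(n_images), function(i) rand_boxes(sample(0:2, 1)))
  if (sum(vapply(per_gt, nrow, 1L)) == 0) per_gt[[1]] <- rand_boxes(1)
  per_det <- lapply(seq_len(n_images), function(i) {
    nb <- sample(0:max_boxes, 1)
    b <- rand_boxes(nb)
    b$score <- round(stats::runif(nb), 2)  # rounded: force score ties
    b
  })
  list(det = per_det, gt = per_gt)
}

# Tiny healthy phantom manifest helper.
tiny_cohort <- function(n, dens_range, seed0, size = c(64, 64), n_masses = 0,
                        style = "hologic-like") {
  set.seed(seed0)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    generate_phantom(sample(c("CC", "MLO"), 1),
                     stats::runif(1, dens_range[1], dens_range[2]),
                     style, n_masses, size, seed0 + i)
  }))
}

# Implementation-side midrank AUC accessor (compared against oracle_pair_auc).
midrank_auc_for_test <- function(pos, neg) {
  densaug:::midrank_placements(pos, neg)$auc
}
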