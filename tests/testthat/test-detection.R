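box <- function(x, y, w, h) list(x = x, y = y, w = w, h = h)

test_that("IoU matches pixel-set enumeration and handles edge cases", {
  expect_equal(iou(box(0, 0, 10, 10), box(0, 0, 10, 10)), 1)
  expect_equal(iou(box(0, 0, 5, 5), box(10, 10, 5, 5)), 0)
  expect_equal(iou(box(0, 0, 5, 5), box(5, 0, 5, 5)), 0)  # touching, half-open
  expect_equal(iou(box(0, 0, 10, 10), box(0, 0, 2, 10)), 0.2)
  expect_error(iou(box(0, 0, 0, 5), box(0, 0, 5, 5)), "positive")
  set.seed(42)
  for (i in 1:25) {
    a <- box(sample(0:20, 1), sample(0:20, 1), sample(1:8, 1), sample(1:8, 1))
    b <- box(sample(0:20, 1), sample(0:20, 1), sample(1:8, 1), sample(1:8, 1))
    expect_equal(iou(a, b), oracle_iou(a, b), tolerance = 1e-12)
  }
})

test_that("TP rule requires IoU strictly above 10% and one detection per lesion", {
  gt <- tibble::tibble(x = 0, y = 0, w = 10, h = 10)
  hit <- tibble::tibble(x = 0, y = 0, w = 10, h = 10, score = 0.9)  # IoU 1
  part <- tibble::tibble(x = 8, y = 0, w = 10, h = 10, score = 0.9) # IoU 2/18
  miss <- tibble::tibble(x = 9, y = 9, w = 10, h = 10, score = 0.9) # IoU 1/199
  expect_true(match_detections(hit, gt)$detections$tp)
  expect_true(match_detections(part, gt)$detections$tp)
  m <- match_detections(miss, gt)
  expect_false(m$detections$tp)
  expect_false(m$gt$hit)
  # exactly-at-threshold overlap is not a TP ("greater than" is strict)
  at <- tibble::tibble(x = 0, y = 0, w = 10, h = 2, score = 0.5)    # IoU 0.2
  expect_false(match_detections(at, gt, iou_threshold = 0.2)$detections$tp)
  # two detections on one lesion: the higher score claims it
  two <- tibble::tibble(x = c(0, 1), y = c(0, 0), w = 10, h = 10,
                        score = c(0.8, 0.9))
  m2 <- match_detections(two, gt)
  expect_equal(m2$detections$tp[order(-m2$detections$score)], c(TRUE, FALSE))
})

test_that("matching is invariant to detection input order", {
  set.seed(7)
  gt <- tibble::tibble(x = c(0, 15), y = c(0, 15), w = 8, h = 8)
  det <- tibble::tibble(x = sample(0:20, 6, TRUE), y = sample(0:20, 6, TRUE),
                        w = 6, h = 6, score = c(.9, .9, .7, .5, .5, .3))
  ref <- match_detections(det, gt)$detections
  for (i in 1:5) {
    perm <- det[sample(nrow(det)), ]
    out <- match_detections(perm, gt)$detections
    expect_identical(out[order(-out$score, out$x, out$y), ],
                     ref[order(-ref$score, ref$x, ref$y), ])
  }
})

test_that("FROC endpoints: perfect detector scores 100%, silent detector 0%", {
  gt <- replicate(4, tibble::tibble(x = 5, y = 5, w = 6, h = 6), simplify = FALSE)
  perfect <- replicate(4, tibble::tibble(x = 5, y = 5, w = 6, h = 6, score = 1),
                       simplify = FALSE)
  silent <- replicate(4, tibble::tibble(x = integer(0), y = integer(0),
                                        w = integer(0), h = integer(0),
                                        score = numeric(0)), simplify = FALSE)
  expect_equal(froc_curve(perfect, gt)$auc_percent, 100)
  expect_equal(froc_curve(silent, gt)$auc_percent, 0)
  expect_error(froc_curve(silent, replicate(4, silent[[1]][, 1:4], simplify = FALSE)),
               "lesion")
})

test_that("FROC partial AUC equals the exhaustive threshold-enumeration oracle", {
  for (s in 1:100) {
    inst <- random_instance(n_images = 8, max_boxes = 4, seed = s)
    got <- froc_curve(inst$det, inst$gt)$auc_percent
    want <- oracle_froc_auc(inst$det, inst$gt)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("FROC curves are monotone and invariant to monotone score maps", {
  for (s in 1:20) {
    inst <- random_instance(seed = 200 + s)
    fr <- froc_curve(inst$det, inst$gt)
    pts <- fr$points[order(fr$points$fppi), ]
    expect_true(all(diff(pts$sensitivity) >= -1e-12))
    warped <- lapply(inst$det, function(d) {
      d$score <- stats::plogis(3 * d$score - 1)  # strictly increasing map
      d
    })
    fr2 <- froc_curve(warped, inst$gt)
    expect_equal(fr2$auc_percent, fr$auc_percent, tolerance = 1e-9)
    expect_equal(fr2$points$fppi, fr$points$fppi)
    expect_equal(fr2$points$sensitivity, fr$points$sensitivity)
  }
})

test_that("case-score construction caps false positives at 10 per image", {
  gt <- list(tibble::tibble(x = 2, y = 2, w = 6, h = 6))
  det <- list(tibble::tibble(x = c(2, 20 + 2 * (1:14)), y = 2, w = 4, h = 4,
                             score = c(0.95, stats::runif(14, 0.1, 0.9))))
  cs <- build_case_scores(det, gt, fppi_cap = 10)
  expect_length(cs$negatives, 10)
  expect_equal(cs$negatives, sort(det[[1]]$score[-1], decreasing = TRUE)[1:10])
  expect_equal(cs$positives, 0.95)
  # missed lesions contribute a zero-score positive
  cs2 <- build_case_scores(list(det[[1]][-1, ]), gt, fppi_cap = 10)
  expect_equal(cs2$positives, 0)
})

test_that("case-level ROC AUC equals the exhaustive U-statistic oracle", {
  for (s in 1:25) {
    inst <- random_instance(n_images = 6, max_boxes = 4, seed = 400 + s)
    cs <- build_case_scores(inst$det, inst$gt)
    if (length(cs$positives) < 2 || length(cs$negatives) < 2) next
    got <- midrank_auc_for_test(cs$positives, cs$negatives)
    expect_equal(got, oracle_pair_auc(cs$positives, cs$negatives), tolerance = 1e-12)
  }
})

test_that("paired DeLong matches the naive structural-component oracle", {
  expect_error(delong_compare(list(positives = 1, negatives = c(.1, .2)),
                              list(positives = 1, negatives = c(.1, .2))),
               "at least 2")
  for (s in 1:100) {
    set.seed(1000 + s)
    m <- 12; n <- 12
    pa <- round(stats::runif(m), 2); na_ <- round(stats::runif(n), 2)
    pb <- pmin(1, pmax(0, pa + stats::rnorm(m, 0, 0.2)))
    nb <- pmin(1, pmax(0, na_ + stats::rnorm(n, 0, 0.2)))
    got <- delong_compare(list(positives = pa, negatives = na_),
                          list(positives = pb, negatives = nb))
    want <- oracle_delong(pa, na_, pb, nb)
    expect_equal(got$auc_A, want$aucA, tolerance = 1e-12)
    expect_equal(got$auc_B, want$aucB, tolerance = 1e-12)
    expect_equal(got$variance, want$var, tolerance = 1e-12)
  }
})

test_that("identical paired score sets give zero difference and p = 1", {
  a <- list(positives = c(.9, .8, .6, .4), negatives = c(.5, .3, .2, .1))
  d <- delong_compare(a, a)
  expect_equal(d$delta, 0)
  expect_equal(d$p_value, 1)
  b <- list(positives = c(.9, .8), negatives = c(.1, .2))
  expect_equal(delong_compare(b, b)$auc_A, 1)
})

test_that("blob detector finds phantom masses, is silent on blanks, deterministic", {
  expect_equal(nrow(baseline_detector(matrix(0, 64, 64))), 0)
  r <- generate_phantom("CC", 15, "hologic-like", 1, c(128, 80), seed = 31)
  det <- baseline_detector(r$image[[1]])
  expect_gt(nrow(det), 0)
  gt <- r$lesions[[1]]
  best <- max(vapply(seq_len(nrow(det)),
                     function(i) iou(det[i, ], gt[1, ]), 0))
  expect_gt(best, 0.1)
  expect_identical(det, baseline_detector(r$image[[1]]))
})

test_that("stratified report agrees with per-stratum recomputation", {
  set.seed(5)
  manifest <- tibble::tibble(birads = rep(c("A", "D"), each = 5))
  inst <- random_instance(n_images = 10, max_boxes = 3, seed = 77)
  rep_out <- stratified_report(inst$det, inst$gt, manifest)
  for (cat in c("A", "D")) {
    idx <- which(manifest$birads == cat)
    n_les <- sum(vapply(inst$gt[idx], nrow, 1L))
    row <- rep_out$by_category[rep_out$by_category$birads == cat, ]
    if (n_les == 0) {
      expect_true(is.na(row$auc_percent))
    } else {
      expect_equal(row$auc_percent,
                   froc_curve(inst$det[idx], inst$gt[idx])$auc_percent)
    }
  }
})

test_that("hand-built perfect and empty strata give sensitivities 1 and 0, gap 1", {
  manifest <- tibble::tibble(birads = c("A", "A", "D", "D"))
  gt <- replicate(4, tibble::tibble(x = 5, y = 5, w = 6, h = 6), simplify = FALSE)
  det <- list(
    tibble::tibble(x = 5, y = 5, w = 6, h = 6, score = 1),
    tibble::tibble(x = 5, y = 5, w = 6, h = 6, score = 1),
    tibble::tibble(x = integer(0), y = integer(0), w = integer(0),
                   h = integer(0), score = numeric(0)),
    tibble::tibble(x = integer(0), y = integer(0), w = integer(0),
                   h = integer(0), score = numeric(0))
  )
  out <- stratified_report(det, gt, manifest, at_fppi = 0.5)
  s <- out$by_category$sensitivity_at_fppi
  expect_equal(sort(s), c(0, 1))
  expect_equal(out$fairness_gap, 1)
  one <- stratified_report(det[1:2], gt[1:2], manifest[1:2, ], at_fppi = 0.5)
  expect_equal(one$fairness_gap, 0)
})
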