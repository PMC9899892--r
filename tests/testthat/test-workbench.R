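test_that("breast crop recovers known foreground bounds", {
  img <- matrix(0, 100, 60)
  img[21:80, 6:45] <- 0.5  # known breast block
  out <- preprocess_mammogram(img, target_size = c(100, 60))
  expect_equal(out$crop, c(21, 80, 6, 45))
  # aspect preserved: scale applied equally to both axes
  expect_equal(out$scale, min(100 / 60, 60 / 40))
  expect_error(preprocess_mammogram(matrix(0, 50, 50)), "foreground")
})

test_that("image already at target size and fully foreground is unchanged", {
  set.seed(3)
  img <- matrix(runif(64 * 40, 0.2, 1), 64, 40)
  out <- preprocess_mammogram(img, target_size = c(64, 40))
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_equal(out$scale, 1)
})

test_that("small bright specks are ignored when locating the breast", {
  img <- matrix(0, 100, 60)
  img[40:90, 5:40] <- 0.5
  img[2, 55] <- 1  # isolated speck far from the breast
  out <- preprocess_mammogram(img, target_size = c(100, 60), min_component = 10)
  expect_equal(out$crop, c(40, 90, 5, 40))
})

test_that("lesion boxes ride through the crop-resize affine", {
  img <- matrix(0, 100, 60)
  img[11:90, 1:50] <- 0.5
  boxes <- tibble::tibble(x = 10L, y = 20L, w = 10L, h = 10L)
  out <- preprocess_mammogram(img, target_size = c(160, 100), boxes = boxes)
  s <- out$scale
  expect_equal(out$boxes$x, round((10 - 0) * s))
  expect_equal(out$boxes$y, round((20 - 10) * s))
  expect_equal(out$boxes$w, round(10 * s))
})

test_that("aspect ratio is preserved within rounding for random inputs", {
  set.seed(11)
  for (i in 1:5) {
    h <- sample(40:120, 1); w <- sample(30:90, 1)
    img <- matrix(0, h, w)
    y0 <- sample(1:10, 1); x0 <- sample(1:8, 1)
    img[y0:(y0 + sample(20:(h - 15), 1)), x0:(x0 + sample(15:(w - 10), 1))] <- 0.6
    out <- preprocess_mammogram(img, target_size = c(128, 80))
    ch <- diff(out$crop[1:2]) + 1; cw <- diff(out$crop[3:4]) + 1
    fg <- which(out$image > 0, arr.ind = TRUE)
    nh <- max(fg[, 1]); nw <- max(fg[, 2])
    expect_lt(abs(nh / nw - ch / cw) * min(nh, nw), 1.5)
  }
})

test_that("experiment bundle has per-seed and aggregated arms and reproduces", {
  cfg <- experiment_config(
    n = 24, birads_distribution = c(A = .3, B = .2, C = .2, D = .3),
    mass_prevalence = 0.7, size = c(64, 40), test_per_category = 2,
    strategies = list(augmentation_strategy("baseline"),
                      augmentation_strategy("single", "fam1")),
    translator = desk_translator_config(iterations = 6, image_size = c(32, 32)),
    n_families = 1, n_repeats = 2, seed = 42
  )
  res <- run_experiment(cfg)
  expect_s3_class(res, "experiment_results")
  expect_equal(nrow(res$per_seed), 4)  # 2 strategies x 2 seeds
  expect_equal(sort(unique(res$per_seed$strategy)),
               c("baseline", "single-1to1-fam1"))
  expect_equal(nrow(res$aggregate), 2)
  expect_true(all(is.finite(res$per_seed$auc_percent)))
  # count law through the whole pipeline
  base_rows <- res$per_seed[res$per_seed$strategy == "baseline", ]
  aug_rows <- res$per_seed[res$per_seed$strategy != "baseline", ]
  expect_equal(base_rows$n_augmented, base_rows$n_train)
  expect_equal(aug_rows$n_augmented, 2 * aug_rows$n_train)
  expect_false(is.null(res$delong))
  expect_equal(nrow(res$delong), 2)  # one comparison per seed
  # at this miniature size the case-score sets can be too small for a
  # variance estimate; p-values are then recorded as NA
  expect_true(all(is.na(res$delong$p_value) |
                    (res$delong$p_value >= 0 & res$delong$p_value <= 1)))
  res2 <- run_experiment(cfg)
  expect_equal(res$per_seed, res2$per_seed)
  expect_equal(res$config_hash, res2$config_hash)
})

test_that("manifest round-trips through PNG + CSV + COCO JSON", {
  skip_if_not_installed("png")
  m <- generate_cohort(4, c(A = .5, B = 0, C = 0, D = .5), mass_prevalence = 1,
                       size = c(64, 40), seed = 8)
  d <- withr::local_tempdir()
  write_cohort(m, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(file.exists(file.path(d, "lesions.json")))
  back <- read_cohort(d)
  expect_equal(back$id, m$id)
  expect_equal(back$birads, m$birads)
  for (i in 1:4) {
    expect_lt(max(abs(back$image[[i]] - m$image[[i]])), 1 / 254)  # 8-bit depth
    expect_equal(as.data.frame(back$lesions[[i]]), as.data.frame(m$lesions[[i]]))
  }
  dets <- tibble::tibble(image_id = m$id[1], x = 1L, y = 2L, w = 3L, h = 4L,
                         score = 0.5)
  f <- file.path(d, "dets.json")
  write_detections(dets, f)
  j <- jsonlite::read_json(f)
  expect_equal(j[[1]]$bbox, list(1, 2, 3, 4))
})

test_that("autoplot methods return ggplot objects", {
  inst <- random_instance(seed = 5)
  fr <- froc_curve(inst$det, inst$gt)
  expect_s3_class(ggplot2::autoplot(fr), "ggplot")
  rec <- generate_phantom("MLO", 60, n_masses = 1, size = c(64, 40), seed = 2)
  expect_s3_class(plot_phantom(rec), "ggplot")
})
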