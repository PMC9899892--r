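make_pool <- function(per_cell = 20, sources = c("OP", "CS", "BC")) {
  tidyr::expand_grid(source = sources, truth = c("original", "synthetic"),
                     view = c("CC", "MLO"), k = seq_len(per_cell)) |>
    dplyr::mutate(id = sprintf("%s-%s-%s-%02d", source, truth, view, k)) |>
    dplyr::select(-"k")
}

test_that("study assembly yields the balanced 180/90/30 design", {
  pool <- make_pool()
  st <- assemble_study(pool, per_source = 30, seed = 4)
  expect_equal(nrow(st$study), 180)
  expect_equal(sum(st$key$truth == "original"), 90)
  expect_equal(sum(st$key$truth == "synthetic"), 90)
  counts <- table(st$key$source, st$key$truth)
  expect_true(all(counts == 30))
  views <- table(st$key$source, st$key$truth, st$key$view)
  expect_true(all(views == 15))
  # truth never leaks into the presentation manifest
  expect_named(st$study, c("position", "image_id"))
  st2 <- assemble_study(pool, per_source = 30, seed = 4)
  expect_identical(st, st2)
})

test_that("assembly scales down and enforces feasibility", {
  pool <- make_pool(per_cell = 2, sources = "OP")
  st <- assemble_study(pool, per_source = 2, seed = 1)
  expect_equal(nrow(st$study), 4)
  expect_equal(sum(st$key$truth == "original"), 2)
  expect_error(assemble_study(pool, per_source = 3, seed = 1), "even")
  expect_error(assemble_study(pool, per_source = 10, seed = 1), "supplies")
})

test_that("choice-to-probability is the printed equally spaced tuple", {
  expect_equal(choice_to_probability(1:6),
               c(0.95, 0.77, 0.59, 0.41, 0.23, 0.05))
  expect_error(choice_to_probability(0), "1..6")
  expect_error(choice_to_probability(7), "1..6")
  # strictly decreasing and symmetric about 0.5
  p <- choice_to_probability(1:6)
  expect_true(all(diff(p) < 0))
  expect_equal(p + rev(p), rep(1, 6))
})

test_that("reader AUC: perfect, constant and flipped readers", {
  key <- tibble::tibble(truth = rep(c("synthetic", "original"), each = 10))
  perfect <- tibble::tibble(choice = ifelse(key$truth == "synthetic", 1L, 6L),
                            truth = key$truth)
  expect_equal(reader_roc_auc(perfect), 1)
  constant <- tibble::tibble(choice = 3L, truth = key$truth)
  expect_equal(reader_roc_auc(constant), 0.5)
  expect_error(reader_roc_auc(tibble::tibble(choice = 1L, truth = "synthetic")),
               "both truth classes")
})

test_that("reader AUC equals pair counting and flips under scale reversal", {
  for (s in 1:10) {
    set.seed(s)
    resp <- tibble::tibble(
      choice = sample(1:6, 40, replace = TRUE),
      truth = sample(c("synthetic", "original"), 40, replace = TRUE,
                     prob = c(.5, .5))
    )
    if (length(unique(resp$truth)) < 2) next
    p <- choice_to_probability(resp$choice)
    want <- oracle_pair_auc(p[resp$truth == "synthetic"],
                            p[resp$truth == "original"])
    expect_equal(reader_roc_auc(resp), want, tolerance = 1e-12)
    flipped <- resp
    flipped$choice <- 7L - resp$choice
    expect_equal(reader_roc_auc(flipped), 1 - reader_roc_auc(resp),
                 tolerance = 1e-12)
  }
})

test_that("across-reader summary uses mean and population standard deviation", {
  tab <- tibble::tibble(
    reader = rep(c("A", "B", "C"), 2),
    model = rep(c("OP", "BC"), each = 3),
    view = rep(c("CC", "MLO"), each = 3),
    auc = c(0.580, 0.576, 0.689, 0.962, 0.956, 0.944)
  )
  out <- summarize_readers(tab)
  op <- out[out$model == "OP", ]
  bc <- out[out$model == "BC", ]
  expect_equal(op$mean_auc, 0.615)
  expect_equal(op$sd_auc, 0.052, tolerance = 0.001 / 0.052)
  expect_equal(bc$mean_auc, 0.954)
  expect_equal(bc$sd_auc, 0.007, tolerance = 0.001 / 0.007)
  same <- summarize_readers(tibble::tibble(reader = c("A", "B"), cell = "x",
                                           auc = c(0.7, 0.7)))
  expect_equal(same$sd_auc, 0)
})

test_that("non-informative simulated readers average to chance AUC", {
  key <- tibble::tibble(image_id = sprintf("i%02d", 1:60),
                        truth = rep(c("synthetic", "original"), each = 30))
  aucs <- vapply(1:200, function(s) {
    reader_roc_auc(simulate_reader(key, skill = 0, seed = s))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  skilled <- reader_roc_auc(simulate_reader(key, skill = 1, seed = 1))
  expect_gt(skilled, 0.9)
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  resp <- tibble::tibble(
    choice = sample(1:6, 80, replace = TRUE),
    truth = rep(c("synthetic", "original"), 40)
  )
  ours <- reader_roc_auc(resp)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = resp$truth, predictor = choice_to_probability(resp$choice),
    levels = c("original", "synthetic"), direction = "<", quiet = TRUE
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})
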