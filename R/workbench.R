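#' Breast-region preprocessing: crop, aspect-preserving resize, pad
#'
#' Mirrors the standard mammogram preprocessing chain: threshold the image
#' to find the breast (dropping small bright specks), crop tightly to the
#' foreground bounding box, resize preserving the aspect ratio so the crop
#' fits inside the target, and zero-pad to the exact target size. Lesion
#' boxes are carried through the same affine transform.
#'
#' @param image Numeric matrix in \[0,1\], background darker than breast.
#' @param target_size `c(height, width)`; the clinical default is
#'   `c(1332, 800)`, desk work typically uses `c(256, 160)`.
#' @param boxes Optional lesion box tibble (`x`, `y`, `w`, `h`, 0-based) to
#'   transform along with the image.
#' @param threshold Foreground intensity threshold.
#' @param min_component Connected components smaller than this many pixels
#'   are not considered breast tissue.
#' @return A list: `image` (target-size matrix), `boxes` (transformed, or
#'   `NULL`), `crop` (`c(y0, y1, x0, x1)`, 1-based bounds used), `scale`.
#' @export
preprocess_mammogram <- function(image, target_size = c(256, 160), boxes = NULL,
                                 threshold = 0.05, min_component = 20) {
  stopifnot_image(image)
  fg <- image > threshold
  if (!any(fg)) stop("no foreground above threshold", call. = FALSE)
  labels <- label_components(fg)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_component)
  if (length(keep) == 0) stop("no foreground component large enough", call. = FALSE)
  fg <- matrix(labels %in% keep, nrow(image), ncol(image))
  rows <- which(rowSums(fg) > 0); cols <- which(colSums(fg) > 0)
  y0 <- min(rows); y1 <- max(rows); x0 <- min(cols); x1 <- max(cols)
  crop <- image[y0:y1, x0:x1, drop = FALSE]
  th <- target_size[1]; tw <- target_size[2]
  scale <- min(th / nrow(crop), tw / ncol(crop))
  nh <- max(1L, round(nrow(crop) * scale)); nw <- max(1L, round(ncol(crop) * scale))
  resized <- resize_bilinear(crop, nh, nw)
  out <- matrix(0, th, tw)
  out[seq_len(nh), seq_len(nw)] <- resized
  new_boxes <- NULL
  if (!is.null(boxes) && nrow(boxes) > 0) {
    new_boxes <- boxes
    new_boxes$x <- pmax(0L, as.integer(round((boxes$x - (x0 - 1)) * scale)))
    new_boxes$y <- pmax(0L, as.integer(round((boxes$y - (y0 - 1)) * scale)))
    new_boxes$w <- pmax(1L, as.integer(round(boxes$w * scale)))
    new_boxes$h <- pmax(1L, as.integer(round(boxes$h * scale)))
  }
  list(image = out, boxes = new_boxes, crop = c(y0, y1, x0, x1), scale = scale)
}

#' Experiment configuration for the end-to-end desk pipeline
#'
#' Bundles every stage's settings with explicit seeds. The desk preset keeps
#' the full-resolution protocol's structure — density-stratified split,
#' translator-based augmentation arms, FROC/DeLong/stratified evaluation,
#' repetition over seeds — at CPU-friendly sizes.
#'
#' @param n Cohort size.
#' @param birads_distribution Category proportions for [generate_cohort()].
#' @param mass_prevalence,view_mix,domain_style,size Cohort settings.
#' @param test_per_category,train_fraction_d,include_real_d Split plan.
#' @param strategies List of [augmentation_strategy()] objects to compare;
#'   the first should be the baseline.
#' @param translator A [translator_config()] for the quick translators
#'   trained inside the experiment.
#' @param n_families Number of translator families trained (a `combined`
#'   strategy uses one synthetic copy per family).
#' @param at_fppi,iou_threshold,fppi_cap Evaluation settings.
#' @param n_repeats Number of repetition seeds (results are averaged with a
#'   normal-theory 95% CI across repeats).
#' @param seed Global seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n = 100,
                              birads_distribution = c(A = 0.25, B = 0.30, C = 0.30, D = 0.15),
                              mass_prevalence = 0.6, view_mix = 0.5,
                              domain_style = "hologic-like", size = c(128, 80),
                              test_per_category = 5, train_fraction_d = 0.25,
                              include_real_d = TRUE,
                              strategies = list(augmentation_strategy("baseline")),
                              translator = desk_translator_config(iterations = 60),
                              n_families = 3,
                              at_fppi = 0.5, iou_threshold = 0.10, fppi_cap = 10,
                              n_repeats = 5, seed = 1) {
  structure(list(
    n = n, birads_distribution = birads_distribution,
    mass_prevalence = mass_prevalence, view_mix = view_mix,
    domain_style = domain_style, size = size,
    test_per_category = test_per_category, train_fraction_d = train_fraction_d,
    include_real_d = include_real_d, strategies = strategies,
    translator = translator, n_families = n_families,
    at_fppi = at_fppi, iou_threshold = iou_threshold, fppi_cap = fppi_cap,
    n_repeats = n_repeats, seed = as.integer(seed)
  ), class = "experiment_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end desk experiment
#'
#' For each repetition seed: generate the phantom cohort, split it by
#' density, train quick translator families on the cohort's healthy
#' low/high-density images, build each strategy's augmented training
#' manifest, run the built-in detector on the test partition, and score it
#' with FROC partial AUC, a density-stratified report, and a paired DeLong
#' comparison of every non-baseline arm against the baseline. Identical
#' configs (including seeds) give identical bundles.
#'
#' Note the built-in blob detector has no trainable parameters, so the
#' augmentation arms exercise the full data pathway (counts, provenance,
#' translation, evaluation) rather than producing genuine detection gains;
#' a learned detector can be substituted wherever
#' \code{\link{baseline_detector}} is called.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_results`: list with `per_seed`
#'   (tibble of per-seed, per-strategy metrics), `aggregate` (mean, sd and
#'   normal-theory 95% CI per strategy), `delong` (per-seed comparisons vs
#'   baseline), `config_hash`, `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  per_seed <- list(); delong_rows <- list(); strat_reports <- list()

  for (rep_i in seq_len(config$n_repeats)) {
    seed_i <- derive_seed(config$seed, paste0("repeat-", rep_i))
    cohort <- generate_cohort(
      config$n, config$birads_distribution, config$mass_prevalence,
      config$view_mix, config$domain_style, config$size, seed = seed_i
    )
    split <- split_cohort(cohort, config$test_per_category,
                          config$train_fraction_d, config$include_real_d,
                          seed = seed_i)

    needs_models <- any(purrr::map_chr(config$strategies, "name") != "baseline")
    registry <- NULL
    if (needs_models) {
      registry <- train_families(cohort, config, seed_i)
    }

    test <- split$test
    dets <- purrr::map(test$image, baseline_detector)
    gts <- test$lesions

    baseline_scores <- NULL
    for (st in config$strategies) {
      st_name <- strategy_label(st)
      aug <- build_augmented_manifest(split$train, st, registry, seed = seed_i)
      fr <- froc_curve(dets, gts, config$iou_threshold)
      strat <- stratified_report(dets, gts, test, config$at_fppi,
                                 config$iou_threshold)
      cs <- build_case_scores(dets, gts, config$fppi_cap, config$iou_threshold)
      if (st$name == "baseline") baseline_scores <- cs
      per_seed[[length(per_seed) + 1]] <- tibble::tibble(
        repeat_seed = rep_i, strategy = st_name,
        n_train = nrow(split$train), n_augmented = nrow(aug),
        n_test = nrow(test), auc_percent = fr$auc_percent,
        fairness_gap = strat$fairness_gap
      )
      strat_reports[[paste(rep_i, st_name, sep = "/")]] <- strat$by_category
      if (st$name != "baseline" && !is.null(baseline_scores)) {
        feasible <- length(cs$positives) >= 2 && length(cs$negatives) >= 2
        row <- if (feasible) {
          tidy.delong_comparison(delong_compare(cs, baseline_scores))
        } else {
          # too few case scores for a variance estimate at this desk size
          tibble::tibble(auc_A = NA_real_, auc_B = NA_real_, delta = NA_real_,
                         variance = NA_real_, z = NA_real_, p_value = NA_real_)
        }
        delong_rows[[length(delong_rows) + 1]] <- dplyr::mutate(
          row, repeat_seed = rep_i, strategy = st_name, .before = 1
        )
      }
    }
  }

  per_seed <- dplyr::bind_rows(per_seed)
  aggregate <- dplyr::summarize(
    dplyr::group_by(per_seed, .data$strategy),
    mean_auc = mean(.data$auc_percent),
    sd_auc = stats::sd(.data$auc_percent),
    ci_lo = mean(.data$auc_percent) -
      1.96 * stats::sd(.data$auc_percent) / sqrt(dplyr::n()),
    ci_hi = mean(.data$auc_percent) +
      1.96 * stats::sd(.data$auc_percent) / sqrt(dplyr::n()),
    n_seeds = dplyr::n(),
    .groups = "drop"
  )
  structure(list(
    per_seed = per_seed, aggregate = aggregate,
    delong = if (length(delong_rows)) dplyr::bind_rows(delong_rows) else NULL,
    stratified = strat_reports,
    config_hash = hash, config = config
  ), class = "experiment_results")
}

strategy_label <- function(st) {
  switch(st$name,
    baseline = "baseline",
    single = paste0("single-1to1-", st$dataset),
    combined = "combined-1to3"
  )
}

# Train one quick translator per family on the cohort's healthy images
# (low-density A as source, high-density D as target), mirroring the rule
# that translators see only normal images.
train_families <- function(cohort, config, seed) {
  healthy <- cohort[cohort$pathology == "normal", , drop = FALSE]
  if (nrow(healthy) < 4) {
    stop("cohort has too few healthy images for translator training", call. = FALSE)
  }
  src <- healthy[healthy$birads == "A", , drop = FALSE]
  tgt <- healthy[healthy$birads == "D", , drop = FALSE]
  # small cohorts may lack healthy images in the extreme categories; fall
  # back to the least/most dense halves of the healthy pool
  if (nrow(src) == 0 || nrow(tgt) == 0) {
    ord <- order(healthy$density_percent)
    half <- floor(nrow(healthy) / 2)
    src <- healthy[ord[seq_len(half)], , drop = FALSE]
    tgt <- healthy[rev(ord)[seq_len(half)], , drop = FALSE]
  }
  fams <- paste0("fam", seq_len(config$n_families))
  purrr::map_dfr(seq_along(fams), function(i) {
    fit <- train_translator(src, tgt, config$translator,
                            seed = derive_seed(seed, paste0("family-", i)))
    tibble::tibble(model_id = paste0(fams[i], "-All"), dataset = fams[i],
                   view = "All", model = list(fit))
  })
}

#' @export
print.experiment_results <- function(x, ...) {
  cat(sprintf("<experiment_results> %d strategies x %d seeds (config %s)\n",
              length(unique(x$per_seed$strategy)),
              max(x$per_seed$repeat_seed), substr(x$config_hash, 1, 8)))
  print(x$aggregate)
  invisible(x)
}

#' @method tidy experiment_results
#' @export
tidy.experiment_results <- function(x, ...) x$per_seed

#' @method glance experiment_results
#' @export
glance.experiment_results <- function(x, ...) x$aggregate
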