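#' Augmentation strategies for density-rebalanced detector training
#'
#' Three strategy shapes mirror the detection experiments: `baseline` (no
#' synthetic images), `single` (one view-matched translation model family,
#' one synthetic copy per real image — 1:1), and `combined` (one synthetic
#' copy per model family per real image — 1:3 with three families).
#'
#' @param name `"baseline"`, `"single"` or `"combined"`.
#' @param dataset For `single`: the model family (dataset tag) to draw from.
#' @param include_real_d Whether the underlying split kept real BI-RADS D
#'   records in training (carried as metadata).
#' @return An `augmentation_strategy` object.
#' @export
augmentation_strategy <- function(name = c("baseline", "single", "combined"),
                                  dataset = NULL, include_real_d = TRUE) {
  name <- match.arg(name)
  if (name == "single" && is.null(dataset)) {
    stop("a 'single' strategy needs the model family's dataset tag", call. = FALSE)
  }
  structure(list(name = name, dataset = dataset,
                 synthetic_per_real = switch(name, baseline = 0L, single = 1L,
                                             combined = NA_integer_),
                 include_real_d = include_real_d),
            class = "augmentation_strategy")
}

# Pick the view-matched model row from a registry subset (falls back to the
# combined-view "All" model).
pick_model_row <- function(registry, dataset, view) {
  rows <- registry[registry$dataset == dataset, , drop = FALSE]
  hit <- rows[rows$view == view, , drop = FALSE]
  if (nrow(hit) == 0) hit <- rows[rows$view == "All", , drop = FALSE]
  if (nrow(hit) == 0) {
    stop(sprintf("no view-matched model for dataset '%s', view '%s'", dataset, view),
         call. = FALSE)
  }
  hit[1, , drop = FALSE]
}

#' Build an augmented training manifest
#'
#' Appends translated synthetic copies to every real training record:
#' one copy from the strategy's model family for `single`, one per family
#' for `combined`, none for `baseline`. Synthetic records keep their
#' parent's lesion boxes and views, carry `provenance = "synthetic"` and a
#' `parent_id`, and have their BI-RADS label rewritten to `D` — they are
#' high-density translations whose purpose is rebalancing category D. The
#' output always has exactly `(1 + synthetic_per_real) * n_real` rows.
#'
#' @param train_manifest The training partition manifest.
#' @param strategy An [augmentation_strategy()].
#' @param models Model registry: tibble with columns `model_id`, `dataset`,
#'   `view` and a `model` list-column of [train_translator()] fits. Not
#'   needed for `baseline`.
#' @param seed Unused for fixed models (translation is deterministic); kept
#'   for interface stability.
#' @return A manifest tibble.
#' @export
build_augmented_manifest <- function(train_manifest, strategy, models = NULL,
                                     seed = 1) {
  stopifnot(inherits(strategy, "augmentation_strategy"),
            is.data.frame(train_manifest))
  base <- train_manifest
  if (!"parent_id" %in% names(base)) base$parent_id <- NA_character_
  if (strategy$name == "baseline" || nrow(train_manifest) == 0) return(base)
  if (is.null(models) || nrow(models) == 0) {
    stop("strategy requires a model registry", call. = FALSE)
  }
  families <- if (strategy$name == "single") strategy$dataset else
    unique(models$dataset)
  if (strategy$name == "single" && !strategy$dataset %in% models$dataset) {
    stop(sprintf("model family '%s' not present in registry", strategy$dataset),
         call. = FALSE)
  }
  syn <- purrr::map_dfr(seq_len(nrow(train_manifest)), function(i) {
    rec <- train_manifest[i, , drop = FALSE]
    purrr::map_dfr(families, function(fam) {
      row <- pick_model_row(models, fam, rec$view)
      out <- translate(row$model[[1]], rec, resize = TRUE)
      out$id <- paste0(rec$id, "-syn-", row$model_id)
      out$birads <- "D"
      out
    })
  })
  dplyr::bind_rows(base, syn)
}

#' Random horizontal flip with consistent box mirroring
#'
#' The only geometric augmentation used during detector training: with the
#' stated probability the image is mirrored left-right and every lesion box
#' is mirrored with it (`x` becomes `width - x - w`). Flipping twice with
#' probability 1 restores the original record.
#'
#' @param record One-row manifest tibble.
#' @param flip_probability Probability in \[0,1\] of flipping.
#' @param seed Integer seed deciding the coin flip.
#' @return The (possibly flipped) record.
#' @export
training_transform <- function(record, flip_probability = 0.5, seed = 1) {
  if (flip_probability < 0 || flip_probability > 1) {
    stop("flip_probability must be in [0,1]", call. = FALSE)
  }
  do_flip <- flip_probability >= 1 ||
    (flip_probability > 0 &&
       with_seed(derive_seed(seed, paste0("flip-", record$id)),
                 stats::runif(1) < flip_probability))
  if (!do_flip) return(record)
  img <- record$image[[1]]
  wid <- ncol(img)
  rec <- record
  rec$image <- list(img[, rev(seq_len(wid)), drop = FALSE])
  if ("mask" %in% names(rec) && !is.null(rec$mask[[1]])) {
    rec$mask <- list(rec$mask[[1]][, rev(seq_len(wid)), drop = FALSE])
  }
  les <- record$lesions[[1]]
  if (!is.null(les) && nrow(les) > 0) {
    les$x <- as.integer(wid - les$x - les$w)
    rec$lesions <- list(les)
  }
  rec
}
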