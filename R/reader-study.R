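#' Assemble a balanced synthetic-vs-original reader study
#'
#' Builds the presentation manifest for a perceptual realism study: for each
#' source dataset, `per_source` original high-density images and `per_source`
#' synthetic ones from that source's translation model family, each cell
#' split equally between CC and MLO views. With three sources and
#' `per_source = 30` this is the 180-image design (90 original, 90
#' synthetic, 15 per view per cell). Presentation order is seeded-shuffled
#' and truth labels are returned separately so the study manifest itself
#' carries no answer key.
#'
#' @param pool Tibble of candidate images with columns `id`, `source`
#'   (dataset tag), `view` (`"CC"`/`"MLO"`) and `truth` (`"original"` or
#'   `"synthetic"`).
#' @param per_source Images per truth class per source (must be even so
#'   views balance).
#' @param seed Integer seed for sampling and shuffling.
#' @return A list: `study` (tibble `position`, `image_id`) and `key` (tibble
#'   `image_id`, `source`, `view`, `truth`).
#' @export
assemble_study <- function(pool, per_source = 30, seed = 1) {
  stopifnot(is.data.frame(pool),
            all(c("id", "source", "view", "truth") %in% names(pool)))
  if (per_source %% 2 != 0) {
    stop("per_source must be even to balance CC and MLO views", call. = FALSE)
  }
  half <- per_source / 2
  cells <- tidyr::expand_grid(
    source = unique(pool$source),
    truth = c("original", "synthetic"),
    view = c("CC", "MLO")
  )
  with_seed(derive_seed(seed, "reader-study"), {
    chosen <- purrr::pmap_dfr(cells, function(source, truth, view) {
      cand <- pool[pool$source == source & pool$truth == truth & pool$view == view, ]
      if (nrow(cand) < half) {
        stop(sprintf("source '%s' supplies %d %s %s images; %d required",
                     source, nrow(cand), truth, view, half), call. = FALSE)
      }
      cand[sample(nrow(cand), half), ]
    })
    shuffled <- chosen[sample(nrow(chosen)), ]
    list(
      study = tibble::tibble(position = seq_len(nrow(shuffled)),
                             image_id = shuffled$id),
      key = tibble::tibble(image_id = shuffled$id, source = shuffled$source,
                           view = shuffled$view, truth = shuffled$truth)
    )
  })
}

#' Convert a 6-point confidence choice to a synthetic-probability
#'
#' Responses use a 6-point scale, choice 1 meaning most confident the image
#' is synthetic and choice 6 most confident it is original; choices map to
#' the equally spaced probabilities (0.95, 0.77, 0.59, 0.41, 0.23, 0.05) of
#' the image being synthetic, i.e. choice k gives 0.95 - 0.18 (k - 1). The
#' scale orientation is a convention: flipping it mirrors every reader AUC
#' about 0.5 without changing the analysis.
#'
#' @param choice Integer vector with values in 1..6.
#' @return Numeric vector of probabilities.
#' @examples
#' choice_to_probability(1:6)
#' @export
choice_to_probability <- function(choice) {
  if (any(is.na(choice)) || any(choice != as.integer(choice)) ||
      any(choice < 1 | choice > 6)) {
    stop("choice must be an integer in 1..6", call. = FALSE)
  }
  0.95 - 0.18 * (as.integer(choice) - 1)
}

#' ROC AUC of one reader's responses
#'
#' Scores are the synthetic-probabilities of the reader's choices, the
#' positive class is `truth == "synthetic"`, and the AUC is the midrank
#' (tie-aware) Mann-Whitney statistic: a reader at chance scores 0.5 and a
#' reader who always recognises synthetic images scores 1.
#'
#' @param responses Tibble with columns `choice` (1..6) and `truth`
#'   (`"synthetic"`/`"original"`); both truth classes must be present.
#' @return AUC in \[0, 1\].
#' @export
reader_roc_auc <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("choice", "truth") %in% names(responses)))
  p <- choice_to_probability(responses$choice)
  pos <- p[responses$truth == "synthetic"]
  neg <- p[responses$truth == "original"]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("responses must contain both truth classes", call. = FALSE)
  }
  midrank_placements(pos, neg)$auc
}

#' Summarise per-reader AUCs per model/view cell
#'
#' Across-reader summary in the reader-study table layout: arithmetic mean
#' and population (divide-by-n) standard deviation of the reader AUCs in
#' each cell. The population convention is what reproduces the printed
#' spreads from printed per-reader values.
#'
#' @param auc_table Tibble with columns `reader`, one or more cell
#'   identifiers (e.g. `model`, `view`), and `auc`.
#' @param ... Grouping columns (tidy-select), default all non-`reader`,
#'   non-`auc` columns.
#' @return A tibble with the grouping columns plus `mean_auc`, `sd_auc`,
#'   `n_readers`.
#' @examples
#' tab <- tibble::tibble(reader = c("A", "B", "C"),
#'                       model = "OP", view = "CC",
#'                       auc = c(0.580, 0.576, 0.689))
#' summarize_readers(tab)   # mean 0.615, population sd 0.052
#' @export
summarize_readers <- function(auc_table, ...) {
  stopifnot(is.data.frame(auc_table), all(c("reader", "auc") %in% names(auc_table)))
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    cols <- setdiff(names(auc_table), c("reader", "auc"))
    grouped <- dplyr::group_by(auc_table, dplyr::across(dplyr::all_of(cols)))
  } else {
    grouped <- dplyr::group_by(auc_table, !!!groups)
  }
  dplyr::summarize(
    grouped,
    mean_auc = mean(.data$auc),
    sd_auc = sqrt(mean((.data$auc - mean(.data$auc))^2)),
    n_readers = dplyr::n(),
    .groups = "drop"
  )
}

#' Simulate reader responses for a study key
#'
#' Generates responses from a simple reader model for testing and
#' calibration: with probability `skill` the reader "sees" the truth and
#' draws a choice from the concordant end of the scale, otherwise uniformly.
#' `skill = 0` is the non-informative reader whose expected AUC is 0.5.
#'
#' @param key Study key tibble (`image_id`, `truth`).
#' @param reader_id Label for the simulated reader.
#' @param skill Probability in \[0,1\] of an informed response.
#' @param seed Integer seed.
#' @return A responses tibble: `reader`, `image_id`, `choice`, `truth`.
#' @export
simulate_reader <- function(key, reader_id = "sim", skill = 0, seed = 1) {
  stopifnot(skill >= 0, skill <= 1)
  with_seed(derive_seed(seed, paste0("reader-", reader_id)), {
    n <- nrow(key)
    informed <- stats::runif(n) < skill
    uninformed_choice <- sample(1:6, n, replace = TRUE)
    concordant <- ifelse(key$truth == "synthetic",
                         sample(1:2, n, replace = TRUE),
                         sample(5:6, n, replace = TRUE))
    tibble::tibble(
      reader = reader_id,
      image_id = key$image_id,
      choice = ifelse(informed, concordant, uninformed_choice),
      truth = key$truth
    )
  })
}
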