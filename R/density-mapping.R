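#' Breast-density to BI-RADS category mappings
#'
#' Vendor density software reports a continuous percentage — Volpara gives a
#' volumetric breast density (VBD) percentage, LIBRA an area-based percent
#' density — while clinical reporting uses the four ACR BI-RADS composition
#' categories A (almost entirely fatty) through D (extremely dense). These
#' functions apply the published cut points used to harmonise the two scales:
#'
#' * Volpara VBD: A if \eqn{\le 3.5}, B in (3.5, 7.5], C in (7.5, 15.5),
#'   D if \eqn{\ge 15.5}.
#' * LIBRA percent density: A if \eqn{\le 2.8}, B in (2.8, 25], C in (25, 75),
#'   D if \eqn{\ge 75}.
#' * ACR categories 1--4 relabel directly to A--D.
#'
#' The printed intervals for B and C are open at their shared interior
#' boundary; each interior boundary is assigned to the lower category so the
#' mapping is total and deterministic on \[0, 100\].
#'
#' @param vbd_percent,percent Numeric vector of density percentages in
#'   \[0, 100\].
#' @param acr_category Integer vector with values in 1--4.
#' @return A factor with levels `A`, `B`, `C`, `D`.
#' @examples
#' map_volpara(c(2, 10, 15.5))
#' map_libra(c(1, 50, 75))
#' map_acr(1:4)
#' @name density_mapping
NULL

birads_levels <- c("A", "B", "C", "D")

map_percent_to_birads <- function(p, cuts) {
  if (any(is.na(p)) || any(p < 0 | p > 100)) {
    stop("density percentage must be in [0, 100]", call. = FALSE)
  }
  # boundaries belong to the lower category: A on [0, c1], B on (c1, c2],
  # C on (c2, c3), D on [c3, 100]
  idx <- ifelse(p <= cuts[1], 1L, ifelse(p <= cuts[2], 2L, ifelse(p < cuts[3], 3L, 4L)))
  factor(birads_levels[idx], levels = birads_levels)
}

#' @rdname density_mapping
#' @export
map_volpara <- function(vbd_percent) map_percent_to_birads(vbd_percent, c(3.5, 7.5, 15.5))

#' @rdname density_mapping
#' @export
map_libra <- function(percent) map_percent_to_birads(percent, c(2.8, 25, 75))

#' @rdname density_mapping
#' @export
map_acr <- function(acr_category) {
  if (any(is.na(acr_category)) || any(acr_category != as.integer(acr_category)) ||
      any(acr_category < 1 | acr_category > 4)) {
    stop("ACR category must be an integer in 1..4", call. = FALSE)
  }
  factor(birads_levels[as.integer(acr_category)], levels = birads_levels)
}

#' Density interval covered by a BI-RADS category under a mapping
#'
#' Returns the half-open percentage interval a category occupies under the
#' chosen density source. The D interval is capped at 95% so sampled phantom
#' densities avoid degenerate fully dense images.
#'
#' @param birads Character vector of categories in `A`--`D`.
#' @param source One of `"volpara"`, `"libra"`, `"acr"`, `"phantom_truth"`.
#'   `"acr"` and `"phantom_truth"` use the LIBRA-style area-fraction cuts,
#'   which is the scale the phantom generator controls by construction.
#' @param d_cap Upper bound used for category D (default 95).
#' @return A two-column matrix with columns `lo`, `hi`.
#' @export
density_interval <- function(birads, source = "libra", d_cap = 95) {
  cuts <- switch(match.arg(source, c("libra", "volpara", "acr", "phantom_truth")),
    volpara = c(3.5, 7.5, 15.5),
    c(2.8, 25, 75)
  )
  lo <- c(A = 0, B = cuts[1], C = cuts[2], D = cuts[3])
  hi <- c(A = cuts[1], B = cuts[2], C = cuts[3], D = d_cap)
  b <- as.character(birads)
  if (any(!b %in% birads_levels)) stop("unknown BI-RADS category", call. = FALSE)
  cbind(lo = lo[b], hi = hi[b])
}

#' Density-stratified train/validation/test split
#'
#' Splits a cohort manifest the way the detection experiments require:
#' a fixed-size seeded test set per BI-RADS category, and a training set that
#' either excludes real BI-RADS D records entirely or includes a ceiling
#' fraction of those available (e.g. 25% of 161 available D records gives
#' 41 in training). BI-RADS D records not placed in train or test form the
#' validation set; all non-D leftovers train.
#'
#' @param manifest A cohort manifest tibble with at least `id` and `birads`
#'   columns (see [generate_cohort()]).
#' @param test_per_category Number of records per category reserved for test.
#' @param train_fraction_d Fraction of the remaining D records placed in
#'   training when `include_real_d = TRUE`; rounded up.
#' @param include_real_d Should real BI-RADS D records enter training at all?
#' @param seed Integer seed controlling the sampling.
#' @return A list of three disjoint tibbles: `train`, `validation`, `test`,
#'   whose row counts sum to `nrow(manifest)`.
#' @examples
#' m <- tibble::tibble(id = as.character(1:200),
#'                     birads = rep(c("A", "B", "C", "D"), 50))
#' sp <- split_cohort(m, test_per_category = 10, seed = 1)
#' nrow(sp$test)
#' @export
split_cohort <- function(manifest, test_per_category = 0, train_fraction_d = 0.25,
                         include_real_d = TRUE, seed = 1) {
  stopifnot(is.data.frame(manifest), "birads" %in% names(manifest))
  if (train_fraction_d < 0 || train_fraction_d > 1) {
    stop("train_fraction_d must be in [0, 1]", call. = FALSE)
  }
  b <- as.character(manifest$birads)
  with_seed(derive_seed(seed, "split"), {
    test_idx <- integer(0)
    for (cat in intersect(birads_levels, unique(b))) {
      pool <- which(b == cat)
      if (length(pool) < test_per_category) {
        stop(sprintf("category %s has %d records, fewer than test_per_category = %d",
                     cat, length(pool), test_per_category), call. = FALSE)
      }
      test_idx <- c(test_idx, sample(pool, test_per_category))
    }
    rest <- setdiff(seq_len(nrow(manifest)), test_idx)
    rest_d <- rest[b[rest] == "D"]
    if (include_real_d) {
      n_train_d <- ceiling(train_fraction_d * length(rest_d))
      train_d <- if (n_train_d > 0) sample(rest_d, n_train_d) else integer(0)
    } else {
      train_d <- integer(0)
    }
    val_idx <- setdiff(rest_d, train_d)
    train_idx <- c(setdiff(rest, rest_d), train_d)
    list(
      train = manifest[sort(train_idx), , drop = FALSE],
      validation = manifest[sort(val_idx), , drop = FALSE],
      test = manifest[sort(test_idx), , drop = FALSE]
    )
  })
}
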