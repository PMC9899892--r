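#' Read and write cohort manifests and annotations
#'
#' A manifest on disk is a plain CSV with one row per image and columns
#' `id, path, view, density_percent, density_source, birads, domain,
#' provenance, pathology`; images are PNG files next to it and lesion boxes
#' live in a COCO-style JSON (`bbox = [x, y, w, h]`, 0-based pixels).
#' [write_cohort()] materialises an in-memory manifest to such a directory
#' and [read_cohort()] loads it back with `image`, `mask` and `lesions`
#' list-columns restored (masks are recomputed as nonzero-intensity support
#' is not stored).
#'
#' @param manifest A manifest tibble with `image` and `lesions` list-columns.
#' @param dir Output/input directory.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a manifest tibble.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort <- function(manifest, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for image I/O", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(manifest$id, ".png"))
  purrr::walk2(manifest$image, paths, function(img, p) png::writePNG(img, p))
  flat <- dplyr::select(manifest, -dplyr::any_of(c("image", "mask", "lesions")))
  flat$path <- basename(paths)
  utils::write.csv(flat, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_coco(manifest, file.path(dir, "lesions.json"))
  invisible(dir)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for image I/O", call. = FALSE)
  }
  flat <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  imgs <- purrr::map(file.path(dir, flat$path), function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  coco <- read_coco(file.path(dir, "lesions.json"))
  lesions <- purrr::map(flat$id, function(id) {
    b <- coco[coco$image_id == id, c("x", "y", "w", "h"), drop = FALSE]
    tibble::as_tibble(b)
  })
  out <- tibble::as_tibble(flat)
  out$image <- imgs
  out$mask <- purrr::map(imgs, function(im) im > 0.1)
  out$lesions <- lesions
  out
}

# COCO-style annotation export: images + annotations arrays, bbox [x,y,w,h].
write_coco <- function(manifest, path) {
  images <- purrr::imap(manifest$id, function(id, i) {
    list(id = id, height = nrow(manifest$image[[i]]), width = ncol(manifest$image[[i]]))
  })
  anns <- list(); k <- 0L
  for (i in seq_len(nrow(manifest))) {
    les <- manifest$lesions[[i]]
    if (is.null(les) || nrow(les) == 0) next
    for (j in seq_len(nrow(les))) {
      k <- k + 1L
      anns[[k]] <- list(
        id = k, image_id = manifest$id[i], category_id = 1L,
        bbox = c(les$x[j], les$y[j], les$w[j], les$h[j])
      )
    }
  }
  jsonlite::write_json(
    list(images = images,
         annotations = anns,
         categories = list(list(id = 1L, name = "mass"))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

read_coco <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(j$annotations) == 0) {
    return(data.frame(image_id = character(0), x = integer(0), y = integer(0),
                      w = integer(0), h = integer(0)))
  }
  purrr::map_dfr(j$annotations, function(a) {
    data.frame(image_id = a$image_id, x = a$bbox[[1]], y = a$bbox[[2]],
               w = a$bbox[[3]], h = a$bbox[[4]])
  })
}

#' Write detector outputs as COCO-style results JSON
#'
#' @param detections A tibble with columns `image_id`, `x`, `y`, `w`, `h`,
#'   `score`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- purrr::pmap(detections, function(image_id, x, y, w, h, score, ...) {
    list(image_id = image_id, bbox = c(x, y, w, h), score = score)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
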