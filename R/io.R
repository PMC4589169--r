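#' Write / read an RGB montage as 8-bit TIFF with a JSON scale sidecar
#'
#' The physical pixel size travels in `<path>.json` next to the image so
#' that size-filtered quantification always has a scale.
#'
#' @param image a [montage_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(image, path) {
  stopifnot(inherits(image, "montage_image"))
  tiff::writeTIFF(image$rgb / 255, path, bits.per.sample = 8L,
                  compression = "LZW")
  jsonlite::write_json(list(pixel_size_um = image$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  arr <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  montage_image(round(arr * 255), pixel_size = meta$pixel_size_um)
}

#' Write / read a grey vessel raster as TIFF with a JSON scale sidecar
#' @param image a `vessel_image`.
#' @param path output TIFF path.
#' @export
write_vessel_image <- function(image, path) {
  stopifnot(inherits(image, "vessel_image"))
  tiff::writeTIFF(image$image, path, bits.per.sample = 8L,
                  compression = "LZW")
  jsonlite::write_json(list(pixel_size_um = image$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vessel_image
#' @export
read_vessel_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(image = img, pixel_size = meta$pixel_size_um),
            class = "vessel_image")
}

#' Write / read a binary lesion mask as PNG with a JSON scale sidecar
#' @param mask a `lesion_mask` or logical matrix.
#' @param path output PNG path.
#' @param mm_per_px scale, required when `mask` is a bare matrix.
#' @export
write_lesion_mask <- function(mask, path, mm_per_px = NULL) {
  if (inherits(mask, "lesion_mask")) {
    mm_per_px <- mask$mm_per_px
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask), is.numeric(mm_per_px))
  png::writePNG(mask * 1, path)
  jsonlite::write_json(list(mm_per_px = mm_per_px), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lesion_mask
#' @export
read_lesion_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(mask = img > 0.5, mm_per_px = meta$mm_per_px,
                 centers_mm = NULL, diameters_mm = NULL, bridges = NULL),
            class = "lesion_mask")
}

#' Read / write a cohort table CSV
#' @param tab a `cohort_table` data.frame.
#' @param path CSV path.
#' @export
write_cohort <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
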